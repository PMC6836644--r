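"""Feature-class circular fingerprints for a list of SMILES.

Usage: python circular_fp.py <diameter> <n_bits> <smiles_file>

Writes one line per input SMILES to stdout: the fingerprint as a string
of 0/1 characters, or the literal token ERROR when the SMILES cannot be
parsed. Used by the optional R adapter; kept dependency-free beyond
RDKit.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def main() -> None:
    diameter = int(sys.argv[1])
    n_bits = int(sys.argv[2])
    if diameter < 0 or diameter % 2 != 0:
        raise SystemExit("diameter must be a non-negative even integer")
    radius = diameter // 2
    with open(sys.argv[3]) as handle:
        for line in handle:
            smiles = line.strip()
            mol = Chem.MolFromSmiles(smiles) if smiles else None
            if mol is None:
                print("ERROR")
                continue
            fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(
                mol, radius, nBits=n_bits, useFeatures=True
            )
            print(fp.ToBitString())


if __name__ == "__main__":
    main()
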