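# mcscreen

Measure-guided multiple classifier systems (MCS) for ligand-based virtual
screening.

## What problem this solves, and for whom

A medicinal-chemistry team with a few thousand compounds of known activity
against a target (binary fingerprints + physicochemical descriptors,
Active/Inactive labels from a potency cutoff) wants to screen a
multi-million-compound vendor library and purchase a small, diverse,
high-confidence set for assay. `mcscreen` implements that workflow
end-to-end:

1. **Feature clustering** — columns are grouped into `k` clusters by Fisher
   score, $F_j = (\mu_{A,j}-\mu_{I,j})^2 / (\sigma^2_{A,j}+\sigma^2_{I,j})$,
   dealt round-robin within each feature type so every cluster gets a
   balanced mix.
2. **Measure-guided selection** — per cluster, a roster of classifier
   families is grid-searched by stratified cross-validation against a chosen
   objective: the Matthews correlation coefficient
   $$MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP{+}FP)(FN{+}TN)(FP{+}TN)(TP{+}FN)}}$$
   or the positive predictive value $PPV = TP/(TP+FP)$.
3. **Voting** — inner probabilities are thresholded at 0.5 and combined by
   majority vote (ties → Active); two measure-optimized models compose two
   meta-models: **minimize FP** (Active iff *both* agree, AND) and
   **minimize FN** (Active iff *either* says Active, OR).
4. **Ranking** — predicted actives are ordered by global relevance
   $\Theta = \prod_i C_i$, the product of all inner-classifier Active
   probabilities, which separates candidates that sum/mean cannot
   ($[0.75,0.75,0.6]$ vs $[0.6,0.9,0.6]$: both sum 2.1, mean 0.7 — products
   0.3375 vs 0.324).
5. **Diversity selection** — Tanimoto leader clustering (distance cap 0.35)
   of the ranked actives, keeping the top-Θ representative per cluster.

A synthetic-data module generates tables with the same schema (fingerprint
bits, discrete + continuous descriptors, class) and controllable
class-conditional signal, so the whole pipeline is testable without any
external data. Pharmacology helpers (Cheng–Prusoff $K_i$, $pK_i$, percent
specific binding, hit rates) cover the downstream assay bookkeeping.

## Worked example

```r
library(mcscreen)

spec <- synthetic_spec(n_active = 300, n_inactive = 300,
                       n_informative_bits = 24,
                       p_active = 0.7, p_inactive = 0.3, seed = 42)
cfg  <- pipeline_config(out_dir = "artifacts", synthetic = spec, seed = 42,
                        screening_prevalence = 0.05, screening_n = 2000,
                        selection_size = 21)
res <- run_pipeline(cfg)
```

Held-out evaluation (group 4 of the 4-group split), as printed from
`res$report`:

```
mcc_model    TP= 73 FP= 4 TN= 71 FN= 2  MCC=0.920 PPV=0.948 acc=0.960 errors=6
ppv_model    TP= 74 FP= 2 TN= 73 FN= 1  MCC=0.960 PPV=0.974 acc=0.980 errors=3
minimize_fp  TP= 73 FP= 2 TN= 73 FN= 2  MCC=0.947 PPV=0.973 acc=0.973 errors=4
minimize_fn  TP= 74 FP= 4 TN= 71 FN= 1  MCC=0.934 PPV=0.949 acc=0.967 errors=5
```

Read the meta-model rows against their constituents: `minimize_fp` (AND)
has FP = 2 ≤ min(4, 2) and `minimize_fn` (OR) has FN = 1 ≤ min(2, 1) — both
inequalities are theorems of the combination rules and are asserted exactly
in the test suite. Screening the 2000-compound synthetic library and
ranking the predicted actives by Θ:

```
library: 2000 compounds, 150 predicted Active, 150 chem clusters, 21 purchased
 rank        id     theta theta_trunc
    1 LIB000044 0.9945807       0.994
    2 LIB000066 0.9883427       0.988
    3 LIB000010 0.9850268       0.985
    4 LIB000054 0.9849975       0.984
    5 LIB000092 0.9848477       0.984

hidden truth of the 21 purchased: 21 Active (hit rate 100%)
```

(150 leader clusters out of 150 candidates: unstructured synthetic
fingerprints rarely fall within 0.35 Tanimoto distance of one another, so
clusters are singletons here — real analogue series collapse.)

Individual pieces are usable on their own:

```r
cm <- confusion_from_counts(tp = 474, fp = 3, tn = 475, fn = 30)
mcc(cm)                                   # 0.9343
ppv(cm)                                   # 0.9937
error_count(cm)                           # 33
global_relevance(c(0.75, 0.75, 0.6))      # 0.3375 -> trunc3() gives 0.337
cheng_prusoff_ki(10, ligand_conc = 1.24, kd = 1.24)  # 5 nM
```

## Command line

A thin CLI over the same functions ships in `inst/cli/mcscreen`
(subcommands: `generate`, `partition`, `cluster-features`, `train`,
`evaluate`, `screen`, `rank`, `chem-cluster`, `pharm`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mcscreen",package="mcscreen"))')" \
    generate --out data.tsv --seed 1 --paper-shape
```

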