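#' Compute feature-class circular fingerprints from SMILES (optional adapter)
#'
#' Thin adapter around an RDKit helper script (shipped in
#' `inst/python/circular_fp.py`) producing FCFP-style feature-class
#' Morgan fingerprints as fixed-length binary vectors. Requires a
#' `python` interpreter with RDKit on the `PATH`; the rest of the package
#' never depends on it (synthetic fingerprints are abstract bit
#' vectors).
#'
#' Unparseable SMILES produce a per-row error record (an all-`NA` row and
#' an entry in `$errors`), not a global failure.
#'
#' @param smiles character vector of SMILES strings.
#' @param diameter even circular-fingerprint diameter (default 6, i.e.
#'   Morgan radius 3 with feature invariants).
#' @param n_bits fingerprint length (default 2048).
#' @param python python executable to use.
#' @return list with `bits` (integer matrix, one row per input, `NA` rows
#'   for failures) and `errors` (data frame `index`, `smiles`).
#' @export
compute_circular_fingerprints <- function(smiles, diameter = 6,
                                          n_bits = 2048,
                                          python = Sys.which("python")) {
  if (!is_count(diameter) || diameter < 0 || diameter %% 2 != 0) {
    abort("diameter must be a non-negative even integer")
  }
  if (!is_count(n_bits) || n_bits < 1) abort("n_bits must be a positive integer")
  if (!nzchar(python)) abort("no python interpreter found for the fingerprint backend")
  script <- system.file("python", "circular_fp.py", package = "mcscreen",
                        mustWork = TRUE)
  if (length(smiles) == 0) {
    return(list(bits = matrix(NA_integer_, 0, n_bits),
                errors = data.frame(index = integer(), smiles = character())))
  }

  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp))
  writeLines(smiles, inp)
  out <- suppressWarnings(
    system2(python, c(script, diameter, n_bits, inp), stdout = TRUE,
            stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort("fingerprint backend failed (exit status %d)", status)
  }
  if (length(out) != length(smiles)) {
    abort("fingerprint backend returned %d lines for %d inputs",
          length(out), length(smiles))
  }

  bits <- matrix(NA_integer_, length(smiles), n_bits)
  failed <- out == "ERROR"
  if (any(!failed)) {
    parsed <- vapply(strsplit(out[!failed], "", fixed = TRUE),
                     function(ch) as.integer(ch), integer(n_bits))
    bits[!failed, ] <- t(parsed)
  }
  list(bits = bits,
       errors = data.frame(index = which(failed),
                           smiles = smiles[failed],
                           stringsAsFactors = FALSE))
}
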