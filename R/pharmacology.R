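#' Cheng-Prusoff inhibition constant
#'
#' Converts an IC50 from a competition binding assay into the
#' equilibrium inhibition constant:
#' \deqn{K_i = \frac{IC_{50}}{1 + [L]/K_D}}
#' where `[L]` is the radioligand concentration used in the experiment
#' and `K_D` its dissociation constant. All concentrations are in nM.
#'
#' @param ic50 IC50 in nM (> 0).
#' @param ligand_conc radioligand concentration `[L]` in nM (>= 0).
#' @param kd radioligand dissociation constant in nM (> 0).
#' @return Ki in nM. Vectorized.
#' @export
#' @examples
#' cheng_prusoff_ki(10, ligand_conc = 1.24, kd = 1.24)  # 5
cheng_prusoff_ki <- function(ic50, ligand_conc, kd) {
  if (any(kd <= 0)) abort("kd must be positive")
  if (any(ic50 <= 0)) abort("ic50 must be positive")
  if (any(ligand_conc < 0)) abort("ligand_conc must be non-negative")
  ic50 / (1 + ligand_conc / kd)
}

#' pKi from a Ki in nM
#'
#' `pKi = -log10(Ki in molar)`; `ki_from_pki()` is the exact inverse.
#'
#' @param ki Ki in nM (> 0).
#' @return unitless pKi. Vectorized.
#' @export
#' @examples
#' pki(100)           # 7
#' ki_from_pki(7.67)  # ~21.4 nM
pki <- function(ki) {
  if (any(ki <= 0)) abort("ki must be positive")
  -log10(ki * 1e-9)
}

#' @rdname pki
#' @param pki_value unitless pKi.
#' @export
ki_from_pki <- function(pki_value) 10^(-pki_value) * 1e9

#' Percent specific radioligand binding
#'
#' Normalizes a raw count so that total binding reads 100% and
#' nonspecific binding reads 0%:
#' `100 * (raw - nonspecific) / (total - nonspecific)`.
#'
#' @param raw,total,nonspecific counts; `total` must differ from
#'   `nonspecific`.
#' @return percentage. Vectorized.
#' @export
percent_specific_binding <- function(raw, total, nonspecific) {
  if (any(total == nonspecific)) {
    abort("total and nonspecific binding must differ")
  }
  100 * (raw - nonspecific) / (total - nonspecific)
}

#' Classify a displacement percentage into hit categories
#'
#' Single-concentration displacement screens grade compounds by the
#' percentage of radioligand displaced: at least `high` percent makes a
#' high hit (worth a full affinity curve), at least `medium` percent a
#' medium hit, anything below is inactive.
#'
#' @param percent displacement percentage(s).
#' @param high,medium category thresholds (defaults 50 and 25).
#' @return character vector in `c("high", "medium", "none")`.
#' @export
classify_displacement <- function(percent, high = 50, medium = 25) {
  if (medium > high) abort("medium threshold must not exceed high")
  ifelse(percent >= high, "high", ifelse(percent >= medium, "medium", "none"))
}

#' Hit rate of an experimental validation campaign
#'
#' `100 * hits / tested`: the percentage of purchased/tested compounds
#' confirmed active.
#'
#' @param n_hits number of confirmed hits.
#' @param n_tested number of compounds tested (> 0).
#' @return percentage.
#' @export
#' @examples
#' hit_rate(11, 21)  # ~52.4
hit_rate <- function(n_hits, n_tested) {
  if (any(n_tested <= 0)) abort("n_tested must be positive")
  if (any(n_hits < 0) || any(n_hits > n_tested)) {
    abort("n_hits must lie in [0, n_tested]")
  }
  100 * n_hits / n_tested
}
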