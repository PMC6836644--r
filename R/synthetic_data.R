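#' Specification of a synthetic compound table
#'
#' Describes the generative model used to emulate a fingerprint +
#' descriptor screening dataset with controllable class-conditional
#' signal:
#'
#' * a subset of `n_informative_bits` fingerprint bits is set with
#'   Bernoulli rate `p_active` in Actives and `p_inactive` in Inactives;
#'   the remaining noise bits fire at `background_rate` regardless of
#'   class (0.5 by default, matching frequency-selected fingerprint bits,
#'   which are chosen for ~50% occurrence);
#' * discrete descriptors are Poisson counts with rate
#'   `discrete_base_rate`, shifted by `discrete_shift` in Actives;
#' * continuous descriptors are Gaussian with standard deviation
#'   `continuous_sd` and an Active mean shift of `continuous_shift`.
#'
#' The default schema is a reduced-width version of the real screening
#' layout (256 bits, 10 discrete and 8 continuous descriptors) so the
#' full pipeline runs in seconds; `paper_shape = TRUE` switches to the
#' full 2048/50/34 layout.
#'
#' @param n_active,n_inactive class sizes.
#' @param n_bits fingerprint length.
#' @param n_informative_bits number of class-informative bits
#'   (`<= n_bits`).
#' @param p_active,p_inactive Bernoulli rates of informative bits per
#'   class.
#' @param background_rate Bernoulli rate of noise bits.
#' @param n_discrete,n_continuous descriptor counts.
#' @param discrete_base_rate,discrete_shift Poisson rate and Active shift.
#' @param continuous_shift,continuous_sd Gaussian Active mean shift and sd.
#' @param seed integer seed; generation is fully reproducible from it.
#' @param paper_shape use the full-width 2048/50/34 schema.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 500, n_inactive = 500,
                           n_bits = 256, n_informative_bits = 40,
                           p_active = 0.8, p_inactive = 0.2,
                           background_rate = 0.5,
                           n_discrete = 10, n_continuous = 8,
                           discrete_base_rate = 5, discrete_shift = 1,
                           continuous_shift = 0.5, continuous_sd = 1,
                           seed = 1, paper_shape = FALSE) {
  if (isTRUE(paper_shape)) {
    n_bits <- 2048
    n_discrete <- 50
    n_continuous <- 34
  }
  rates <- c(p_active = p_active, p_inactive = p_inactive,
             background_rate = background_rate)
  if (any(rates < 0) || any(rates > 1)) abort("Bernoulli rates must lie in [0, 1]")
  counts <- c(n_active, n_inactive, n_bits, n_informative_bits,
              n_discrete, n_continuous)
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    abort("counts must be non-negative integers")
  }
  if (n_informative_bits > n_bits) {
    abort("n_informative_bits (%d) exceeds n_bits (%d)",
          n_informative_bits, n_bits)
  }
  if (!is_count(seed)) abort("seed must be an integer")
  structure(list(n_active = n_active, n_inactive = n_inactive,
                 n_bits = n_bits, n_informative_bits = n_informative_bits,
                 p_active = p_active, p_inactive = p_inactive,
                 background_rate = background_rate,
                 n_discrete = n_discrete, n_continuous = n_continuous,
                 discrete_base_rate = discrete_base_rate,
                 discrete_shift = discrete_shift,
                 continuous_shift = continuous_shift,
                 continuous_sd = continuous_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# informative bit columns are a deterministic function of the spec seed,
# so a screening library generated from the same spec shares them
informative_bit_columns <- function(spec) {
  idx <- with_seed(spec$seed,
                   sort(sample.int(spec$n_bits, spec$n_informative_bits)))
  sprintf("B%04d", idx)
}

generate_rows <- function(spec, n_active, n_inactive, id_prefix) {
  n <- n_active + n_inactive
  labels <- rep(c("Active", "Inactive"), c(n_active, n_inactive))
  inf_cols <- informative_bit_columns(spec)
  bit_names <- sprintf("B%04d", seq_len(spec$n_bits))
  inf <- bit_names %in% inf_cols

  rate <- matrix(spec$background_rate, n, spec$n_bits)
  rate[labels == "Active", inf] <- spec$p_active
  rate[labels == "Inactive", inf] <- spec$p_inactive
  bits <- matrix(as.integer(stats::runif(n * spec$n_bits) < rate), n,
                 spec$n_bits, dimnames = list(NULL, bit_names))

  desc <- NULL
  types <- NULL
  nd <- spec$n_discrete
  nc <- spec$n_continuous
  if (nd + nc > 0) {
    lam <- ifelse(labels == "Active",
                  spec$discrete_base_rate + spec$discrete_shift,
                  spec$discrete_base_rate)
    disc <- matrix(stats::rpois(n * nd, rep(lam, nd)), n, nd,
                   dimnames = list(NULL, if (nd > 0) sprintf("D%04d", seq_len(nd))))
    mu <- ifelse(labels == "Active", spec$continuous_shift, 0)
    cont <- matrix(stats::rnorm(n * nc, mean = rep(mu, nc),
                                sd = spec$continuous_sd), n, nc,
                   dimnames = list(NULL, if (nc > 0) sprintf("X%04d", seq_len(nc))))
    desc <- cbind(disc, cont)
    types <- rep(c("discrete", "continuous"), c(nd, nc))
  }

  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  list(table = compound_table(ids, bits, desc, types, labels),
       informative = inf_cols)
}

#' Generate a labeled synthetic compound table
#'
#' Draws a [compound_table()] from the generative model described by a
#' [synthetic_spec()]. Byte-identical output for identical spec (the seed
#' is part of the spec).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (labeled [compound_table()]) and
#'   `informative` (character vector of ground-truth informative bit
#'   columns).
#' @export
#' @examples
#' out <- generate_dataset(synthetic_spec(n_active = 20, n_inactive = 20,
#'                                        n_bits = 32, seed = 7))
#' out$table
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L,
            generate_rows(spec, spec$n_active, spec$n_inactive, "CMPD"))
}

#' Generate an unlabeled screening library with hidden truth
#'
#' Draws compounds from the same generative model (identical informative
#' bit columns, so models trained on [generate_dataset()] output
#' transfer), at a chosen Active prevalence, strips the labels and
#' returns the hidden truth separately for evaluation. Stands in for a
#' large vendor HTS collection.
#'
#' @param spec a [synthetic_spec()].
#' @param prevalence fraction of actives in \[0, 1\].
#' @param n library size (default: `n_active + n_inactive` of the spec).
#' @param fixed_count `TRUE` (default): exactly `round(prevalence * n)`
#'   actives, for test determinism; `FALSE`: a Binomial draw.
#' @return list with `table` (unlabeled [compound_table()]) and `truth`
#'   (named character vector of hidden labels).
#' @export
generate_screening_library <- function(spec, prevalence,
                                       n = spec$n_active + spec$n_inactive,
                                       fixed_count = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1) {
    abort("prevalence must lie in [0, 1]")
  }
  if (!is_count(n) || n < 1) abort("n must be a positive integer")
  # distinct stream offset: the library must not replicate the training draw
  out <- with_seed(spec$seed + 2L, {
    n_act <- if (fixed_count) round(prevalence * n) else stats::rbinom(1, n, prevalence)
    res <- generate_rows(spec, n_act, n - n_act, "LIB")
    # shuffle rows so actives are not a prefix of the library
    perm <- sample.int(n)
    res$table <- subset_rows(res$table, perm)
    res
  })
  truth <- compound_labels(out$table)
  out$table$labels <- rep("Unknown", n)
  list(table = out$table, truth = truth)
}
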