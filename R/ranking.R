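#' Compile Active-class probabilities of predicted actives
#'
#' Stage one of the probabilistic candidate ranking: from a screening
#' prediction, keep only compounds whose final label is Active and return
#' their per-inner-classifier Active probabilities in the documented fixed
#' order (the prediction's probability columns; for a meta-model built
#' with [combine_meta()] that is first-model classifiers by cluster index,
#' then second-model classifiers).
#'
#' @param prediction a `prediction_result` carrying inner probabilities.
#' @return named list (compound id -> numeric probability vector); empty
#'   when nothing was predicted Active.
#' @export
compile_probabilities <- function(prediction) {
  stopifnot(inherits(prediction, "prediction_result"))
  keep <- prediction$ids[prediction$labels[prediction$ids] == "Active"]
  out <- lapply(keep, function(id) prediction$probs[id, ])
  stats::setNames(out, keep)
}

#' Global relevance of a candidate (product of probabilities)
#'
#' \deqn{\Theta = \prod_{i=1}^{m} C_i}
#' where \eqn{C_i} are the candidate's inner-classifier Active
#' probabilities. The product discriminates between probability vectors
#' that the sum and the arithmetic mean cannot separate: e.g.
#' `c(0.75, 0.75, 0.6)` and `c(0.6, 0.9, 0.6)` share sum 2.1 and mean
#' 0.7, but yield products 0.3375 and 0.324.
#'
#' @param probabilities non-empty numeric vector with every element in
#'   (0, 1].
#' @return \eqn{\Theta} in (0, 1], at full floating precision (use
#'   [trunc3()] for the 3-decimal report rendering).
#' @export
#' @examples
#' global_relevance(c(0.75, 0.75, 0.6))  # 0.3375
#' global_relevance(c(0.6, 0.9, 0.6))    # 0.324
global_relevance <- function(probabilities) {
  if (length(probabilities) == 0) abort("empty probability vector")
  if (!is.numeric(probabilities) || any(is.na(probabilities)) ||
      any(probabilities <= 0) || any(probabilities > 1)) {
    abort("probabilities must lie in (0, 1]")
  }
  prod(probabilities)
}

#' Sum and arithmetic mean of a probability vector
#'
#' Provided to demonstrate the discriminating power of the product
#' aggregator: distinct probability vectors can share both sum and mean
#' while their products differ.
#'
#' @param probabilities non-empty numeric vector.
#' @return named numeric vector `c(sum = ..., mean = ...)`.
#' @export
comparison_aggregates <- function(probabilities) {
  if (length(probabilities) == 0) abort("empty probability vector")
  c(sum = sum(probabilities), mean = mean(probabilities))
}

#' Rank candidates by descending global relevance
#'
#' Stage three of the candidate ranking: compute \eqn{\Theta} per
#' candidate and arrange the compounds in descending order of
#' \eqn{\Theta}, so the best candidates occupy the initial positions.
#' Ties are broken by ascending compound id, making purchasing lists
#' reproducible.
#'
#' @param candidates named list (id -> probability vector) as returned by
#'   [compile_probabilities()].
#' @return data frame with columns `rank`, `id`, `theta`, `theta_trunc`
#'   (3-decimal truncated rendering) followed by one column per inner
#'   probability.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) == 0) {
    return(data.frame(rank = integer(), id = character(), theta = numeric(),
                      theta_trunc = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(names(candidates)) || any(!nzchar(names(candidates)))) {
    abort("candidates must be a named list (compound id -> probabilities)")
  }
  theta <- vapply(candidates, global_relevance, numeric(1))
  ids <- names(candidates)
  ord <- order(-theta, ids)
  probs <- do.call(rbind, candidates)[ord, , drop = FALSE]
  rownames(probs) <- NULL
  if (is.null(colnames(probs))) {
    colnames(probs) <- sprintf("C%d", seq_len(ncol(probs)))
  }
  out <- data.frame(rank = seq_along(ord), id = ids[ord],
                    theta = unname(theta[ord]),
                    theta_trunc = trunc3(unname(theta[ord])),
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(probs, row.names = NULL))
}

#' Rank the predicted actives of a screening run
#'
#' Convenience wrapper chaining [compile_probabilities()] and
#' [rank_candidates()].
#'
#' @param prediction a `prediction_result`.
#' @return the [rank_candidates()] data frame.
#' @export
rank_screen <- function(prediction) {
  rank_candidates(compile_probabilities(prediction))
}
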