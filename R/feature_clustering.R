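#' Fisher score of a feature column
#'
#' Measures class separation of a single numeric feature as
#' \deqn{F = \frac{(\mu_A - \mu_I)^2}{\sigma^2_A + \sigma^2_I}}
#' with population (divide-by-n) variances computed per class
#' (A = Active, I = Inactive). A column constant across all compounds — or
#' any column with equal class means — scores 0. A perfectly separating
#' column with zero within-class variance has an infinite ratio; it is
#' capped at `cap` so score-based sorting stays total.
#'
#' @param values numeric feature column.
#' @param labels `"Active"`/`"Inactive"` labels, same length; both classes
#'   must be present.
#' @param cap finite score assigned when both class variances are zero but
#'   the means differ (default `1e6`).
#' @return non-negative numeric scalar.
#' @export
#' @examples
#' fisher_score(c(1, 1, 0, 0, 0, 0, 0, 0),
#'              rep(c("Active", "Inactive"), each = 4))  # 1
fisher_score <- function(values, labels, cap = 1e6) {
  if (length(values) != length(labels)) abort("values and labels differ in length")
  check_labels(labels, allow_unknown = FALSE)
  a <- values[labels == "Active"]
  i <- values[labels == "Inactive"]
  if (length(a) == 0 || length(i) == 0) {
    abort("both classes must be present to compute a Fisher score")
  }
  pop_var <- function(x) mean((x - mean(x))^2)
  num <- (mean(a) - mean(i))^2
  if (num == 0) return(0)
  den <- pop_var(a) + pop_var(i)
  if (den == 0) return(cap)
  min(num / den, cap)
}

#' Group feature columns into k clusters by Fisher score
#'
#' Stage one of the multiple-classifier system: every feature column is
#' scored by [fisher_score()], then, within each feature type (binary
#' bits, discrete descriptors, continuous descriptors), columns are sorted
#' by score descending and dealt round-robin into the `k` clusters. The
#' dealing pointer continues across types, so each cluster receives a
#' stratified mixture of strong and weak features of every type and no
#' cluster is left empty when `k` does not exceed the column count.
#' Score ties are broken by original column order, making the clustering
#' deterministic.
#'
#' @param table a labeled [compound_table()].
#' @param labels class labels (default: the table's own labels).
#' @param k number of feature clusters (default 3).
#' @param cap passed to [fisher_score()].
#' @return an object of class `feature_clustering`: list with `k`,
#'   `clusters` (list of column-name vectors) and `scores` (named numeric).
#' @export
cluster_features <- function(table, labels = compound_labels(table), k = 3,
                             cap = 1e6) {
  stopifnot(inherits(table, "compound_table"))
  if (!is_count(k) || k < 1) abort("k must be a positive integer")
  cols <- feature_names(table)
  if (k > length(cols)) {
    abort("k (%d) exceeds the number of feature columns (%d)", k, length(cols))
  }
  labels <- unname(labels)
  check_labels(labels, allow_unknown = FALSE)
  x <- feature_matrix(table)
  scores <- vapply(cols, function(cn) fisher_score(x[, cn], labels, cap),
                   numeric(1))

  types <- feature_types(table)
  clusters <- rep(list(character(0)), k)
  pointer <- 0L
  for (ty in c("binary", "discrete", "continuous")) {
    ty_cols <- names(types)[types == ty]
    if (length(ty_cols) == 0) next
    ord <- ty_cols[order(-scores[ty_cols], match(ty_cols, cols))]
    for (cn in ord) {
      slot <- (pointer %% k) + 1L
      clusters[[slot]] <- c(clusters[[slot]], cn)
      pointer <- pointer + 1L
    }
  }

  structure(list(k = as.integer(k), clusters = clusters, scores = scores),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, length, 1L)
  cat(sprintf("<feature_clustering> k=%d, cluster sizes: %s\n", x$k,
              paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Save / load a feature clustering as JSON
#'
#' The clustering is stored as a map `{"1": [column names], ...}` plus the
#' per-column Fisher scores, so trained models are portable across
#' sessions.
#'
#' @param clustering a [cluster_features()] result.
#' @param path JSON file path.
#' @return `path` (write) or a `feature_clustering` (read).
#' @export
write_feature_clustering <- function(clustering, path) {
  stopifnot(inherits(clustering, "feature_clustering"))
  payload <- list(
    k = clustering$k,
    clusters = stats::setNames(clustering$clusters,
                               as.character(seq_len(clustering$k))),
    scores = as.list(clustering$scores)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_clustering
#' @export
read_feature_clustering <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(k = as.integer(raw$k),
                 clusters = lapply(unname(raw$clusters), as.character),
                 scores = unlist(raw$scores)),
            class = "feature_clustering")
}
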