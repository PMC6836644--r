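#' Tanimoto similarity and distance between binary fingerprints
#'
#' \eqn{sim(a, b) = |a \wedge b| / |a \vee b|} (Jaccard index on set
#' bits); distance is `1 - similarity`. Two all-zero fingerprints are
#' defined as identical (similarity 1) — empty fingerprints can occur in
#' synthetic data and are treated as indistinguishable objects.
#'
#' @param a,b binary vectors of equal length.
#' @return numeric scalar in \[0, 1\].
#' @export
#' @examples
#' tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 0, 0))  # 0.5
tanimoto_similarity <- function(a, b) {
  if (length(a) != length(b)) {
    abort("fingerprints differ in length (%d vs %d)", length(a), length(b))
  }
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) {
    abort("fingerprints must be binary")
  }
  inter <- sum(a == 1 & b == 1)
  union <- sum(a == 1 | b == 1)
  if (union == 0) return(1)
  inter / union
}

#' @rdname tanimoto_similarity
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto_similarity(a, b)

# similarity matrix between rows of A and rows of B (both binary)
tanimoto_sim_matrix <- function(A, B) {
  inter <- A %*% t(B)
  union <- outer(rowSums(A), rowSums(B), "+") - inter
  sim <- ifelse(union == 0, 1, inter / pmax(union, 1))
  sim
}

#' Leader (sphere-exclusion) clustering under a Tanimoto distance cap
#'
#' Single-pass clustering of binary fingerprints: compounds are visited
#' in the given order; each joins the earliest existing cluster whose
#' center lies within `max_center_distance` (Tanimoto distance), or
#' becomes the center of a new cluster. A cap of 0.35 forces a within-
#' cluster similarity to the center above 0.65. The result is order-
#' sensitive by construction; pass the ranked candidate order so cluster
#' centers are the most promising compounds.
#'
#' @param fps binary matrix of fingerprints with compound ids as row
#'   names.
#' @param max_center_distance distance cap in \[0, 1\] (default 0.35).
#' @param ordering character vector of compound ids giving the visit
#'   order; must cover exactly the rows of `fps`.
#' @return list of `chem_cluster` objects (fields `center`, `members` —
#'   center included —, `threshold`).
#' @export
leader_cluster <- function(fps, max_center_distance = 0.35,
                           ordering = rownames(fps)) {
  if (!is.matrix(fps) || is.null(rownames(fps))) {
    abort("fps must be a matrix with compound ids as row names")
  }
  if (!all(fps %in% c(0, 1))) abort("fingerprints must be binary")
  if (!is.numeric(max_center_distance) || max_center_distance < 0 ||
      max_center_distance > 1) {
    abort("max_center_distance must lie in [0, 1]")
  }
  unknown <- setdiff(ordering, rownames(fps))
  if (length(unknown) > 0) {
    abort("unknown id in ordering: %s", unknown[1])
  }
  if (!setequal(ordering, rownames(fps)) ||
      length(ordering) != nrow(fps)) {
    abort("ordering must cover every fingerprint id exactly once")
  }

  centers <- character(0)
  members <- list()
  for (id in ordering) {
    v <- fps[id, , drop = FALSE]
    assigned <- FALSE
    if (length(centers) > 0) {
      d <- 1 - tanimoto_sim_matrix(v, fps[centers, , drop = FALSE])[1, ]
      hit <- which(d <= max_center_distance)
      if (length(hit) > 0) {
        members[[hit[1]]] <- c(members[[hit[1]]], id)
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centers <- c(centers, id)
      members[[length(centers)]] <- id
    }
  }

  lapply(seq_along(centers), function(i) {
    structure(list(center = centers[i], members = members[[i]],
                   threshold = max_center_distance),
              class = "chem_cluster")
  })
}

#' @export
print.chem_cluster <- function(x, ...) {
  cat(sprintf("<chem_cluster> center=%s, %d member(s), threshold=%.2f\n",
              x$center, length(x$members), x$threshold))
  invisible(x)
}

#' Pick the top-scoring representative of each chemical cluster
#'
#' From each cluster, the member with the highest global relevance
#' \eqn{\Theta} is kept and the other members are discarded; ties go to
#' the lexicographically smaller id.
#'
#' @param clusters list of `chem_cluster` objects from [leader_cluster()].
#' @param theta_by_id named numeric vector (compound id -> \eqn{\Theta}).
#' @return character vector of representative ids, one per cluster.
#' @export
select_representatives <- function(clusters, theta_by_id) {
  vapply(clusters, function(cl) {
    missing <- setdiff(cl$members, names(theta_by_id))
    if (length(missing) > 0) {
      abort("no relevance score for compound %s", missing[1])
    }
    th <- theta_by_id[cl$members]
    ids <- cl$members[th == max(th)]
    sort(ids)[1]
  }, character(1))
}

#' Diversity statistics of a selected compound set
#'
#' Two summaries of chemical diversity on Tanimoto distances:
#' the mean and standard deviation over all unordered pairs of the
#' selection (internal diversity), and the mean/sd of each selected
#' compound's distance to its nearest training-set neighbour (novelty
#' relative to the training chemistry).
#'
#' @param selected binary fingerprint matrix of the selected compounds
#'   (>= 2 rows for the pairwise statistic).
#' @param training binary fingerprint matrix of the training set; `NULL`
#'   skips the nearest-training statistic.
#' @return list with `pairwise_mean`, `pairwise_sd`, `nearest_mean`,
#'   `nearest_sd` (the latter two `NA` when `training` is `NULL`).
#' @export
diversity_stats <- function(selected, training = NULL) {
  if (!is.matrix(selected) || nrow(selected) < 2) {
    abort("selected must be a matrix with at least 2 rows")
  }
  sim <- tanimoto_sim_matrix(selected, selected)
  d <- 1 - sim[upper.tri(sim)]
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- list(pairwise_mean = mean(d), pairwise_sd = sd0(d),
              nearest_mean = NA_real_, nearest_sd = NA_real_)
  if (!is.null(training)) {
    if (!is.matrix(training) || nrow(training) == 0) {
      abort("training set is empty: nearest-training distance undefined")
    }
    dist_to_train <- 1 - apply(tanimoto_sim_matrix(selected, training), 1, max)
    out$nearest_mean <- mean(dist_to_train)
    out$nearest_sd <- stats::sd(dist_to_train)
  }
  out
}
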