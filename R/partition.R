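#' Randomly partition compounds into evenly sized groups
#'
#' Splits the rows of a compound table into `n_groups` disjoint groups
#' whose sizes differ by at most one. With `stratify = TRUE` (default) the
#' shuffle is performed within each class, so per-group class counts stay
#' within one compound of proportionality — the "homogeneous and evenly
#' sized" split used to separate feature-clustering, model-building and
#' held-out test data.
#'
#' @param table a [compound_table()].
#' @param n_groups number of groups (default 4).
#' @param seed integer seed; the assignment is deterministic given the
#'   seed and the table.
#' @param stratify shuffle within class labels (ignored when all labels
#'   are `Unknown`).
#' @return an object of class `group_assignment`: a list with `groups`
#'   (integer group index named by compound id), `n_groups`, `seed`,
#'   `stratify`.
#' @export
#' @examples
#' tab <- generate_dataset(synthetic_spec(n_active = 6, n_inactive = 6,
#'                                        n_bits = 8, seed = 1))$table
#' pa <- partition_rows(tab, n_groups = 4, seed = 42)
#' table(pa$groups)
partition_rows <- function(table, n_groups = 4, seed, stratify = TRUE) {
  stopifnot(inherits(table, "compound_table"))
  if (!is_count(n_groups) || n_groups < 1) {
    abort("n_groups must be a positive integer")
  }
  n <- n_compounds(table)
  if (n_groups > n) abort("n_groups (%d) exceeds number of records (%d)", n_groups, n)
  if (missing(seed) || !is_count(seed)) abort("an integer seed is required")

  labels <- table$labels
  use_strata <- isTRUE(stratify) && length(unique(labels)) > 1

  order_ids <- with_seed(seed, {
    if (use_strata) {
      # shuffle within class, then concatenate classes in a fixed order;
      # the round-robin pointer runs across class blocks so overall group
      # sizes still differ by at most one
      unlist(lapply(sort(unique(labels)), function(cl) {
        ids <- table$ids[labels == cl]
        sample(ids, length(ids))
      }), use.names = FALSE)
    } else {
      sample(table$ids, n)
    }
  })
  grp <- ((seq_len(n) - 1L) %% n_groups) + 1L
  groups <- stats::setNames(grp[match(table$ids, order_ids)], table$ids)

  structure(list(groups = groups, n_groups = as.integer(n_groups),
                 seed = as.integer(seed), stratify = isTRUE(stratify)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %d ids in %d groups (seed %d%s)\n",
              length(x$groups), x$n_groups, x$seed,
              if (x$stratify) ", stratified" else ""))
  print(table(group = x$groups))
  invisible(x)
}

#' Compound ids belonging to given groups
#'
#' @param assignment a [partition_rows()] result.
#' @param groups integer vector of group indices.
#' @return character vector of compound ids.
#' @export
group_ids <- function(assignment, groups) {
  stopifnot(inherits(assignment, "group_assignment"))
  bad <- setdiff(groups, seq_len(assignment$n_groups))
  if (length(bad) > 0) abort("unknown group index: %s", paste(bad, collapse = ", "))
  names(assignment$groups)[assignment$groups %in% groups]
}
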