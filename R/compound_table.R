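#' Compound feature tables
#'
#' A `compound_table` is the universal currency of the screening pipeline:
#' one row per compound, identified by a unique key (an InChIKey for real
#' data, any unique string for synthetic data), with three blocks of
#' feature columns:
#'
#' * `bits` — fixed-length binary substructure fingerprints (e.g. 2048
#'   FCFP_6-style circular-fingerprint bits), values strictly 0/1;
#' * `descriptors` — physicochemical descriptors, each column tagged
#'   `"discrete"` or `"continuous"`;
#' * `labels` — an activity class per compound, one of `"Active"`,
#'   `"Inactive"` or `"Unknown"` (unlabeled screening libraries).
#'
#' @param ids character vector of unique, non-empty compound identifiers.
#' @param bits integer/numeric matrix of 0/1 fingerprint bits, one row per
#'   compound. Column names are kept; unnamed columns are named `B0001`,
#'   `B0002`, ...
#' @param descriptors optional numeric matrix of descriptors (no missing
#'   values). Unnamed columns are named `D0001`, ...
#' @param descriptor_types character vector, one of `"discrete"` or
#'   `"continuous"` per descriptor column.
#' @param labels optional character vector of class labels; `NULL` means
#'   all `"Unknown"`.
#' @return an object of class `compound_table`.
#' @seealso [read_compound_table()], [write_compound_table()],
#'   [partition_rows()], [feature_matrix()]
#' @export
#' @examples
#' tab <- compound_table(
#'   ids = c("A", "B"),
#'   bits = matrix(c(1, 0, 0, 1), 2, 2),
#'   descriptors = matrix(c(3, 5, 0.1, 0.9), 2, 2),
#'   descriptor_types = c("discrete", "continuous"),
#'   labels = c("Active", "Inactive")
#' )
#' n_compounds(tab)
compound_table <- function(ids, bits, descriptors = NULL,
                           descriptor_types = NULL, labels = NULL) {
  ids <- as.character(ids)
  if (length(ids) == 0 && is.null(dim(bits))) bits <- matrix(0L, 0, 0)
  if (!is.matrix(bits)) bits <- as.matrix(bits)
  n <- length(ids)
  if (any(!nzchar(ids)) || anyNA(ids)) abort("compound ids must be non-empty")
  if (anyDuplicated(ids)) {
    abort("duplicate compound id: %s", ids[duplicated(ids)][1])
  }
  if (nrow(bits) != n) abort("bits must have one row per compound")
  storage.mode(bits) <- "integer"
  if (length(bits) > 0 && !all(bits %in% c(0L, 1L))) {
    bad <- which(!(bits %in% c(0L, 1L)) | is.na(bits), arr.ind = FALSE)[1]
    rc <- arrayInd(bad, dim(bits))
    abort("non-binary fingerprint value at row %d, column %d", rc[1], rc[2])
  }
  if (is.null(colnames(bits)) && ncol(bits) > 0) {
    colnames(bits) <- sprintf("B%04d", seq_len(ncol(bits)))
  }

  if (!is.null(descriptors)) {
    if (!is.matrix(descriptors)) descriptors <- as.matrix(descriptors)
    storage.mode(descriptors) <- "double"
    if (nrow(descriptors) != n) {
      abort("descriptors must have one row per compound")
    }
    if (anyNA(descriptors)) {
      bad <- which(is.na(descriptors))[1]
      rc <- arrayInd(bad, dim(descriptors))
      abort("missing descriptor value at row %d, column %d (missing values are not supported)",
            rc[1], rc[2])
    }
    if (is.null(colnames(descriptors)) && ncol(descriptors) > 0) {
      colnames(descriptors) <- sprintf("D%04d", seq_len(ncol(descriptors)))
    }
    if (is.null(descriptor_types) ||
        length(descriptor_types) != ncol(descriptors)) {
      abort("descriptor_types must give one type per descriptor column")
    }
    bad_t <- setdiff(unique(descriptor_types), c("discrete", "continuous"))
    if (length(bad_t) > 0) {
      abort("invalid descriptor type(s): %s", paste(bad_t, collapse = ", "))
    }
  } else {
    descriptors <- matrix(numeric(0), n, 0)
    descriptor_types <- character(0)
  }
  if (anyDuplicated(c(colnames(bits), colnames(descriptors)))) {
    abort("feature column names must be unique across bits and descriptors")
  }

  if (is.null(labels)) labels <- rep("Unknown", n)
  labels <- as.character(labels)
  if (length(labels) != n) abort("labels must have one value per compound")
  check_labels(labels)

  structure(
    list(ids = ids, bits = bits, descriptors = descriptors,
         descriptor_types = stats::setNames(descriptor_types,
                                            colnames(descriptors)),
         labels = labels),
    class = "compound_table"
  )
}

#' @export
print.compound_table <- function(x, ...) {
  cat(sprintf("<compound_table> %d compounds, %d bits, %d descriptors (%d discrete, %d continuous)\n",
              n_compounds(x), ncol(x$bits), ncol(x$descriptors),
              sum(x$descriptor_types == "discrete"),
              sum(x$descriptor_types == "continuous")))
  cat("labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                               as.integer(table(x$labels))), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of compounds in a table
#' @param table a [compound_table()].
#' @return integer count of rows.
#' @export
n_compounds <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  length(table$ids)
}

#' Feature column names and types
#'
#' `feature_names()` returns all feature column names (bits first, then
#' descriptors); `feature_types()` returns a named vector with entries
#' `"binary"`, `"discrete"` or `"continuous"`.
#'
#' @param table a [compound_table()].
#' @return character vector (named, for `feature_types`).
#' @export
feature_names <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  c(colnames(table$bits), colnames(table$descriptors))
}

#' @rdname feature_names
#' @export
feature_types <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  c(stats::setNames(rep("binary", ncol(table$bits)), colnames(table$bits)),
    table$descriptor_types)
}

#' Extract a numeric feature matrix
#'
#' @param table a [compound_table()].
#' @param columns character vector of feature columns to extract, in order;
#'   `NULL` means all features (bits then descriptors).
#' @return numeric matrix with compound ids as row names.
#' @export
feature_matrix <- function(table, columns = NULL) {
  stopifnot(inherits(table, "compound_table"))
  full <- cbind(table$bits + 0, table$descriptors)
  rownames(full) <- table$ids
  if (is.null(columns)) return(full)
  missing <- setdiff(columns, colnames(full))
  if (length(missing) > 0) {
    abort("unknown feature column(s): %s", paste(missing, collapse = ", "))
  }
  full[, columns, drop = FALSE]
}

#' Compound class labels
#' @param table a [compound_table()].
#' @return character vector named by compound id.
#' @export
compound_labels <- function(table) {
  stopifnot(inherits(table, "compound_table"))
  stats::setNames(table$labels, table$ids)
}

#' Row subset of a compound table
#' @param table a [compound_table()].
#' @param idx integer, logical, or character (id) index.
#' @return a [compound_table()] with the selected rows.
#' @export
subset_rows <- function(table, idx) {
  stopifnot(inherits(table, "compound_table"))
  if (is.character(idx)) {
    pos <- match(idx, table$ids)
    if (anyNA(pos)) abort("unknown compound id: %s", idx[is.na(pos)][1])
    idx <- pos
  }
  compound_table(table$ids[idx], table$bits[idx, , drop = FALSE],
                 table$descriptors[idx, , drop = FALSE],
                 unname(table$descriptor_types),
                 table$labels[idx])
}
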