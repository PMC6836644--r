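#' Column schema for tab-delimited compound tables
#'
#' Describes how the columns of a TSV file map onto a [compound_table()]:
#' which column holds the id, which are fingerprint bits, which are
#' discrete/continuous descriptors and (optionally) which holds the class.
#'
#' @param id name of the identifier column.
#' @param bits character vector of fingerprint-bit column names.
#' @param discrete,continuous character vectors of descriptor column names.
#' @param class name of the activity-class column, or `NULL` if the file is
#'   unlabeled.
#' @return an object of class `table_schema`.
#' @export
table_schema <- function(id = "id", bits = character(),
                         discrete = character(), continuous = character(),
                         class = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  all_cols <- c(bits, discrete, continuous)
  if (anyDuplicated(c(id, all_cols, class))) {
    abort("schema column names must be unique")
  }
  structure(list(id = id, bits = as.character(bits),
                 discrete = as.character(discrete),
                 continuous = as.character(continuous),
                 class = class),
            class = "table_schema")
}

schema_sidecar_path <- function(path) paste0(path, ".schema.json")

write_schema <- function(schema, path) {
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  table_schema(id = raw$id, bits = raw$bits %||% character(),
               discrete = raw$discrete %||% character(),
               continuous = raw$continuous %||% character(),
               class = raw$class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a tab-delimited compound table
#'
#' Parses a UTF-8, tab-separated file with a header row into a
#' [compound_table()]. The column layout is given by a [table_schema()];
#' when `schema` is `NULL` the sidecar file `<path>.schema.json` written by
#' [write_compound_table()] is used. Class values must be the strings
#' `"Active"`/`"Inactive"`; a file without a class column yields
#' `"Unknown"` labels throughout.
#'
#' @param path file path.
#' @param schema a [table_schema()] or `NULL` to use the sidecar file.
#' @return a [compound_table()].
#' @export
read_compound_table <- function(path, schema = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  if (is.null(schema)) {
    side <- schema_sidecar_path(path)
    if (!file.exists(side)) {
      abort("no schema given and no sidecar schema file found at %s", side)
    }
    schema <- read_schema(side)
  }
  stopifnot(inherits(schema, "table_schema"))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          data.table = TRUE, showProgress = FALSE)
  need <- c(schema$id, schema$bits, schema$discrete, schema$continuous)
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0) {
    abort("file is missing schema column(s): %s", paste(missing, collapse = ", "))
  }
  ids <- dt[[schema$id]]
  if (anyDuplicated(ids)) {
    abort("duplicate compound id: %s", ids[duplicated(ids)][1])
  }

  n <- nrow(dt)
  bits <- matrix(0L, n, length(schema$bits),
                 dimnames = list(NULL, schema$bits))
  for (j in seq_along(schema$bits)) {
    v <- dt[[schema$bits[j]]]
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad) > 0) {
      abort("non-binary value '%s' in bit column '%s', row %d",
            v[bad[1]], schema$bits[j], bad[1])
    }
    bits[, j] <- as.integer(v)
  }

  desc_cols <- c(schema$discrete, schema$continuous)
  desc <- matrix(NA_real_, n, length(desc_cols),
                 dimnames = list(NULL, desc_cols))
  for (j in seq_along(desc_cols)) {
    v <- suppressWarnings(as.numeric(dt[[desc_cols[j]]]))
    bad <- which(is.na(v) | !nzchar(dt[[desc_cols[j]]]))
    if (length(bad) > 0) {
      abort("missing or non-numeric descriptor value in column '%s', row %d",
            desc_cols[j], bad[1])
    }
    desc[, j] <- v
  }
  types <- c(rep("discrete", length(schema$discrete)),
             rep("continuous", length(schema$continuous)))

  labels <- NULL
  if (!is.null(schema$class) && schema$class %in% names(dt)) {
    labels <- dt[[schema$class]]
    labels[!nzchar(labels)] <- "Unknown"
    check_labels(labels, what = "class")
  }

  compound_table(ids, bits,
                 if (length(desc_cols) > 0) desc else NULL,
                 if (length(desc_cols) > 0) types else NULL,
                 labels)
}

#' Write a compound table to a tab-delimited file
#'
#' Emits UTF-8, tab-separated text with a header row and a "." decimal
#' separator, plus a JSON sidecar (`<path>.schema.json`) recording the
#' column schema, so [read_compound_table()] round-trips the table exactly
#' (values and column order).
#'
#' @param table a [compound_table()].
#' @param path output file path.
#' @param write_class `"auto"` (class column present iff any label is not
#'   `"Unknown"`), `TRUE` (always; `Unknown` written as empty string) or
#'   `FALSE` (class column omitted).
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path, write_class = "auto") {
  stopifnot(inherits(table, "compound_table"))
  include_class <- if (identical(write_class, "auto")) {
    any(table$labels != "Unknown")
  } else {
    isTRUE(write_class)
  }

  cols <- list(table$ids)
  header <- "id"
  if (ncol(table$bits) > 0) {
    for (j in seq_len(ncol(table$bits))) cols <- c(cols, list(as.character(table$bits[, j])))
    header <- c(header, colnames(table$bits))
  }
  if (ncol(table$descriptors) > 0) {
    for (j in seq_len(ncol(table$descriptors))) {
      cols <- c(cols, list(fmt_num(table$descriptors[, j])))
    }
    header <- c(header, colnames(table$descriptors))
  }
  if (include_class) {
    lab <- table$labels
    lab[lab == "Unknown"] <- ""
    cols <- c(cols, list(lab))
    header <- c(header, "class")
  }

  lines <- c(paste(header, collapse = "\t"),
             if (n_compounds(table) > 0) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)

  types <- feature_types(table)
  schema <- table_schema(
    id = "id",
    bits = colnames(table$bits),
    discrete = names(types)[types == "discrete"],
    continuous = names(types)[types == "continuous"],
    class = if (include_class) "class" else NULL
  )
  write_schema(schema, schema_sidecar_path(path))
  invisible(path)
}
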