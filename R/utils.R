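# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so library functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Truncate toward zero at three decimals
#'
#' Reporting helper used for global-relevance values: 0.3375 renders as
#' 0.337 (truncation, not rounding).
#'
#' @param x numeric vector.
#' @return numeric vector truncated toward zero at the third decimal.
#' @export
#' @examples
#' trunc3(0.3375)   # 0.337
#' trunc3(-0.3375)  # -0.337
trunc3 <- function(x) {
  stopifnot(is.numeric(x))
  trunc(x * 1000) / 1000
}

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

# canonical label set
LABELS <- c("Active", "Inactive", "Unknown")

check_labels <- function(labels, allow_unknown = TRUE, what = "label") {
  ok <- if (allow_unknown) LABELS else LABELS[1:2]
  bad <- setdiff(unique(labels), ok)
  if (length(bad) > 0) {
    abort("invalid %s value(s): %s (allowed: %s)", what,
          paste(bad, collapse = ", "), paste(ok, collapse = ", "))
  }
  invisible(labels)
}

fmt_num <- function(x) {
  # full-precision decimal rendering so TSV round-trips are exact
  out <- sprintf("%.17g", x)
  ok <- as.numeric(out) == x
  if (!all(ok)) out[!ok] <- sprintf("%.17e", x[!ok])
  out
}
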