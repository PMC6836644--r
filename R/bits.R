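#' Select fingerprint bits by occurrence frequency
#'
#' Ranks binary columns by how close their occurrence frequency (column
#' mean) lies to a target frequency and returns the closest
#' `target_count` column indices. The default target of 0.5 avoids both
#' significant under- and over-representation of a substructure: a bit set
#' in about half the compounds carries the most discriminating power.
#' Ties in closeness are broken by ascending column index.
#'
#' @param bit_matrix binary matrix (compounds in rows, candidate bits in
#'   columns).
#' @param target_count number of columns to keep.
#' @param target_frequency target occurrence frequency in \[0, 1\].
#' @return integer vector of column indices, ordered by closeness to the
#'   target and then by column index.
#' @export
#' @examples
#' m <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0), c = c(1, 1, 1, 1))
#' select_bits_by_frequency(m, 2)  # columns a (0.5) then b (0.25)
select_bits_by_frequency <- function(bit_matrix, target_count,
                                     target_frequency = 0.5) {
  if (!is.matrix(bit_matrix) || length(bit_matrix) == 0) {
    abort("bit_matrix must be a non-empty matrix")
  }
  if (!all(bit_matrix %in% c(0, 1))) abort("bit_matrix must be binary")
  if (!is_count(target_count) || target_count < 1) {
    abort("target_count must be a positive integer")
  }
  if (target_count > ncol(bit_matrix)) {
    abort("target_count (%d) exceeds the number of candidate columns (%d)",
          target_count, ncol(bit_matrix))
  }
  if (!is.numeric(target_frequency) || target_frequency < 0 ||
      target_frequency > 1) {
    abort("target_frequency must lie in [0, 1]")
  }
  freq <- colMeans(bit_matrix)
  ord <- order(abs(freq - target_frequency), seq_along(freq))
  ord[seq_len(target_count)]
}
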