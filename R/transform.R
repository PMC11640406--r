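#' Rank the 12 leads of one sample by descending amplitude
#'
#' The elementary step of the lead transformer: given the 12 lead
#' amplitudes at a single sample, return the lead indexes sorted from
#' largest to smallest amplitude. Ties are broken deterministically in
#' favour of the lower lead index (a stable descending sort), so an
#' all-equal block maps to `1:12`.
#'
#' @param block Numeric vector of 12 finite lead amplitudes (mV).
#' @return Integer permutation of `1:12`.
#' @export
#' @examples
#' rank_block(c(12:1))   # already descending -> 1..12
#' rank_block(rep(0, 12))  # all tied -> 1..12 by the tie rule
rank_block <- function(block) {
  if (length(block) != N_LEADS) {
    abort("A lead block must contain exactly 12 amplitudes.",
          class = "cardioish_dimension_error")
  }
  if (!all(is.finite(block))) {
    abort("Lead amplitudes must be finite.", class = "cardioish_data_error")
  }
  # radix sort is stable, so equal amplitudes keep lead-index order
  order(-block, method = "radix")
}

#' Transform a beat into its lead-index sequence
#'
#' Applies [rank_block()] to every sample of a 12 x L beat and
#' concatenates the resulting permutations, yielding an integer sequence
#' of length `12 * L` in which each aligned 12-block records which leads
#' carried the largest down to the smallest amplitude at that sample. The
#' encoding is invariant to any positive rescaling of the whole beat and
#' to any per-sample constant added to all leads: only the amplitude
#' *ranking* survives.
#'
#' @param beat Numeric 12 x L matrix (rows = leads, columns = samples).
#' @return Integer vector of length `12 * L` with values in 1..12.
#' @export
transform_beat <- function(beat) {
  if (!is.matrix(beat) || nrow(beat) != N_LEADS) {
    abort("A beat must be a 12 x L numeric matrix.",
          class = "cardioish_dimension_error")
  }
  if (ncol(beat) < 1L) {
    abort("A beat needs at least one sample.", class = "cardioish_dimension_error")
  }
  if (!all(is.finite(beat))) {
    abort("Beat amplitudes must be finite.", class = "cardioish_data_error")
  }
  as.integer(apply(beat, 2L, function(col) order(-col, method = "radix")))
}
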