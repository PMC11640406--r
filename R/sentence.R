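#' Decode a feature index into its (from, to) lead pair
#'
#' Feature `u` of the 144-vector is transition cell `[k, l]` of the 12x12
#' table under row-major flattening, so `u` decodes to
#' `from = ceiling(u / 12)` and `to = ((u - 1) %% 12) + 1` -- the exact
#' inverse of [flatten_features()].
#'
#' @param u Feature index in 1..144.
#' @return Integer vector `c(from, to)` of symbol indexes in 1..12.
#' @export
#' @examples
#' feature_symbol_pair(1)    # (1, 1): Ld1 -> Ld1
#' feature_symbol_pair(24)   # (2, 12): Ld2 -> V6L
feature_symbol_pair <- function(u) {
  u <- as.integer(u)
  if (length(u) != 1L || is.na(u) || u < 1L || u > N_FEATURES) {
    abort("Feature index must be a single integer in 1..144.",
          class = "cardioish_index_error")
  }
  c(from = ((u - 1L) %/% N_LEADS) + 1L, to = ((u - 1L) %% N_LEADS) + 1L)
}

#' Build a Cardioish sentence from selected feature indexes
#'
#' Each selected feature decodes into its (from-lead, to-lead) symbol
#' pair; concatenating the pairs in selection-ranking order gives the
#' sentence, a symbol sequence of length `2 * nosf` for `nosf` selected
#' features.
#'
#' @param sel_indexes Integer vector of feature indexes in 1..144 (e.g.
#'   `$sel_indexes` of a [inca()] result), in ranking order.
#' @return Object of class `cardioish_sentence`: list with `tokens`
#'   (character), `sind` (parallel symbol indexes 1..12) and `nosf`.
#' @export
#' @examples
#' build_sentence(c(24, 1))  # "Ld2V6LLd1Ld1"
build_sentence <- function(sel_indexes) {
  sel_indexes <- as.integer(sel_indexes)
  if (length(sel_indexes) == 0L) {
    warn("Empty selection: building a zero-length sentence.")
    return(new_sentence(character(0), integer(0)))
  }
  if (anyNA(sel_indexes) || any(sel_indexes < 1L) || any(sel_indexes > N_FEATURES)) {
    abort("Selected feature indexes must lie in 1..144.",
          class = "cardioish_index_error")
  }
  pairs <- vapply(sel_indexes, feature_symbol_pair, integer(2))
  sind <- as.integer(pairs)   # interleaves from/to per feature
  new_sentence(cardioish_alphabet()[sind], sind)
}

new_sentence <- function(tokens, sind) {
  structure(list(tokens = tokens, sind = sind, nosf = length(tokens) %/% 2L),
            class = "cardioish_sentence")
}

#' @export
print.cardioish_sentence <- function(x, ...) {
  cat(sprintf("<cardioish_sentence> %d tokens (%d features)\n",
              length(x$tokens), x$nosf))
  cat(strwrap(format(x), width = 72), sep = "\n")
  invisible(x)
}

#' @export
format.cardioish_sentence <- function(x, ...) {
  paste(x$tokens, collapse = "")
}

#' Tokenize a rendered Cardioish sentence
#'
#' Splits a concatenated sentence string back into its 3-character
#' symbols, validating every chunk against the alphabet.
#'
#' @param text A string whose length is a multiple of 3.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize_sentence("AVLV1SV2S")
tokenize_sentence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  n <- nchar(text)
  if (n %% 3L != 0L) {
    abort("Sentence length must be a multiple of 3 characters.",
          class = "cardioish_parse_error")
  }
  if (n == 0L) return(character(0))
  starts <- seq(1L, n, by = 3L)
  tokens <- substring(text, starts, starts + 2L)
  bad <- which(!tokens %in% cardioish_alphabet())
  if (length(bad) > 0L) {
    abort(sprintf("Unknown symbol '%s' at character %d.",
                  tokens[bad[1]], starts[bad[1]]),
          class = "cardioish_parse_error")
  }
  tokens
}

#' Symbol frequency distribution and Shannon entropy of a sentence
#'
#' Counts each of the 12 symbols in a token sequence, converts counts to
#' probabilities and computes the base-2 Shannon entropy
#' \eqn{H = -\sum_{p > 0} p \log_2 p}, bounded above by
#' \eqn{\log_2 12 \approx 3.5850} bits.
#'
#' @param tokens Character vector of alphabet symbols, or a
#'   `cardioish_sentence`.
#' @return Object of class `cardioish_distribution`: tibble with columns
#'   `symbol`, `count`, `probability`, and attribute `entropy_bits`
#'   (also exposed via [glance()]).
#' @export
#' @examples
#' d <- symbol_distribution(tokenize_sentence("AVLV1SV2SAVL"))
#' attr(d, "entropy_bits")
symbol_distribution <- function(tokens) {
  if (inherits(tokens, "cardioish_sentence")) tokens <- tokens$tokens
  if (length(tokens) == 0L) {
    abort("Cannot form a distribution from an empty token list.",
          class = "cardioish_data_error")
  }
  alpha <- cardioish_alphabet()
  bad <- setdiff(unique(tokens), alpha)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown symbol '%s'.", bad[1]), class = "cardioish_parse_error")
  }
  counts <- as.integer(table(factor(tokens, levels = alpha)))
  out <- tibble::tibble(symbol = alpha, count = counts,
                        probability = counts / sum(counts))
  attr(out, "entropy_bits") <- shannon_entropy(counts)
  class(out) <- c("cardioish_distribution", class(out))
  out
}

#' Shannon entropy (bits) of a count vector
#'
#' @param counts Non-negative counts.
#' @return Entropy in bits; zero counts contribute nothing.
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' @export
glance.cardioish_distribution <- function(x, ...) {
  tibble::tibble(
    n_tokens = sum(x$count),
    entropy_bits = attr(x, "entropy_bits"),
    max_entropy_bits = log2(N_LEADS)
  )
}

#' @export
autoplot.cardioish_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$symbol <- factor(df$symbol, levels = cardioish_alphabet())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$symbol, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("Symbol frequencies (entropy %.4f bits)",
                                  attr(object, "entropy_bits")))
}

#' Transition table of consecutive sentence symbols
#'
#' Counts all consecutive token pairs of a sentence, spanning the
#' boundaries between feature pairs, into a 12x12 table over the
#' alphabet. The total count is always one less than the token count.
#'
#' @param tokens Character token vector or a `cardioish_sentence`.
#' @return 12 x 12 integer matrix with symbol dimnames.
#' @export
sentence_transition_table <- function(tokens) {
  if (inherits(tokens, "cardioish_sentence")) tokens <- tokens$tokens
  alpha <- cardioish_alphabet()
  tab <- matrix(0L, N_LEADS, N_LEADS, dimnames = list(from = alpha, to = alpha))
  if (length(tokens) < 2L) {
    warn("Fewer than two tokens: returning an empty transition table.")
    return(tab)
  }
  ids <- match(tokens, alpha)
  if (anyNA(ids)) {
    abort("Sentence contains symbols outside the alphabet.",
          class = "cardioish_parse_error")
  }
  counts <- count_transitions_generic(ids, length(tokens))
  tab[] <- counts
  tab
}

# pair-count helper shared with count_transitions' layout (row-major cells)
count_transitions_generic <- function(ids, n) {
  cell <- (ids[-n] - 1L) * N_LEADS + ids[-1L]
  matrix(tabulate(cell, nbins = N_FEATURES), nrow = N_LEADS, byrow = TRUE)
}
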