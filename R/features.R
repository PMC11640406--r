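#' Count lead-index transitions in a transformed signal
#'
#' Tallies how often lead index `a` is immediately followed by lead index
#' `b` along the full lead-index sequence of one beat, including the
#' positions where one sample's 12-block meets the next (the only places a
#' diagonal cell can be hit, since a permutation never repeats a value
#' within a block). For a beat of length L the counts always sum to
#' `12 * L - 1`.
#'
#' @param tr Integer vector, values in 1..12 (see [transform_beat()]).
#' @return 12 x 12 integer matrix of transition counts; `[a, b]` counts
#'   transitions from lead `a` to lead `b`.
#' @export
count_transitions <- function(tr) {
  tr <- as.integer(tr)
  if (length(tr) < 2L) {
    abort("A transformed signal needs at least two entries.",
          class = "cardioish_data_error")
  }
  if (anyNA(tr) || any(tr < 1L) || any(tr > N_LEADS)) {
    abort("Transformed-signal values must lie in 1..12.",
          class = "cardioish_data_error")
  }
  n <- length(tr)
  cell <- (tr[-n] - 1L) * N_LEADS + tr[-1L]   # row-major cell index
  counts <- tabulate(cell, nbins = N_FEATURES)
  matrix(counts, nrow = N_LEADS, byrow = TRUE)
}

#' Row-normalise a transition matrix
#'
#' Divides each row by its sum plus a small `epsilon`, turning counts into
#' (slightly deflated) empirical transition probabilities. Rows with no
#' counts stay all-zero instead of producing NaNs.
#'
#' @param mat 12 x 12 non-negative count matrix.
#' @param epsilon Positive stabiliser added to each row sum (default
#'   `1e-10`, invisible at realistic beat lengths).
#' @return 12 x 12 numeric matrix with entries in `[0, 1)`.
#' @export
normalize_rows <- function(mat, epsilon = 1e-10) {
  stopifnot(is.matrix(mat), all(dim(mat) == N_LEADS))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    abort("`epsilon` must be a positive scalar.", class = "cardioish_config_error")
  }
  if (any(mat < 0)) {
    abort("Transition counts must be non-negative.", class = "cardioish_data_error")
  }
  mat / (rowSums(mat) + epsilon)
}

#' Flatten a normalised transition matrix to the 144-feature vector
#'
#' Row-major flattening: feature `u = (k - 1) * 12 + l` is cell `[k, l]`,
#' i.e. the (from-lead `k`, to-lead `l`) transition probability. This
#' ordering is the exact inverse of [feature_symbol_pair()], which decodes
#' a feature index back into its lead pair.
#'
#' @param matn 12 x 12 numeric matrix.
#' @return Numeric vector of length 144.
#' @seealso [unflatten_features()] for the inverse.
#' @export
flatten_features <- function(matn) {
  stopifnot(is.matrix(matn), all(dim(matn) == N_LEADS))
  as.vector(t(matn))
}

#' @rdname flatten_features
#' @param fv Numeric vector of length 144.
#' @export
unflatten_features <- function(fv) {
  if (length(fv) != N_FEATURES) {
    abort("A feature vector must have exactly 144 entries.",
          class = "cardioish_dimension_error")
  }
  matrix(fv, nrow = N_LEADS, byrow = TRUE)
}

#' Extract the 144 transition features from every beat
#'
#' Runs the full feature-extraction phase per beat: rank encoding
#' ([transform_beat()]), transition counting ([count_transitions()]),
#' row normalisation ([normalize_rows()]) and row-major flattening
#' ([flatten_features()]).
#'
#' @param beats A beat-set tibble (see [generate_beatset()]).
#' @param epsilon Row-normalisation stabiliser, see [normalize_rows()].
#' @return Tibble with columns `beat_id`, `label` and `f001`..`f144`.
#' @export
#' @examples
#' beats <- generate_beatset(separable_profiles(2, noise_sd = 0),
#'                           n_per_class = 2, rng_seed = 1)
#' extract_features(beats)
extract_features <- function(beats, epsilon = 1e-10) {
  validate_beatset(beats)
  rows <- purrr::map(beats$signal, function(s) {
    flatten_features(normalize_rows(count_transitions(transform_beat(s)),
                                    epsilon = epsilon))
  })
  X <- do.call(rbind, rows)
  colnames(X) <- feature_names()
  dplyr::bind_cols(
    tibble::tibble(beat_id = beats$beat_id, label = as.integer(beats$label)),
    tibble::as_tibble(X)
  )
}

#' Feature column names `f001`..`f144`
#' @return Character vector of length 144.
#' @export
feature_names <- function() {
  sprintf("f%03d", seq_len(N_FEATURES))
}

# split a feature tibble into the numeric matrix X and integer labels y
feature_matrix <- function(features) {
  fn <- feature_names()
  missing <- setdiff(fn, names(features))
  if (length(missing) > 0L) {
    abort(paste0("Feature table is missing columns: ", missing[1], " ..."),
          class = "cardioish_format_error")
  }
  X <- as.matrix(features[, fn])
  y <- if ("label" %in% names(features)) as.integer(features$label) else NULL
  list(X = X, y = y)
}
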