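#' Synthetic beat template
#'
#' A single-beat waveform model: the sum of five Gaussian bumps standing in
#' for the P, Q, R, S and T waves of one cardiac cycle. Amplitudes are in
#' millivolts and positions/widths in samples. The default parameters give
#' a visually plausible 651-sample beat (positive P, R, T; negative Q, S)
#' whose lead-amplitude rankings fluctuate over the cycle the way real
#' multi-lead beats do.
#'
#' @param wave_centers Numeric length 5, strictly increasing sample
#'   positions of the P, Q, R, S, T wave peaks, each in `[0, length)`. The
#'   default places them at fixed fractions of the beat (20%, 44.5%, 50%,
#'   55.3%, 80%), i.e. samples 130, 290, 325, 360, 520 at the default
#'   length.
#' @param wave_widths Numeric length 5, positive Gaussian widths
#'   (samples); the default scales with the beat length (25, 8, 12, 8, 40
#'   samples at the default length).
#' @param wave_amplitudes Numeric length 5, wave amplitudes (mV).
#' @param length Beat length in samples (default 651).
#' @return An object of class `beat_template`.
#' @export
#' @examples
#' tpl <- beat_template()
#' plot(template_waveform(tpl), type = "l", ylab = "mV")
beat_template <- function(wave_centers = NULL,
                          wave_widths = NULL,
                          wave_amplitudes = c(0.15, -0.12, 1.2, -0.25, 0.35),
                          length = 651L) {
  length <- as.integer(length)
  wave_centers <- wave_centers %||%
    (length * c(0.1997, 0.4455, 0.4993, 0.5530, 0.7988))
  wave_widths <- wave_widths %||%
    (length * c(25, 8, 12, 8, 40) / 651)
  stopifnot(length(wave_centers) == 5L, length(wave_widths) == 5L,
            length(wave_amplitudes) == 5L)
  if (length < N_LEADS) {
    abort("`length` must be at least 12 samples.", class = "cardioish_dimension_error")
  }
  if (any(wave_widths <= 0)) {
    abort("`wave_widths` must all be positive.", class = "cardioish_config_error")
  }
  if (any(diff(wave_centers) <= 0)) {
    abort("`wave_centers` must be strictly increasing.", class = "cardioish_config_error")
  }
  if (any(wave_centers < 0) || any(wave_centers >= length)) {
    abort("`wave_centers` must lie in [0, length).", class = "cardioish_config_error")
  }
  structure(
    list(wave_centers = as.numeric(wave_centers),
         wave_widths = as.numeric(wave_widths),
         wave_amplitudes = as.numeric(wave_amplitudes),
         length = length),
    class = "beat_template"
  )
}

#' Evaluate a beat template's noise-free waveform
#'
#' @param template A [beat_template()].
#' @return Numeric vector of `template$length` amplitudes (mV), the sum of
#'   the five Gaussian waves at samples `0:(length - 1)`.
#' @export
template_waveform <- function(template) {
  stopifnot(inherits(template, "beat_template"))
  t <- seq_len(template$length) - 1
  w <- numeric(template$length)
  for (j in 1:5) {
    w <- w + template$wave_amplitudes[j] *
      exp(-(t - template$wave_centers[j])^2 / (2 * template$wave_widths[j]^2))
  }
  w
}

#' Per-class lead profile
#'
#' Controls how one class reshapes the template across the 12 leads: each
#' lead gets the template waveform scaled by a multiplicative gain, shifted
#' by an additive offset, plus i.i.d. Gaussian amplitude noise. Gains are
#' the lever that sets the per-sample lead-amplitude ranking, which is the
#' only thing the downstream rank encoding sees.
#'
#' @param lead_gains Numeric length 12, positive multiplicative scales.
#' @param lead_offsets Numeric length 12, additive offsets (mV).
#' @param noise_sd Non-negative Gaussian noise standard deviation (mV).
#' @return An object of class `class_profile`.
#' @export
class_profile <- function(lead_gains,
                          lead_offsets = rep(0, N_LEADS),
                          noise_sd = 0) {
  if (length(lead_gains) != N_LEADS || length(lead_offsets) != N_LEADS) {
    abort("`lead_gains` and `lead_offsets` must each have 12 entries.",
          class = "cardioish_dimension_error")
  }
  if (any(lead_gains <= 0)) {
    abort("`lead_gains` must be positive.", class = "cardioish_config_error")
  }
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.", class = "cardioish_config_error")
  }
  structure(
    list(lead_gains = as.numeric(lead_gains),
         lead_offsets = as.numeric(lead_offsets),
         noise_sd = as.numeric(noise_sd)),
    class = "class_profile"
  )
}

#' Class profiles with distinct strict gain orderings
#'
#' Builds `n_classes` profiles over a common, strictly decreasing gain
#' ladder, assigning the ladder to leads along a different permutation per
#' class so every class induces a different strict lead-amplitude
#' ordering. Because a constant ranking contributes its transition cells
#' as a *cycle*, and two rotations of one cycle hit the same cells, the
#' class permutations are chosen to differ as cycles: the first four
#' classes walk the leads with strides 1, 5, 7 and 11 (coprime to 12, so
#' their transition-cell sets are pairwise disjoint); further classes use
#' fixed seeded permutations screened to share no full adjacency set with
#' any earlier class.
#'
#' Each lead also carries a baseline offset proportional to its gain
#' (`baseline` mV per unit gain, standing in for per-electrode DC level
#' differences); since the default template waveform never dips below
#' `-baseline`, the noise-free amplitude ordering equals the gain ordering
#' at *every* sample, making each class's rank encoding a single constant,
#' class-specific permutation. With `noise_sd = 0` the classes are
#' therefore separable by construction; the default `noise_sd = 0.016` mV
#' is calibrated so that, under the default template and ladder, roughly
#' one sample in ten has its full 12-lead ranking perturbed by noise.
#'
#' @param n_classes Number of classes (2..12).
#' @param noise_sd Gaussian amplitude noise (mV) shared by all profiles.
#' @param baseline Per-unit-gain baseline offset (mV, default 0.5).
#' @return List of [class_profile()] objects, with the class's lead
#'   ranking attached as attribute `ranking`.
#' @seealso [planted_cells()] for the transition cells a class plants.
#' @export
separable_profiles <- function(n_classes = 2L, noise_sd = 0.016,
                               baseline = 0.5) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > N_LEADS) {
    abort("`n_classes` must be between 2 and 12.", class = "cardioish_config_error")
  }
  perms <- class_rankings(n_classes)
  ladder <- seq(1.6, 0.5, length.out = N_LEADS)
  lapply(seq_len(n_classes), function(k) {
    gains <- numeric(N_LEADS)
    gains[perms[[k]]] <- ladder   # rank-m lead of class k gets the m-th gain
    prof <- class_profile(lead_gains = gains,
                          lead_offsets = gains * baseline,
                          noise_sd = noise_sd)
    attr(prof, "ranking") <- perms[[k]]
    prof
  })
}

# one lead-ranking permutation per class, pairwise distinct as cycles
class_rankings <- function(n_classes) {
  strides <- c(1L, 5L, 7L, 11L)
  cycle_cells <- function(p) {
    nxt <- c(p[-1], p[1])
    sort((p - 1L) * N_LEADS + nxt)
  }
  perms <- lapply(strides[seq_len(min(n_classes, 4L))], function(s) {
    ((seq_len(N_LEADS) - 1L) * s) %% N_LEADS + 1L
  })
  k <- length(perms)
  attempt <- 0L
  while (k < n_classes) {
    attempt <- attempt + 1L
    cand <- with_local_seed(90000L + attempt, sample.int(N_LEADS))
    if (!any(vapply(perms, function(p)
      identical(cycle_cells(p), cycle_cells(cand)), logical(1)))) {
      perms <- c(perms, list(cand))
      k <- k + 1L
    }
  }
  perms
}

#' Transition cells planted by a class's constant ranking
#'
#' For a class whose noise-free rank encoding is the constant permutation
#' `ranking`, the transition table of a beat concentrates on the 12 cells
#' of the cycle `ranking[1] -> ranking[2] -> ... -> ranking[12] ->
#' ranking[1]`. These are the feature indexes where that class carries its
#' signature; the symmetric difference of two classes' planted cells is
#' where they genuinely differ.
#'
#' @param profile A profile from [separable_profiles()] (or an integer
#'   ranking permutation of 1..12).
#' @return Integer vector of 12 feature indexes in 1..144.
#' @export
planted_cells <- function(profile) {
  ranking <- if (inherits(profile, "class_profile")) {
    attr(profile, "ranking") %||%
      order(-profile$lead_gains, seq_len(N_LEADS), method = "radix")
  } else {
    as.integer(profile)
  }
  stopifnot(identical(sort(ranking), seq_len(N_LEADS)))
  nxt <- c(ranking[-1], ranking[1])
  sort((ranking - 1L) * N_LEADS + nxt)
}

# run `code` under set.seed(seed) without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-beat child seed; multiplier * seed stays exact in doubles
child_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483629 * 69069 + index) %% 2147483629)
}

#' Render one synthetic 12-lead beat
#'
#' Lead `l` is `lead_gains[l] * waveform + lead_offsets[l] + noise`, with
#' the waveform from [template_waveform()] and i.i.d. Gaussian noise of
#' standard deviation `noise_sd`. Deterministic given `rng_seed`; the
#' caller's RNG state is left untouched.
#'
#' @param template A [beat_template()].
#' @param profile A [class_profile()].
#' @param rng_seed Integer seed for the noise draw.
#' @return A 12 x L numeric matrix (rows = leads in [lead_names()] order).
#' @export
render_beat <- function(template, profile, rng_seed = 1L) {
  stopifnot(inherits(template, "beat_template"), inherits(profile, "class_profile"))
  w <- template_waveform(template)
  beat <- outer(profile$lead_gains, w) + profile$lead_offsets
  if (profile$noise_sd > 0) {
    noise <- with_local_seed(rng_seed,
      matrix(rnorm(N_LEADS * template$length, sd = profile$noise_sd),
             nrow = N_LEADS))
    beat <- beat + noise
  }
  rownames(beat) <- lead_names()
  beat
}

#' Generate a labelled synthetic beat set
#'
#' Draws `n_per_class` beats from each profile in `profiles`, labelling
#' them 1..K in profile order. Per-beat noise seeds are derived
#' deterministically from `rng_seed` (a fixed linear congruential mix of
#' the master seed and the beat index), so the same configuration and seed
#' always reproduce the identical beat set.
#'
#' @param profiles List of [class_profile()] objects, one per class (>= 2).
#' @param n_per_class Beats per class (>= 1).
#' @param template A [beat_template()] shared by all classes.
#' @param rng_seed Integer master seed.
#' @return A beat-set tibble of class `cardioish_beatset` with columns
#'   `beat_id` (integer), `label` (integer class 1..K) and `signal`
#'   (list-column of 12 x L matrices).
#' @export
#' @examples
#' beats <- generate_beatset(separable_profiles(2, noise_sd = 0),
#'                           n_per_class = 3, rng_seed = 7)
#' beats
generate_beatset <- function(profiles, n_per_class,
                             template = beat_template(), rng_seed = 1L) {
  if (!is.list(profiles) || length(profiles) < 2L) {
    abort("`profiles` must be a list of at least two class profiles.",
          class = "cardioish_config_error")
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "class_profile")))
  n_per_class <- as.integer(n_per_class)
  if (n_per_class < 1L) {
    abort("`n_per_class` must be at least 1.", class = "cardioish_config_error")
  }
  k <- length(profiles)
  labels <- rep(seq_len(k), each = n_per_class)
  signals <- purrr::map(seq_along(labels), function(i) {
    render_beat(template, profiles[[labels[i]]], child_seed(rng_seed, i))
  })
  new_beatset(tibble::tibble(
    beat_id = seq_along(labels),
    label = as.integer(labels),
    signal = signals
  ))
}

new_beatset <- function(df) {
  class(df) <- c("cardioish_beatset", class(tibble::tibble()))
  df
}

#' Validate a beat-set tibble
#'
#' Checks the beat-set contract: columns `beat_id`, `label`, `signal`;
#' every signal a finite 12 x L matrix with a common L; every label class
#' non-empty. Called internally by every consumer of a beat set.
#'
#' @param beats A beat-set tibble.
#' @return `beats`, invisibly, if valid; otherwise an error.
#' @export
validate_beatset <- function(beats) {
  if (!is.data.frame(beats) ||
      !all(c("beat_id", "label", "signal") %in% names(beats))) {
    abort("A beat set needs columns `beat_id`, `label` and `signal`.",
          class = "cardioish_format_error")
  }
  if (nrow(beats) == 0L) {
    abort("Beat set is empty.", class = "cardioish_format_error")
  }
  dims <- vapply(beats$signal, function(s) {
    if (!is.matrix(s) || !is.numeric(s)) return(c(-1, -1))
    dim(s)
  }, numeric(2))
  if (any(dims[1, ] != N_LEADS)) {
    bad <- beats$beat_id[which(dims[1, ] != N_LEADS)[1]]
    abort(paste0("Beat ", bad, " does not have 12 lead rows."),
          class = "cardioish_dimension_error")
  }
  if (length(unique(dims[2, ])) != 1L) {
    abort("All beats must share the same length L.",
          class = "cardioish_format_error")
  }
  if (!all(vapply(beats$signal, function(s) all(is.finite(s)), logical(1)))) {
    abort("Beat signals must be finite.", class = "cardioish_data_error")
  }
  invisible(beats)
}

#' @export
print.cardioish_beatset <- function(x, ...) {
  L <- if (nrow(x)) ncol(x$signal[[1]]) else 0L
  cat(sprintf("<cardioish_beatset> %d beats x 12 leads x %d samples, %d classes\n",
              nrow(x), L, length(unique(x$label))))
  NextMethod()
}

#' Beat set in long (tidy) form
#'
#' @param beats A beat-set tibble.
#' @return Tibble with columns `beat_id`, `label`, `lead` (1..12),
#'   `lead_name`, `sample` (1..L) and `value` (mV).
#' @export
beatset_long <- function(beats) {
  validate_beatset(beats)
  purrr::map2_dfr(beats$beat_id, beats$signal, function(id, s) {
    tibble::tibble(
      beat_id = id,
      lead = rep(seq_len(N_LEADS), times = ncol(s)),
      sample = rep(seq_len(ncol(s)), each = N_LEADS),
      value = as.vector(s)
    )
  }) |>
    dplyr::left_join(dplyr::select(beats, "beat_id", "label"), by = "beat_id") |>
    dplyr::mutate(lead_name = lead_names()[.data$lead]) |>
    dplyr::select("beat_id", "label", "lead", "lead_name", "sample", "value")
}

#' @rdname beatset_long
#' @param object,... passed through; `autoplot` draws a lead-faceted trace
#'   of a handful of beats per class.
#' @param max_beats Cap on beats drawn per class.
#' @export
autoplot.cardioish_beatset <- function(object, max_beats = 2L, ...) {
  keep <- object |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = max_beats) |>
    dplyr::ungroup()
  long <- beatset_long(new_beatset(keep))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$value,
                                     group = .data$beat_id,
                                     colour = factor(.data$label))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~lead_name, ncol = 4) +
    ggplot2::labs(x = "sample", y = "amplitude (mV)", colour = "class")
}
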