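# shared fixtures, built in code

random_beat <- function(L = 30L, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(12L * L), nrow = 12L)
}

random_tr <- function(n = 240L, seed = 1L) {
  set.seed(seed)
  sample.int(12L, n, replace = TRUE)
}

# an all-positive template so gain orderings translate to amplitude
# orderings at every sample
positive_template <- function(L = 60L) {
  beat_template(
    wave_centers = c(8, 20, 30, 40, 52),
    wave_widths = c(30, 30, 30, 30, 30),
    wave_amplitudes = c(0.3, 0.2, 1.0, 0.2, 0.4),
    length = L
  )
}

# symbol frequency rows of the two published example sentences
mi_frequency_counts <- c(16, 18, 13, 18, 16, 13, 18, 15, 19, 17, 16, 15)
mental_frequency_counts <- c(16, 11, 17, 19, 18, 13, 17, 18, 15, 15, 18, 11)

example_sentence_path <- function(which = c("mi", "mental")) {
  which <- match.arg(which)
  system.file("extdata", paste0("sentence_", which, ".txt"),
              package = "cardioish", mustWork = TRUE)
}

# a small two-class feature problem with one planted informative column
toy_feature_problem <- function(n = 40L, p = 4L, seed = 2L) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  x <- matrix(runif(n * p), n, p)
  x[, 1] <- y + rnorm(n, sd = 0.01)
  list(x = x, y = y)
}
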