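test_that("render_beat reduces to the template under unit gains and no noise", {
  tpl <- beat_template(length = 50)
  prof <- class_profile(rep(1, 12), rep(0, 12), noise_sd = 0)
  beat <- render_beat(tpl, prof, rng_seed = 1)
  w <- template_waveform(tpl)
  for (l in 1:12) expect_equal(unname(beat[l, ]), w)
})

test_that("strictly ordered gains give strictly ordered amplitudes everywhere", {
  tpl <- positive_template()
  prof <- class_profile(lead_gains = 12:1, noise_sd = 0)
  beat <- render_beat(tpl, prof, rng_seed = 1)
  expect_true(all(diff(beat) < 0))   # column-wise: lead l+1 < lead l
})

test_that("beat rendering is deterministic given the seed", {
  tpl <- beat_template(length = 40)
  prof <- class_profile(runif(12, 0.5, 2), noise_sd = 0.1)
  expect_identical(render_beat(tpl, prof, 42), render_beat(tpl, prof, 42))
  expect_false(identical(render_beat(tpl, prof, 42), render_beat(tpl, prof, 43)))
})

test_that("rendering does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- rnorm(1)
  set.seed(99)
  invisible(render_beat(beat_template(length = 20),
                        class_profile(rep(1, 12), noise_sd = 0.5), 7))
  expect_identical(rnorm(1), a)
})

test_that("generate_beatset counts, labels and reproduces deterministically", {
  profs <- separable_profiles(2, noise_sd = 0.05)
  beats <- generate_beatset(profs, n_per_class = 10,
                            template = beat_template(length = 40), rng_seed = 3)
  expect_equal(nrow(beats), 20L)
  expect_equal(as.vector(table(beats$label)), c(10L, 10L))
  again <- generate_beatset(profs, n_per_class = 10,
                            template = beat_template(length = 40), rng_seed = 3)
  expect_identical(beats, again)
  expect_identical(extract_features(beats), extract_features(again))
})

test_that("constant strict gain ordering yields a constant rank permutation", {
  profs <- separable_profiles(3, noise_sd = 0)
  tpl <- beat_template(length = 80)
  for (prof in profs) {
    tr <- transform_beat(render_beat(tpl, prof, 1))
    ranking <- attr(prof, "ranking")
    expect_identical(tr, rep(ranking, 80))
  }
})

test_that("separable profiles plant pairwise distinct transition-cell cycles", {
  profs <- separable_profiles(6, noise_sd = 0)
  cells <- lapply(profs, planted_cells)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_false(identical(cells[[i]], cells[[j]]))
  }
  # the four stride-based classes are fully disjoint
  expect_length(Reduce(union, cells[1:4]), 48L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(beat_template(wave_widths = c(1, 2, -1, 2, 3)),
               class = "cardioish_config_error")
  expect_error(beat_template(wave_centers = c(5, 4, 10, 20, 30)),
               class = "cardioish_config_error")
  expect_error(class_profile(rep(1, 11)), class = "cardioish_dimension_error")
  expect_error(class_profile(rep(1, 12), noise_sd = -1),
               class = "cardioish_config_error")
  expect_error(generate_beatset(list(), 5), class = "cardioish_config_error")
  expect_error(generate_beatset(separable_profiles(2), 0),
               class = "cardioish_config_error")
})
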