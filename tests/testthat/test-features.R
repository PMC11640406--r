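test_that("count_transitions matches the worked single- and double-block cases", {
  m1 <- count_transitions(1:12)               # L = 1
  expect_equal(sum(m1), 11)
  for (a in 1:11) expect_equal(m1[a, a + 1], 1)
  expect_equal(sum(diag(m1)), 0)

  m2 <- count_transitions(rep(1:12, 2))       # L = 2: doubled + wraparound
  expect_equal(sum(m2), 23)
  for (a in 1:11) expect_equal(m2[a, a + 1], 2)
  expect_equal(m2[12, 1], 1)
})

test_that("count_transitions equals a brute-force pair-counting loop", {
  tr <- random_tr(240, seed = 11)
  oracle <- matrix(0L, 12, 12)
  for (j in seq_len(length(tr) - 1)) {
    oracle[tr[j], tr[j + 1]] <- oracle[tr[j], tr[j + 1]] + 1L
  }
  expect_equal(count_transitions(tr), oracle)
})

test_that("transition totals are conserved at 12L - 1", {
  for (s in 1:10) {
    L <- 5 + s
    tr <- transform_beat(random_beat(L = L, seed = s))
    expect_equal(sum(count_transitions(tr)), 12 * L - 1)
  }
})

test_that("count_transitions rejects out-of-range values", {
  expect_error(count_transitions(c(1, 13)), class = "cardioish_data_error")
  expect_error(count_transitions(c(0, 5)), class = "cardioish_data_error")
  expect_error(count_transitions(3L), class = "cardioish_data_error")
})

test_that("normalize_rows divides by row sums and preserves zero rows", {
  m <- matrix(0, 12, 12)
  m[1, 1:2] <- c(1, 1)
  m[2, 1:2] <- c(3, 1)
  out <- normalize_rows(m, epsilon = 1e-10)
  expect_equal(out[1, 1:2], c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(out[2, 1:2], c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(sum(out[1, ]), 1, tolerance = 1e-9)
  expect_true(all(out[3:12, ] == 0))
  expect_error(normalize_rows(m, epsilon = 0), class = "cardioish_config_error")
  expect_error(normalize_rows(m, epsilon = -1), class = "cardioish_config_error")
})

test_that("flattening is row-major and invertible", {
  vals <- matrix(seq_len(144), 12, 12, byrow = TRUE)
  fv <- flatten_features(vals)
  expect_equal(fv, 1:144, ignore_attr = TRUE)
  expect_equal(fv[1], vals[1, 1])
  expect_equal(fv[144], vals[12, 12])
  expect_equal(unflatten_features(fv), vals)
  diag_m <- diag(12) * 0.5
  expect_identical(which(flatten_features(diag_m) != 0), as.integer((0:11) * 12 + 1:12))
})

test_that("extract_features yields one 144-feature row per beat, in [0, 1)", {
  beats <- generate_beatset(separable_profiles(2, noise_sd = 0.05), 3,
                            template = beat_template(length = 40), rng_seed = 1)
  feats <- extract_features(beats)
  expect_equal(nrow(feats), 6L)
  expect_identical(setdiff(names(feats), c("beat_id", "label")), feature_names())
  x <- as.matrix(feats[, feature_names()])
  expect_true(all(x >= 0 & x < 1))
})

test_that("a constant-ranking beat has the analytic transition counts", {
  L <- 70
  prof <- separable_profiles(2, noise_sd = 0)[[1]]
  p <- attr(prof, "ranking")
  mat <- count_transitions(transform_beat(render_beat(beat_template(length = L),
                                                      prof, 1)))
  for (m in 1:11) expect_equal(mat[p[m], p[m + 1]], L)
  expect_equal(mat[p[12], p[1]], L - 1)
  expect_equal(sum(mat), 12 * L - 1)
})

test_that("relabelling leads permutes features equivariantly", {
  set.seed(21)
  for (rep in 1:5) {
    beat <- random_beat(L = 18, seed = 100 + rep)
    perm <- sample(12)
    base <- count_transitions(transform_beat(beat))
    permuted <- count_transitions(transform_beat(beat[perm, , drop = FALSE]))
    # lead a of the permuted beat is original lead perm[a], so cell (a, b)
    # of the permuted table is cell (perm[a], perm[b]) of the original
    expect_equal(permuted, base[perm, perm])
  }
})
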