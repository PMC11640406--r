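test_that("min-max normalisation maps columns to [0, 1) and kills constants", {
  x <- cbind(c(0, 0.5, 1), c(0.3, 0.3, 0.3), c(2, 4, 6))
  xn <- minmax_normalize(x)
  expect_equal(xn[, 1], c(0, 0.5, 1), tolerance = 1e-6)
  expect_identical(xn[, 2], c(0, 0, 0))
  expect_equal(min(xn[, 3]), 0)
  expect_lt(abs(max(xn[, 3]) - 1), 1e-6)
})

test_that("NCA gives the informative feature the dominant weight", {
  prob <- toy_feature_problem(n = 40, p = 2, seed = 2)
  rk <- nca_weights(minmax_normalize(prob$x), prob$y)
  expect_gt(rk$weights[1], rk$weights[2])
  expect_equal(rk$idx[1], 1L)
  # objective must not decrease along the trace (ascent contract)
  expect_true(all(diff(rk$objective) >= -1e-12))
})

test_that("duplicated informative features receive near-identical weights", {
  prob <- toy_feature_problem(n = 40, p = 3, seed = 4)
  x <- cbind(prob$x[, 1], prob$x[, 1], prob$x[, 3])
  rk <- nca_weights(minmax_normalize(x), prob$y)
  expect_lt(abs(rk$weights[1] - rk$weights[2]),
            0.1 * max(rk$weights[1], rk$weights[2]))
})

test_that("a huge ridge penalty shrinks all NCA weights towards zero", {
  prob <- toy_feature_problem(n = 30, p = 4, seed = 6)
  rk <- nca_weights(minmax_normalize(prob$x), prob$y, lambda = 1e3)
  rk0 <- nca_weights(minmax_normalize(prob$x), prob$y, lambda = 0)
  expect_lt(max(rk$weights), 1e-2)
  expect_lt(sum(rk$weights), 0.01 * sum(rk0$weights))
})

test_that("NCA rejects degenerate label sets", {
  x <- matrix(runif(20), 10, 2)
  expect_error(nca_weights(x, rep(1, 10)),
               class = "cardioish_degenerate_label_error")
  expect_error(nca_weights(x[1:3, ], c(1, 2, 1)), class = "cardioish_config_error")
})

test_that("prefix losses are zero once a separating feature is included", {
  set.seed(8)
  n <- 40
  y <- rep(1:2, each = n / 2)
  x <- cbind(y * 10, matrix(runif(n * 3), n, 3))   # column 1 separates alone
  curve <- evaluate_prefixes(minmax_normalize(x), y, idx = 1:4, stop = 4,
                             folds = 5, seed = 1)
  expect_equal(curve$loss, rep(0, 4))
  expect_true(all(curve$loss >= 0 & curve$loss <= 1))
})

test_that("shuffled labels give chance-level prefix losses", {
  set.seed(123)
  n <- 200
  x <- matrix(runif(n * 10), n, 10)
  y <- sample(rep(1:2, each = n / 2))
  curve <- evaluate_prefixes(minmax_normalize(x), y, idx = 1:10, stop = 10,
                             folds = 10, seed = 7)
  expect_lt(abs(mean(curve$loss) - 0.5), 0.1)
})

test_that("prefix evaluation is incremental-consistent with direct CV", {
  # the incremental distance sweep must agree with evaluating one prefix
  # from scratch with the same folds
  set.seed(31)
  n <- 60
  y <- rep(1:3, each = n / 3)
  x <- matrix(runif(n * 6), n, 6)
  x[, 2] <- y + rnorm(n, sd = 0.3)
  idx <- c(2L, 5L, 1L, 3L, 6L, 4L)
  curve <- evaluate_prefixes(x, y, idx, stop = 6, folds = 5, seed = 9)
  for (j in c(1L, 3L, 6L)) {
    direct <- cross_validate(x[, idx[1:j], drop = FALSE], y, folds = 5, seed = 9)
    expect_equal(curve$loss[j], 1 - direct$accuracy / 100)
  }
})

test_that("choose_prefix takes the smallest argmin of the loss curve", {
  curve <- tibble::tibble(size = 1:3, loss = c(0.3, 0.1, 0.2))
  expect_equal(choose_prefix(curve)$size, 2L)
  curve$loss <- c(0.2, 0.1, 0.1)
  expect_equal(choose_prefix(curve)$size, 2L)
  curve$loss <- c(0.1, 0.1, 0.1)
  expect_equal(choose_prefix(curve)$size, 1L)
})

test_that("inca recovers planted signatures, deterministically", {
  profs <- separable_profiles(2, noise_sd = 0.05)
  beats <- generate_beatset(profs, n_per_class = 20,
                            template = beat_template(length = 120), rng_seed = 13)
  feats <- extract_features(beats)
  sel <- inca(feats, stop = 40, folds = 5, seed = 13)
  planted <- union(planted_cells(profs[[1]]), planted_cells(profs[[2]]))
  expect_gt(length(intersect(sel$sel_indexes, planted)), 0)
  # determinism under identical seed
  sel2 <- inca(feats, stop = 40, folds = 5, seed = 13)
  expect_identical(sel$weights, sel2$weights)
  expect_identical(sel$idx, sel2$idx)
  expect_identical(sel$loss_curve, sel2$loss_curve)
  expect_identical(sel$sel_indexes, sel2$sel_indexes)
  # greedy contract
  expect_equal(sel$min_loss, min(sel$loss_curve$loss))
  expect_lte(sel$min_loss, sel$loss_curve$loss[nrow(sel$loss_curve)])
  expect_identical(sort(sel$idx), 1:144)
  expect_identical(sel$sel_indexes, sel$idx[seq_len(sel$size)])
})
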