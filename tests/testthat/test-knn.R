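test_that("1-NN picks the nearest training point under cityblock distance", {
  train <- rbind(c(0, 0), c(10, 10))
  expect_equal(knn_predict(train, c("A", "B"), rbind(c(1, 1))), "A")
  expect_equal(knn_predict(train, c("A", "B"), train), c("A", "B"))
  # distance ties go to the lowest training index
  tied <- rbind(c(0, 0), c(2, 2))
  expect_equal(knn_predict(tied, c("A", "B"), rbind(c(1, 1))), "A")
})

test_that("knn_predict matches an exhaustive brute-force oracle", {
  set.seed(17)
  for (rep in 1:10) {
    train <- matrix(rnorm(30 * 5), 30, 5)
    y <- sample(1:3, 30, replace = TRUE)
    test <- matrix(rnorm(8 * 5), 8, 5)
    oracle <- apply(test, 1, function(q) {
      d <- apply(train, 1, function(t) sum(abs(q - t)))
      y[which(d == min(d))[1]]
    })
    expect_equal(knn_predict(train, y, test), oracle)
  }
})

test_that("knn_predict validates its configuration", {
  expect_error(knn_predict(matrix(0, 0, 2), integer(0), matrix(0, 1, 2)),
               class = "cardioish_config_error")
  expect_error(knn_predict(matrix(0, 3, 2), 1:3, matrix(0, 1, 3)),
               class = "cardioish_dimension_error")
  expect_error(knn_predict(matrix(0, 3, 2), 1:3, matrix(0, 1, 2), k = 4),
               class = "cardioish_config_error")
})

test_that("stratified folds are balanced, seeded and reduced when needed", {
  y <- rep(1:2, c(40, 30))
  f <- make_folds(y, folds = 10, seed = 5)
  expect_identical(f, make_folds(y, folds = 10, seed = 5))
  expect_equal(attr(f, "folds"), 10L)
  expect_true(all(table(y, f) >= 1))   # every class in every fold
  expect_true(max(table(f[y == 1])) - min(table(f[y == 1])) <= 1)
  expect_warning(f2 <- make_folds(rep(1:2, c(40, 4)), folds = 10, seed = 1),
                 "reducing")
  expect_equal(attr(f2, "folds"), 4L)
  expect_error(make_folds(rep(1, 10)), class = "cardioish_degenerate_label_error")
})

test_that("cross-validation pools out-of-fold predictions exactly once", {
  set.seed(23)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- rep(1:2, each = 30)
  ev <- cross_validate(x, y, folds = 6, seed = 2)
  expect_equal(nrow(ev$predictions), 60L)
  expect_identical(sort(ev$predictions$index), 1:60)
  expect_equal(rowSums(ev$confusion), c(`1` = 30, `2` = 30),
               ignore_attr = TRUE)
  expect_equal(ev$accuracy,
               100 * sum(diag(ev$confusion)) / sum(ev$confusion))
})

test_that("a separable problem evaluates to 100% accuracy and G-mean", {
  x <- cbind(rep(c(0, 100), each = 20), rnorm(40))
  y <- rep(1:2, each = 20)
  ev <- cross_validate(x, y, folds = 10, seed = 3)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$geometric_mean, 100)
  expect_equal(unname(ev$recalls), c(1, 1))
})

test_that("geometric mean is the K-th root of the recall product", {
  expect_equal(geometric_mean(diag(c(5, 7, 9))), 100)
  expect_equal(geometric_mean(matrix(c(9, 1, 6, 4), 2, byrow = TRUE)), 60)
  # all-majority predictions zero out the minority recall
  expect_equal(geometric_mean(matrix(c(20, 0, 10, 0), 2, byrow = TRUE)), 0)
  expect_error(geometric_mean(matrix(c(1, 0, 0, 0), 2)),
               class = "cardioish_degenerate_label_error")
})

test_that("eval accessors expose recalls and headline metrics", {
  x <- cbind(rep(c(0, 100), each = 10))
  y <- rep(1:2, each = 10)
  ev <- cross_validate(x, y, folds = 5, seed = 1)
  td <- tidy(ev)
  expect_equal(td$class, 1:2)
  expect_equal(td$recall, c(1, 1))
  gl <- glance(ev)
  expect_equal(gl$accuracy, 100)
  expect_equal(gl$n, 20L)
})
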