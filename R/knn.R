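#' k-nearest-neighbour prediction with cityblock distance
#'
#' Plain kNN under the L1 (cityblock) metric, the classifier used
#' throughout the pipeline with `k = 1`. Distance ties are resolved in
#' favour of the lowest training-row index, and (for `k > 1`) vote ties in
#' favour of the tied label whose nearest representative comes first, so
#' predictions are fully deterministic.
#'
#' @param train_x Numeric training matrix (rows = observations).
#' @param train_y Labels aligned with `train_x` rows.
#' @param test_x Numeric matrix with the same number of columns.
#' @param k Number of neighbours (default 1).
#' @return Vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 1L) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0L) {
    abort("Training set is empty.", class = "cardioish_config_error")
  }
  if (ncol(train_x) != ncol(test_x)) {
    abort("Train and test must have the same number of features.",
          class = "cardioish_dimension_error")
  }
  if (k > nrow(train_x)) {
    abort("`k` cannot exceed the number of training rows.",
          class = "cardioish_config_error")
  }
  d <- l1_distances(test_x, train_x)
  if (k == 1L) {
    # which.min returns the first minimum -> lowest-index tie rule
    return(train_y[apply(d, 1L, which.min)])
  }
  apply(d, 1L, function(row) {
    nb <- order(row, method = "radix")[seq_len(k)]
    votes <- table(train_y[nb])
    winners <- names(votes)[votes == max(votes)]
    # among tied labels, keep the one reached first in neighbour order
    train_y[nb][match(TRUE, as.character(train_y[nb]) %in% winners)]
  })
}

# pairwise L1 distance matrix, rows of a vs rows of b
l1_distances <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (f in seq_len(ncol(a))) {
    out <- out + abs(outer(a[, f], b[, f], "-"))
  }
  out
}

#' Seeded stratified fold assignment
#'
#' Assigns each observation to one of `folds` cross-validation folds,
#' stratified by class: within each class the members are shuffled (with
#' the given seed) and dealt out cyclically, so per-fold class proportions
#' match the data as closely as integer counts allow. If some class has
#' fewer members than `folds`, the fold count is reduced to the minimum
#' class size with a warning.
#'
#' @param y Label vector.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling the within-class shuffles.
#' @return Integer vector of fold ids in `1..folds`, aligned with `y`;
#'   the (possibly reduced) fold count is attached as attribute `folds`.
#' @export
make_folds <- function(y, folds = 10L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) {
    abort("`folds` must be at least 2.", class = "cardioish_config_error")
  }
  counts <- table(y)
  if (length(counts) < 2L) {
    abort("Fold stratification needs at least two classes.",
          class = "cardioish_degenerate_label_error")
  }
  if (min(counts) < folds) {
    folds <- max(2L, as.integer(min(counts)))
    warn(sprintf("Smallest class has %d members; reducing to %d folds.",
                 min(counts), folds))
  }
  assignment <- integer(length(y))
  with_local_seed(seed, {
    for (cls in names(counts)) {
      members <- which(y == cls)
      members <- members[sample.int(length(members))]
      assignment[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  attr(assignment, "folds") <- folds
  assignment
}

#' Cross-validated kNN evaluation
#'
#' Stratified k-fold cross-validation of the kNN classifier: each fold is
#' held out in turn, predicted from the remaining folds, and the pooled
#' out-of-fold predictions are scored with overall accuracy, per-class
#' recalls and their geometric mean.
#'
#' @param x Numeric feature matrix or a feature tibble containing
#'   `f001..f144` columns (any subset of columns may be supplied as a
#'   plain matrix).
#' @param y Integer class labels (ignored when `x` is a feature tibble
#'   with a `label` column).
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param k Number of neighbours (default 1).
#' @return Object of class `cardioish_eval`: list with `predictions`
#'   tibble, `confusion` matrix, `accuracy` and `geometric_mean` (both in
#'   percent), `recalls`, and the CV configuration. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
cross_validate <- function(x, y = NULL, folds = 10L, seed = 1L, k = 1L) {
  if (is.data.frame(x)) {
    fm <- feature_matrix(x)
    y <- y %||% fm$y
    x <- fm$X
  }
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    abort("Cross-validation needs at least two classes.",
          class = "cardioish_degenerate_label_error")
  }
  assignment <- make_folds(y, folds = folds, seed = seed)
  nfolds <- attr(assignment, "folds")
  pred <- integer(length(y))
  for (f in seq_len(nfolds)) {
    test <- assignment == f
    pred[test] <- knn_predict(x[!test, , drop = FALSE], y[!test],
                              x[test, , drop = FALSE], k = k)
  }
  classes <- sort(unique(y))
  confusion <- table(factor(y, levels = classes),
                     factor(pred, levels = classes))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(truth = classes, prediction = classes)
  recalls <- diag(confusion) / rowSums(confusion)
  structure(
    list(
      predictions = tibble::tibble(index = seq_along(y), truth = y,
                                   prediction = pred, fold = as.integer(assignment)),
      confusion = confusion,
      accuracy = 100 * sum(diag(confusion)) / sum(confusion),
      geometric_mean = geometric_mean(confusion),
      recalls = recalls,
      folds = nfolds, seed = seed, k = k
    ),
    class = "cardioish_eval"
  )
}

#' Geometric mean of per-class recalls
#'
#' The K-th root of the product of the class-wise recalls of a confusion
#' matrix, in percent. A single class with zero recall drives the score to
#' zero, which is what makes the metric sensitive to minority-class
#' failure.
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' geometric_mean(matrix(c(9, 1, 6, 4), 2, byrow = TRUE))  # recalls .9, .4
geometric_mean <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  totals <- rowSums(confusion)
  if (any(totals == 0)) {
    abort("Every class row must contain at least one observation.",
          class = "cardioish_degenerate_label_error")
  }
  recalls <- diag(confusion) / totals
  if (any(recalls == 0)) return(0)
  100 * exp(mean(log(recalls)))
}

#' @export
print.cardioish_eval <- function(x, ...) {
  cat(sprintf("<cardioish_eval> %d-fold CV, k=%d: accuracy %.2f%%, G-mean %.2f%%\n",
              x$folds, x$k, x$accuracy, x$geometric_mean))
  invisible(x)
}

#' @export
tidy.cardioish_eval <- function(x, ...) {
  tibble::tibble(
    class = as.integer(rownames(x$confusion)),
    n = rowSums(x$confusion),
    recall = unname(x$recalls)
  )
}

#' @export
glance.cardioish_eval <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    geometric_mean = x$geometric_mean,
    folds = x$folds,
    k = x$k,
    n = nrow(x$predictions)
  )
}

#' @export
autoplot.cardioish_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "prediction", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Pooled CV confusion (accuracy %.2f%%)",
                                  object$accuracy))
}
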