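#' Column-wise min-max normalisation
#'
#' Rescales every feature column to `(x - min) / (max - min + epsilon)`.
#' The epsilon keeps the map defined for constant columns, which collapse
#' to all zeros; non-constant columns end up spanning `[0, 1)` up to the
#' epsilon-induced deflation.
#'
#' @param x Numeric matrix, or a feature tibble with `f001..f144` columns.
#' @param epsilon Positive stabiliser (default `1e-10`).
#' @return Same shape as `x` (matrix in, matrix out; tibble in, tibble out
#'   with only the feature columns rescaled).
#' @export
minmax_normalize <- function(x, epsilon = 1e-10) {
  if (is.data.frame(x)) {
    fn <- intersect(feature_names(), names(x))
    x[fn] <- as.data.frame(minmax_normalize(as.matrix(x[fn]), epsilon))
    return(x)
  }
  x <- as.matrix(x)
  mins <- apply(x, 2L, min)
  maxs <- apply(x, 2L, max)
  sweep(sweep(x, 2L, mins, "-"), 2L, maxs - mins + epsilon, "/")
}

#' NCA feature weighting
#'
#' Learns one non-negative relevance weight per feature by neighbourhood
#' component analysis: weights `w` are fitted to maximise the expected
#' leave-one-out soft 1-NN accuracy
#' \deqn{F(w) = \frac{1}{n}\sum_i \sum_{j \ne i,\, y_j = y_i} p_{ij}
#'   \; - \; \lambda \sum_f w_f^2,}
#' where \eqn{p_{ij} = \exp(-d_{ij}) / \sum_{k \ne i} \exp(-d_{ik})} and
#' \eqn{d_{ij} = \sum_f w_f^2 \, |x_{if} - x_{jf}|} is a weighted
#' cityblock distance. Optimisation is deterministic full-batch gradient
#' ascent from unit initial weights with an adaptive step size, so
#' identical inputs always give identical weights.
#'
#' @param xn Normalised feature matrix (rows = observations).
#' @param y Integer class labels (>= 2 classes, >= 4 observations).
#' @param lambda Ridge penalty on the weights; default `1/n`.
#' @param max_iter Iteration cap (default 60).
#' @param tol Relative objective-improvement tolerance (default `1e-6`).
#' @return Object of class `cardioish_ranking`: list with `weights` (the
#'   squared weights, one per feature, non-negative), `idx` (feature
#'   indexes by decreasing weight, ties to the lower index), `objective`
#'   (trace of F(w)), `lambda`, `iterations`.
#' @export
nca_weights <- function(xn, y, lambda = NULL, max_iter = 60L, tol = 1e-6) {
  xn <- as.matrix(xn)
  y <- as.integer(y)
  n <- nrow(xn)
  p <- ncol(xn)
  if (length(unique(y)) < 2L) {
    abort("NCA needs at least two classes.",
          class = "cardioish_degenerate_label_error")
  }
  if (n < 4L) {
    abort("NCA needs at least four observations.", class = "cardioish_config_error")
  }
  lambda <- lambda %||% (1 / n)

  # per-feature pairwise |x_if - x_jf|, vectorised as an n^2 x p matrix
  amat <- matrix(0, n * n, p)
  for (f in seq_len(p)) {
    amat[, f] <- abs(outer(xn[, f], xn[, f], "-"))
  }
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective_and_coef <- function(w) {
    d <- matrix(amat %*% (w^2), n, n)
    diag(d) <- Inf
    e <- exp(-(d - apply(d, 1L, min)))     # row-shifted softmax
    diag(e) <- 0
    pmat <- e / rowSums(e)
    pi_same <- rowSums(pmat * same)
    obj <- mean(pi_same) - lambda * sum(w^2)
    coef <- pmat * pi_same - pmat * same   # gradient pair coefficients
    list(obj = obj, coef = coef)
  }

  w <- rep(1, p)
  state <- objective_and_coef(w)
  trace <- state$obj
  lr <- 1
  for (iter in seq_len(max_iter)) {
    grad <- (2 / n) * w * drop(crossprod(amat, as.vector(state$coef))) -
      2 * lambda * w
    accepted <- FALSE
    for (try in 1:30) {
      w_new <- w + lr * grad
      cand <- objective_and_coef(w_new)
      if (cand$obj > state$obj) {
        w <- w_new
        state <- cand
        lr <- lr * 1.1
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    trace <- c(trace, state$obj)
    if (!accepted) break
    k <- length(trace)
    if (abs(trace[k] - trace[k - 1]) <= tol * max(1, abs(trace[k - 1]))) break
  }

  weights <- w^2
  idx <- order(-weights, seq_along(weights), method = "radix")
  structure(
    list(weights = weights, idx = idx, objective = trace,
         lambda = lambda, iterations = length(trace) - 1L),
    class = "cardioish_ranking"
  )
}

#' @export
print.cardioish_ranking <- function(x, ...) {
  cat(sprintf("<cardioish_ranking> %d features, lambda=%.3g, %d iterations, F=%.4f\n",
              length(x$weights), x$lambda, x$iterations,
              x$objective[length(x$objective)]))
  cat("top features:", paste(head(x$idx, 8L), collapse = ", "), "...\n")
  invisible(x)
}

#' Misclassification loss of growing ranked-feature prefixes
#'
#' For each prefix size `j` in `start..stop`, evaluates the features
#' `idx[1..j]` with stratified k-fold cross-validated 1-NN (cityblock) and
#' records the pooled misclassification rate. One fold partition, fixed by
#' `seed`, is reused for every prefix so the loss curve is comparable
#' across sizes; distances are accumulated incrementally one feature at a
#' time, making the whole sweep linear in `stop`.
#'
#' @param xn Normalised feature matrix.
#' @param y Integer labels.
#' @param idx Feature ranking (permutation of column indexes).
#' @param start,stop Prefix-size range (defaults 1 and `ncol(xn)`).
#' @param folds,seed Cross-validation settings (defaults 10, 1).
#' @return Tibble with columns `size` and `loss` (misclassification rate).
#' @export
evaluate_prefixes <- function(xn, y, idx, start = 1L, stop = ncol(xn),
                              folds = 10L, seed = 1L) {
  xn <- as.matrix(xn)
  y <- as.integer(y)
  start <- as.integer(start)
  stop <- as.integer(stop)
  if (start < 1L || stop < start || stop > ncol(xn)) {
    abort("Need 1 <= start <= stop <= ncol(xn).", class = "cardioish_config_error")
  }
  assignment <- make_folds(y, folds = folds, seed = seed)
  nfolds <- attr(assignment, "folds")
  correct <- integer(stop)
  for (f in seq_len(nfolds)) {
    test <- which(assignment == f)
    train <- which(assignment != f)
    d <- matrix(0, length(test), length(train))
    for (j in seq_len(stop)) {
      col <- idx[j]
      d <- d + abs(outer(xn[test, col], xn[train, col], "-"))
      if (j >= start) {
        pred <- y[train][max.col(-d, ties.method = "first")]
        correct[j] <- correct[j] + sum(pred == y[test])
      }
    }
  }
  sizes <- start:stop
  tibble::tibble(size = sizes, loss = 1 - correct[sizes] / length(y))
}

#' Greedy choice of the best prefix
#'
#' Picks the smallest prefix size attaining the minimum loss (fewest
#' features wins ties).
#'
#' @param curve Tibble from [evaluate_prefixes()] with `size` and `loss`.
#' @return List with `size` (chosen prefix length) and `loss` (its value).
#' @export
choose_prefix <- function(curve) {
  stopifnot(nrow(curve) > 0L)
  i <- which.min(curve$loss)   # first minimum -> smallest size
  list(size = curve$size[i], loss = curve$loss[i])
}

#' Iterative NCA feature selection (INCA)
#'
#' The full selection phase: min-max normalise the 144 transition
#' features, rank them by NCA weight, sweep ranked prefixes of sizes
#' `start..stop` under a cross-validated 1-NN loss, and keep the prefix
#' with minimum misclassification rate (smallest prefix on ties). Note
#' that, as in the original procedure, selection sees the labels of all
#' observations before any final evaluation; for an honest generalisation
#' estimate use `nested = TRUE` in [run_pipeline()].
#'
#' @param features Feature tibble from [extract_features()] (or a plain
#'   matrix of 144 columns plus `y`).
#' @param y Labels; taken from the `label` column when `features` is a
#'   feature tibble.
#' @param start,stop Prefix range (defaults 1, 144).
#' @param folds,seed Internal CV settings for the prefix losses.
#' @param lambda NCA ridge penalty; default `1/n`.
#' @param epsilon Min-max normalisation stabiliser.
#' @param max_iter,tol NCA optimiser controls.
#' @return Object of class `cardioish_selection`: `weights`, `idx`,
#'   `loss_curve` tibble, `size` (chosen prefix length), `sel_indexes`
#'   (1-based selected feature indexes, in ranking order), `sel` (the
#'   normalised selected sub-matrix), plus the settings used. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' beats <- generate_beatset(separable_profiles(2, noise_sd = 0.05),
#'                           n_per_class = 15, rng_seed = 3)
#' sel <- inca(extract_features(beats), stop = 30, seed = 3)
#' glance(sel)
inca <- function(features, y = NULL, start = 1L, stop = N_FEATURES,
                 folds = 10L, seed = 1L, lambda = NULL, epsilon = 1e-10,
                 max_iter = 60L, tol = 1e-6) {
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    y <- y %||% fm$y
    x <- fm$X
  } else {
    x <- as.matrix(features)
  }
  if (is.null(y)) {
    abort("Labels `y` are required.", class = "cardioish_config_error")
  }
  if (ncol(x) != N_FEATURES) {
    abort("INCA expects the 144-column transition feature matrix.",
          class = "cardioish_dimension_error")
  }
  y <- as.integer(y)
  xn <- minmax_normalize(x, epsilon = epsilon)
  ranking <- nca_weights(xn, y, lambda = lambda, max_iter = max_iter, tol = tol)
  curve <- evaluate_prefixes(xn, y, ranking$idx, start = start, stop = stop,
                             folds = folds, seed = seed)
  best <- choose_prefix(curve)
  sel_indexes <- ranking$idx[seq_len(best$size)]
  structure(
    list(
      weights = ranking$weights,
      idx = ranking$idx,
      objective = ranking$objective,
      loss_curve = curve,
      size = best$size,
      min_loss = best$loss,
      sel_indexes = sel_indexes,
      sel = xn[, sel_indexes, drop = FALSE],
      start = start, stop = stop, folds = folds, seed = seed,
      lambda = ranking$lambda, epsilon = epsilon
    ),
    class = "cardioish_selection"
  )
}

#' @export
print.cardioish_selection <- function(x, ...) {
  cat(sprintf("<cardioish_selection> %d of 144 features, CV loss %.4f\n",
              x$size, x$min_loss))
  cat("selected:", paste(head(x$sel_indexes, 10L), collapse = ", "),
      if (x$size > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
tidy.cardioish_selection <- function(x, ...) {
  rank_of <- match(seq_len(N_FEATURES), x$idx)
  pairs <- t(vapply(seq_len(N_FEATURES), feature_symbol_pair, integer(2)))
  alpha <- cardioish_alphabet()
  tibble::tibble(
    feature = seq_len(N_FEATURES),
    name = feature_names(),
    from = alpha[pairs[, 1]],
    to = alpha[pairs[, 2]],
    weight = x$weights,
    rank = rank_of,
    selected = seq_len(N_FEATURES) %in% x$sel_indexes
  ) |>
    dplyr::arrange(.data$rank)
}

#' @export
glance.cardioish_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = x$size,
    min_loss = x$min_loss,
    full_loss = x$loss_curve$loss[nrow(x$loss_curve)],
    folds = x$folds,
    lambda = x$lambda
  )
}

#' @export
autoplot.cardioish_selection <- function(object, ...) {
  ggplot2::ggplot(object$loss_curve, ggplot2::aes(x = .data$size, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(object$loss_curve,
                                             .data$size == object$size),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "ranked-prefix size", y = "CV misclassification rate",
                  title = sprintf("INCA loss curve (chosen size %d)", object$size))
}
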