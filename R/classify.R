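#' Train an RBF-kernel SVM with a (c, g) grid search
#'
#' Fits a binary C-SVM with radial basis kernel at every pair of a log2
#' penalty grid `c in 2^(-2..10)` and kernel-width grid `g in 2^(-6..6)`,
#' scoring each pair by stratified `n_folds`-fold cross-validation on the
#' calibration set, and refits the winner on all calibration data. Ties
#' resolve to the smaller `c`, then the smaller `g`. Fold assignment is
#' the only source of randomness and is driven by `seed`.
#'
#' @param X calibration spectra (samples x bands) or a
#'   [spectral_dataset()] (then `y` is taken from its `class` column).
#' @param y integer labels (1 = wild type, 2 = mutant).
#' @param bands optional `band_selection` (or integer indices) restricting
#'   the model to selected bands.
#' @param c_grid,g_grid parameter grids.
#' @param n_folds cross-validation folds.
#' @param seed RNG seed for fold assignment.
#' @return A `seed_classifier` (kind `"svm"`) with elements `fit`, `c`,
#'   `g`, `cv_accuracy`, `bands`, `n_features`.
#' @export
train_svm <- function(X, y = NULL, bands = NULL,
                      c_grid = 2^(-2:10), g_grid = 2^(-6:6),
                      n_folds = 5, seed = 1L) {
  dat <- resolve_xy(X, y)
  Xm <- restrict_bands(dat$X, bands)
  y <- dat$y
  check_two_classes(y)
  yf <- factor(y, levels = c(1L, 2L))
  n_folds <- min(n_folds, min(table(y)))  # every fold needs test samples
  folds <- with_rng(seed, stratified_folds(y, n_folds))
  grid <- tidyr::crossing(c = sort(c_grid), g = sort(g_grid))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      if (!any(!tr) || length(unique(y[tr])) < 2L) next
      fit <- e1071::svm(Xm[tr, , drop = FALSE], yf[tr], type = "C-classification",
                        kernel = "radial", cost = grid$c[i],
                        gamma = grid$g[i], scale = FALSE)
      pr <- predict(fit, Xm[!tr, , drop = FALSE])
      correct <- correct + sum(pr == yf[!tr])
    }
    correct / length(y)
  }, numeric(1))
  best <- which.max(acc)  # grid ordered by c then g => desired tie-break
  fit <- e1071::svm(Xm, yf, type = "C-classification", kernel = "radial",
                    cost = grid$c[best], gamma = grid$g[best], scale = FALSE)
  new_seed_classifier(
    kind = "svm", fit = fit, bands = bands, n_features = ncol(Xm),
    params = list(c = grid$c[best], g = grid$g[best],
                  cv_accuracy = 100 * acc[best])
  )
}

#' Train an extreme learning machine
#'
#' Single-hidden-layer feedforward network whose input weights and biases
#' are drawn once from `U(-1, 1)` and never updated; output weights (and
#' an output bias) are solved in closed form by least squares
#' (Moore-Penrose pseudoinverse) against one-hot class targets. Inputs are min-max scaled to \[0, 1\]
#' per band using calibration ranges (logistic sigmoid activations need
#' bounded inputs). The hidden-layer size is chosen from
#' `n_hidden_range` by accuracy on an inner Kennard-Stone 2:1 sub-split
#' of the calibration set; ties prefer the smaller size. All randomness
#' derives from `seed`, so retraining with the same seed reproduces the
#' model exactly.
#'
#' @inheritParams train_svm
#' @param n_hidden_range candidate hidden-node counts (default `1:80`).
#' @return A `seed_classifier` (kind `"elm"`) with the hidden-layer
#'   weights, output weights, scaling ranges and the selection trace.
#' @export
train_elm <- function(X, y = NULL, bands = NULL, n_hidden_range = 1:80,
                      seed = 1L) {
  dat <- resolve_xy(X, y)
  Xm <- restrict_bands(dat$X, bands)
  y <- dat$y
  check_two_classes(y)
  rng <- list(min = apply(Xm, 2L, min), max = apply(Xm, 2L, max))
  Xs <- minmax_scale(Xm, rng)

  n <- nrow(Xs)
  n_inner <- as.integer(round_half_up(n * 2 / 3))
  inner <- if (n >= 4L) kennard_stone(Xs, n_inner) else seq_len(max(n - 1L, 1L))
  val <- setdiff(seq_len(n), inner)
  if (!length(val)) {
    inner <- seq_len(n - 1L)
    val <- n
  }
  acc <- vapply(n_hidden_range, function(h) {
    m <- elm_solve(Xs[inner, , drop = FALSE], y[inner], h, seed)
    mean(elm_predict(m, Xs[val, , drop = FALSE]) == y[val])
  }, numeric(1))
  best_h <- n_hidden_range[which.max(acc)]
  model <- elm_solve(Xs, y, best_h, seed)
  new_seed_classifier(
    kind = "elm", fit = model, bands = bands, n_features = ncol(Xm),
    params = list(n_hidden = best_h, val_accuracy = 100 * max(acc),
                  seed = seed, scale = rng,
                  trace = tibble(n_hidden = n_hidden_range,
                                 val_accuracy = 100 * acc))
  )
}

# hidden weights from `seed` (same seed + same h => identical weights)
elm_solve <- function(Xs, y, n_hidden, seed) {
  p <- ncol(Xs)
  wb <- with_rng(seed, list(
    W = matrix(runif(p * n_hidden, -1, 1), p, n_hidden),
    b = runif(n_hidden, -1, 1)
  ))
  H <- cbind(1, elm_hidden(Xs, wb$W, wb$b))  # output bias column
  target <- cbind(as.numeric(y == 1L), as.numeric(y == 2L))
  B <- MASS::ginv(H) %*% target
  list(W = wb$W, b = wb$b, B = B, n_hidden = n_hidden, seed = seed)
}

elm_hidden <- function(Xs, W, b) {
  A <- Xs %*% W
  A <- sweep(A, 2L, b, "+")
  1 / (1 + exp(-A))
}

elm_predict <- function(model, Xs) {
  out <- cbind(1, elm_hidden(Xs, model$W, model$b)) %*% model$B
  ifelse(out[, 2L] > out[, 1L], 2L, 1L)
}

minmax_scale <- function(X, rng) {
  span <- rng$max - rng$min
  span[span == 0] <- 1
  Xs <- sweep(X, 2L, rng$min)
  Xs <- sweep(Xs, 2L, span, "/")
  pmin(pmax(Xs, -0.5), 1.5)  # clamp mild extrapolation outside cal range
}

new_seed_classifier <- function(kind, fit, bands, n_features, params) {
  structure(
    list(kind = kind, fit = fit, bands = bands, n_features = n_features,
         params = params),
    class = "seed_classifier"
  )
}

#' @export
print.seed_classifier <- function(x, ...) {
  if (x$kind == "svm") {
    cat(sprintf("<seed_classifier/svm> c = %g, g = %g (CV accuracy %.2f%%)\n",
                x$params$c, x$params$g, x$params$cv_accuracy))
  } else {
    cat(sprintf("<seed_classifier/elm> %d hidden nodes (val accuracy %.2f%%)\n",
                x$params$n_hidden, x$params$val_accuracy))
  }
  cat(sprintf("  features: %d%s\n", x$n_features,
              if (is.null(x$bands)) " (full spectrum)" else " (selected bands)"))
  invisible(x)
}

#' Predict seed classes
#'
#' @param object a `seed_classifier`.
#' @param newdata a [spectral_dataset()] or numeric matrix; full-spectrum
#'   matrices are restricted to the model's bands automatically.
#' @param ... unused.
#' @return Integer labels (1 = wild type, 2 = mutant).
#' @export
predict.seed_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_dataset") ||
           (is.data.frame(newdata) && "spectra" %in% names(newdata))) {
    spectral_matrix(newdata)
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != object$n_features) {
    X <- restrict_bands(X, object$bands)
    if (ncol(X) != object$n_features) {
      abort(sprintf("model expects %d features, data provide %d.",
                    object$n_features, ncol(X)))
    }
  }
  if (object$kind == "svm") {
    as.integer(as.character(predict(object$fit, X)))
  } else {
    Xs <- minmax_scale(X, object$params$scale)
    elm_predict(object$fit, Xs)
  }
}

#' Accuracy report on calibration and prediction sets
#'
#' `evaluate()` computes per-set accuracies (`100 * correct / total`) and
#' confusion tables; `evaluate_split()` is the tidy wrapper taking a
#' [ks_split()] dataset. Reports print accuracies to two decimals.
#'
#' @param model a fitted `seed_classifier`.
#' @param Xcal,ycal,Xpred,ypred calibration / prediction data and labels.
#' @return An `eval_report`: `accuracy_cal`, `accuracy_pred`,
#'   `confusion_cal`, `confusion_pred`, `params`.
#' @export
evaluate <- function(model, Xcal, ycal, Xpred, ypred) {
  pc <- predict(model, Xcal)
  pp <- predict(model, Xpred)
  conf <- function(truth, pred) {
    table(truth = factor(truth, c(1L, 2L)), pred = factor(pred, c(1L, 2L)))
  }
  structure(
    list(
      accuracy_cal = 100 * mean(pc == ycal),
      accuracy_pred = 100 * mean(pp == ypred),
      confusion_cal = conf(ycal, pc),
      confusion_pred = conf(ypred, pp),
      n_cal = length(ycal), n_pred = length(ypred),
      kind = model$kind, params = model$params
    ),
    class = "eval_report"
  )
}

#' @rdname evaluate
#' @param ds_split a dataset with a `set` column from [ks_split()].
#' @export
evaluate_split <- function(model, ds_split) {
  cal <- calibration_set(ds_split)
  pred <- prediction_set(ds_split)
  evaluate(model, spectral_matrix(cal), cal$class,
           spectral_matrix(pred), pred$class)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report/%s> calibration %.2f%% (n=%d), prediction %.2f%% (n=%d)\n",
              x$kind, x$accuracy_cal, x$n_cal, x$accuracy_pred, x$n_pred))
  invisible(x)
}

#' @rdname evaluate
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(
    set = c("calibration", "prediction"),
    n = c(x$n_cal, x$n_pred),
    accuracy = c(x$accuracy_cal, x$accuracy_pred)
  )
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    model = x$kind,
    accuracy_cal = x$accuracy_cal,
    accuracy_pred = x$accuracy_pred,
    n_cal = x$n_cal,
    n_pred = x$n_pred
  )
}

resolve_xy <- function(X, y) {
  if (inherits(X, "spectral_dataset") ||
      (is.data.frame(X) && "spectra" %in% names(X))) {
    list(X = spectral_matrix(X), y = as.integer(X$class))
  } else {
    if (is.null(y)) abort("`y` must be supplied with a matrix `X`.")
    list(X = as.matrix(X), y = as.integer(y))
  }
}

restrict_bands <- function(X, bands) {
  if (is.null(bands)) return(X)
  X[, band_indices(bands, ncol(X)), drop = FALSE]
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2L) {
    abort("both classes must be present in the training labels.")
  }
}

stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}
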