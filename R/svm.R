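#' SVM grid-search configuration
#'
#' The canonical log-scale grid for the RBF penalty `c` and kernel width
#' `g`: candidate values are `base^e` for exponents `e` from `exp_range[1]`
#' to `exp_range[2]` in steps of `step`, for both parameters. The defaults
#' (-10..10, step 0.2, base 2) give 101 values per axis, 10201 pairs,
#' evaluated by stratified k-fold cross-validation.
#'
#' @param exp_range length-2 exponent bounds (ordered).
#' @param step exponent step (> 0).
#' @param base grid base (default 2, the libsvm convention).
#' @param folds number of CV folds (>= 2).
#' @return An `SVMGridConfig`.
#' @export
svm_grid_config <- function(exp_range = c(-10, 10), step = 0.2, base = 2,
                            folds = 5L) {
  stopifnot(length(exp_range) == 2, exp_range[1] <= exp_range[2], step > 0,
            folds >= 2)
  structure(list(exp_range = exp_range, step = step, base = base,
                 folds = as.integer(folds)), class = "SVMGridConfig")
}

#' Candidate (c, g) values of a grid config
#' @param cfg an [svm_grid_config()].
#' @return list with `exponents`, `values` (one axis; both axes share it).
#' @export
svm_grid <- function(cfg) {
  e <- seq(cfg$exp_range[1], cfg$exp_range[2], by = cfg$step)
  list(exponents = e, values = cfg$base^e)
}

# encode a category factor/character as +1 (target) / -1 (non-target)
encode_pm1 <- function(y) {
  y <- as.character(y)
  lv <- sort(unique(y))
  if (length(lv) < 2) stop("training data contains a single class")
  if (length(lv) > 2) stop("binary classifier got >2 classes")
  pos <- if ("target" %in% lv) "target" else lv[2]
  ifelse(y == pos, 1L, -1L)
}

svm_fit_kernel <- function(K, y_pm, C) {
  cpp_smo_train(K, as.integer(y_pm), C)
}

#' Fit a binary RBF-kernel SVM
#'
#' C-SVC solved by sequential minimal optimization on the full kernel
#' matrix `K(x, z) = exp(-g ||x - z||^2)`.
#'
#' @param x numeric matrix (rows = samples). Standardize beforehand (the
#'   higher-level [train_classifier()] does).
#' @param y labels, two classes; `"target"` is the positive class when
#'   present.
#' @param C penalty parameter.
#' @param gamma RBF kernel parameter g.
#' @return An `svm_model` (support vectors, coefficients, intercept).
#' @export
svm_fit <- function(x, y, C = 1, gamma = 1 / ncol(x)) {
  x <- as.matrix(x)
  y_pm <- encode_pm1(y)
  D <- cpp_sqdist(x, x)
  K <- exp(-gamma * D)
  sol <- svm_fit_kernel(K, y_pm, C)
  sv <- which(sol$alpha > 1e-8)
  lv <- sort(unique(as.character(y)))
  pos <- if ("target" %in% lv) "target" else lv[2]
  structure(list(sv = x[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * y_pm[sv], b = sol$b, C = C,
                 gamma = gamma, positive = pos,
                 negative = setdiff(lv, pos)[1]), class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, decision = FALSE, ...) {
  newdata <- as.matrix(newdata)
  Kt <- exp(-object$gamma * cpp_sqdist(newdata, object$sv))
  f <- drop(Kt %*% object$coef) + object$b
  if (decision) return(f)
  ifelse(f >= 0, object$positive, object$negative)
}

# stratified fold assignment (1..folds per row)
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    if (length(i) < folds)
      stop("a class has fewer rows than CV folds")
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

#' Cross-validated grid search for the RBF SVM
#'
#' Evaluates every (c, g) pair of the grid by stratified k-fold
#' cross-validation accuracy and returns the argmax; ties break toward the
#' smallest `c`, then the smallest `g`. The squared-distance matrix is
#' computed once and reused across the grid.
#'
#' @param x numeric matrix (standardized), `y` two-class labels.
#' @param y labels.
#' @param cfg an [svm_grid_config()].
#' @param seed RNG seed for the fold assignment.
#' @return list with `c`, `g`, `cv_accuracy`, and the full `surface`
#'   (accuracy matrix, rows = c values, cols = g values).
#' @export
grid_search_svm <- function(x, y, cfg = svm_grid_config(), seed = 1L) {
  x <- as.matrix(x)
  y_pm <- encode_pm1(y)
  set.seed(seed)
  fold <- stratified_folds(y_pm, cfg$folds)
  vals <- svm_grid(cfg)$values
  D <- cpp_sqdist(x, x)
  surface <- matrix(NA_real_, length(vals), length(vals),
                    dimnames = list(c = format(vals), g = format(vals)))
  n <- nrow(x)
  correct <- array(0, c(length(vals), length(vals)))
  for (jg in seq_along(vals)) {
    K <- exp(-vals[jg] * D)
    for (fd in seq_len(cfg$folds)) {
      tr <- fold != fd
      Ktr <- K[tr, tr, drop = FALSE]
      Kte <- K[!tr, tr, drop = FALSE]
      ytr <- y_pm[tr]
      yte <- y_pm[!tr]
      for (jc in seq_along(vals)) {
        sol <- cpp_smo_train(Ktr, as.integer(ytr), vals[jc])
        f <- drop(Kte %*% (sol$alpha * ytr)) + sol$b
        correct[jc, jg] <- correct[jc, jg] + sum((f >= 0) == (yte == 1))
      }
    }
  }
  surface[] <- correct / n
  best <- which(surface == max(surface), arr.ind = TRUE)
  # ties: smallest c then smallest g; vals ascending so order rows then cols
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(c = vals[best[1]], g = vals[best[2]],
       cv_accuracy = max(surface), surface = surface)
}
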