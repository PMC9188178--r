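#' Fit a single-hidden-layer perceptron (sigmoid hidden, softmax output)
#'
#' Binary classifier trained by full-batch Adam on the cross-entropy loss
#' with a small L2 penalty. When the training set is large enough a 10%
#' stratified slice is held out for early stopping (best-weights restore).
#'
#' @param x numeric matrix (standardized by [train_classifier()]).
#' @param y two-class labels; `"target"` is positive when present.
#' @param hidden hidden-layer width (default 32).
#' @param epochs maximum epochs (default 400).
#' @param lr Adam learning rate.
#' @param l2 L2 penalty on weights.
#' @param val_fraction early-stopping slice (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for initialization and the validation slice.
#' @return An `mlp_model`.
#' @export
mlp_fit <- function(x, y, hidden = 32L, epochs = 400L, lr = 0.01,
                    l2 = 1e-4, val_fraction = 0.1, patience = 40L,
                    seed = 1L) {
  x <- as.matrix(x)
  y_pm <- encode_pm1(y)
  lv <- sort(unique(as.character(y)))
  pos <- if ("target" %in% lv) "target" else lv[2]
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)

  val_idx <- integer(0)
  if (val_fraction > 0 && n >= 20) {
    for (cl in c(-1L, 1L)) {
      i <- which(y_pm == cl)
      nv <- floor(length(i) * val_fraction)
      if (nv >= 1) val_idx <- c(val_idx, sample(i, nv))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- x[tr_idx, , drop = FALSE]
  Ttr <- cbind(y_pm[tr_idx] == -1, y_pm[tr_idx] == 1) * 1  # one-hot
  Xva <- x[val_idx, , drop = FALSE]
  yva <- y_pm[val_idx]

  W1 <- matrix(rnorm(p * hidden, sd = sqrt(1 / p)), p, hidden)
  b1 <- rep(0, hidden)
  W2 <- matrix(rnorm(hidden * 2, sd = sqrt(1 / hidden)), hidden, 2)
  b2 <- rep(0, 2)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(z) z * 0)
  v <- lapply(params, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsd <- 1e-8
  best <- list(err = Inf, params = params, since = 0L)

  sigmoid <- function(z) 1 / (1 + exp(-z))
  ntr <- nrow(Xtr)
  for (ep in seq_len(epochs)) {
    H <- sigmoid(sweep(Xtr %*% params$W1, 2, params$b1, `+`))
    S <- sweep(H %*% params$W2, 2, params$b2, `+`)
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    dS <- (P - Ttr) / ntr
    g <- list(W1 = NULL, b1 = NULL,
              W2 = crossprod(H, dS) + l2 * params$W2, b2 = colSums(dS))
    dH <- (dS %*% t(params$W2)) * H * (1 - H)
    g$W1 <- crossprod(Xtr, dH) + l2 * params$W1
    g$b1 <- colSums(dH)
    for (nm in names(params)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^ep)
      vhat <- v[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsd)
    }
    if (length(val_idx)) {
      Hv <- sigmoid(sweep(Xva %*% params$W1, 2, params$b1, `+`))
      Sv <- sweep(Hv %*% params$W2, 2, params$b2, `+`)
      # validation cross-entropy (continuous, unlike 0/1 error)
      z <- (Sv[, 2] - Sv[, 1]) * yva
      err <- mean(log1p(exp(-abs(z))) + pmax(-z, 0))
      if (err < best$err - 1e-12) {
        best <- list(err = err, params = params, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= patience) { params <- best$params; break }
      }
    }
  }
  if (length(val_idx) && best$err < Inf) params <- best$params
  structure(c(params, list(positive = pos, negative = setdiff(lv, pos)[1],
                           hidden = hidden)), class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, prob = FALSE, ...) {
  X <- as.matrix(newdata)
  H <- 1 / (1 + exp(-sweep(X %*% object$W1, 2, object$b1, `+`)))
  S <- sweep(H %*% object$W2, 2, object$b2, `+`)
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  if (prob) return(P[, 2])
  ifelse(P[, 2] >= P[, 1], object$positive, object$negative)
}
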