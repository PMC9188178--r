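#' Successive projections chain from one start band
#'
#' Builds a chain of low-collinearity bands: starting from `start`, each step
#' picks the band whose (mean-centered) column has maximal norm after
#' orthogonal projection onto the complement of the span of the columns
#' already chosen. Ties break toward the lowest band index. If the requested
#' length exceeds the achievable rank the chain is truncated with a warning.
#'
#' @param X numeric matrix, seeds x bands.
#' @param start 1-based start band index.
#' @param k chain length (1 <= k <= ncol(X)).
#' @param center mean-center columns first (default TRUE, standard practice).
#' @return Integer vector of band indices, beginning with `start`.
#' @export
spa_chain <- function(X, start, k, center = TRUE) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(start >= 1, start <= p, k >= 1, k <= p)
  if (all(abs(X) < .Machine$double.eps)) stop("X has no non-zero column")
  if (center) X <- sweep(X, 2, colMeans(X))
  res <- cpp_spa_chain(X, as.integer(start - 1), as.integer(k))
  if (isTRUE(res$truncated))
    warning(sprintf("chain truncated at length %d (rank exhausted)",
                    length(res$chain)))
  as.integer(res$chain) + 1L
}

# OLS (with intercept) of y on X[, idx]; ridge-stabilized if rank-deficient.
# Returns list(coef, ridged)
ols_fit <- function(X, y, idx) {
  B <- cbind(1, X[, idx, drop = FALSE])
  G <- crossprod(B)
  cy <- crossprod(B, y)
  ridged <- FALSE
  coef <- tryCatch(solve(G, cy), error = function(e) {
    ridged <<- TRUE
    solve(G + diag(1e-8 * max(diag(G)), nrow(G)), cy)
  })
  list(coef = coef, ridged = ridged)
}

rmse_of <- function(pred, y) sqrt(mean((pred - y)^2))

#' SPA characteristic-wavelength selection
#'
#' For every start band and every subset size in `[k_min, k_max]`, fits an
#' ordinary least squares model of the numeric response on the chain prefix
#' (fit on the training rows) and computes validation RMSE. Returns the
#' subset minimizing validation RMSE; ties break toward smaller subset size,
#' then lexicographically smaller sorted index set. For binary genuineness
#' screening the response is the 0/1 category label.
#'
#' @param X_train,y_train training spectra (seeds x bands) and numeric
#'   response (target = 1, non-target = 0).
#' @param X_val,y_val held-out validation rows (disjoint from training).
#' @param k_min,k_max subset-size range; `k_max` is capped at
#'   `min(nrow(X_train) - 2, ncol(X_train))`.
#' @param wavelengths optional band centers in nm for reporting.
#' @return An `SPAResult`: list with `selected` (indices), `selected_nm`,
#'   `rmse` (winning validation RMSE), `rmse_path` (RMSE per k for the
#'   winning start), `chain_store` (chain per start), `ridged` flag.
#' @export
spa_select <- function(X_train, y_train, X_val, y_val, k_min = 1,
                       k_max = 30, wavelengths = NULL) {
  X_train <- as.matrix(X_train)
  X_val <- as.matrix(X_val)
  y_train <- as.numeric(y_train)
  y_val <- as.numeric(y_val)
  p <- ncol(X_train)
  k_max <- min(k_max, nrow(X_train) - 2L, p)
  k_min <- max(1L, min(k_min, k_max))

  mu <- colMeans(X_train)
  Xc <- sweep(X_train, 2, mu)

  best <- list(rmse = Inf, k = Inf, idx = NULL, start = NA_integer_)
  chain_store <- vector("list", p)
  rmse_store <- vector("list", p)
  any_ridged <- FALSE
  for (s in seq_len(p)) {
    ch <- cpp_spa_chain(Xc, s - 1L, as.integer(k_max))
    chain <- as.integer(ch$chain) + 1L
    chain_store[[s]] <- chain
    rmses <- rep(NA_real_, length(chain))
    for (k in seq_along(chain)) {
      if (k < k_min) next
      idx <- chain[seq_len(k)]
      fit <- ols_fit(X_train, y_train, idx)
      any_ridged <- any_ridged || fit$ridged
      pred <- cbind(1, X_val[, idx, drop = FALSE]) %*% fit$coef
      rmses[k] <- rmse_of(pred, y_val)
      better <- rmses[k] < best$rmse - 1e-12 ||
        (abs(rmses[k] - best$rmse) <= 1e-12 &&
           (k < best$k ||
              (k == best$k && lex_less(sort(idx), sort(best$idx)))))
      if (better)
        best <- list(rmse = rmses[k], k = k, idx = idx, start = s)
    }
    rmse_store[[s]] <- rmses
  }
  selected <- best$idx
  structure(list(
    selected = selected,
    selected_nm = if (is.null(wavelengths)) NULL else wavelengths[selected],
    rmse = best$rmse,
    rmse_path = rmse_store[[best$start]],
    start = best$start,
    chain_store = chain_store,
    ridged = any_ridged), class = "SPAResult")
}

lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.SPAResult <- function(x, ...) {
  cat(sprintf("SPAResult: %d bands selected, validation RMSE %.4g\n",
              length(x$selected), x$rmse))
  if (!is.null(x$selected_nm))
    cat("  nm:", paste(sprintf("%.1f", x$selected_nm), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an SPAResult
#'
#' `write_spa_json` stores indices, nm values and the RMSE path;
#' `write_spa_csv` writes a one-line CSV (`source, wavelengths_nm`) matching
#' the conventional characteristic-wavelength table layout.
#'
#' @param x an `SPAResult`.
#' @param path output path.
#' @param source label for the CSV row (e.g. `"mixed"`).
#' @export
write_spa_json <- function(x, path) {
  jsonlite::write_json(list(selected = x$selected,
                            selected_nm = x$selected_nm, rmse = x$rmse,
                            rmse_path = x$rmse_path),
                       path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spa_json
#' @export
write_spa_csv <- function(x, path, source = "mixed") {
  nm <- if (is.null(x$selected_nm)) x$selected else x$selected_nm
  df <- data.frame(source = source,
                   wavelengths_nm = paste(sprintf("%.1f", nm),
                                          collapse = ", "))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
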