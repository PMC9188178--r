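# spa: projection chains and RMSE-minimizing wavelength selection

# independent straight-line oracle for the chain recursion: residual norm of
# each candidate after projecting out span(chosen) via an explicit QR solve
oracle_chain <- function(X, start, k, center = TRUE) {
  if (center) X <- sweep(X, 2, colMeans(X))
  chosen <- start
  while (length(chosen) < k) {
    A <- X[, chosen, drop = FALSE]
    resid_norm <- vapply(seq_len(ncol(X)), function(j) {
      if (j %in% chosen) return(-1)
      r <- X[, j] - A %*% qr.solve(crossprod(A) +
                                     diag(1e-12, ncol(A)),
                                   crossprod(A, X[, j]))
      sqrt(sum(r^2))
    }, numeric(1))
    if (max(resid_norm) < 1e-9) break
    chosen <- c(chosen, which.max(resid_norm))
  }
  chosen
}

# exhaustive best-subset validation RMSE over all subsets of sizes in `ks`
oracle_best_subset <- function(Xtr, ytr, Xva, yva, ks) {
  best <- list(rmse = Inf, idx = NULL)
  for (k in ks) {
    for (idx in utils::combn(ncol(Xtr), k, simplify = FALSE)) {
      B <- cbind(1, Xtr[, idx, drop = FALSE])
      cf <- qr.solve(crossprod(B) + diag(1e-10, ncol(B)),
                     crossprod(B, ytr))
      r <- sqrt(mean((cbind(1, Xva[, idx, drop = FALSE]) %*% cf - yva)^2))
      if (r < best$rmse) best <- list(rmse = r, idx = idx)
    }
  }
  best
}

test_that("orthogonal columns: projections keep norms, largest wins", {
  X <- rbind(diag(c(3, 2, 1)), 0)
  expect_equal(spa_chain(X, start = 2, k = 2, center = FALSE), c(2L, 1L))
  expect_equal(spa_chain(X, start = 3, k = 3, center = FALSE),
               c(3L, 1L, 2L))
})

test_that("a duplicated column is never selected after its copy", {
  set.seed(1)
  X <- matrix(rnorm(8 * 5), 8)
  X <- cbind(X, X[, 2])  # column 6 duplicates column 2
  for (k in 2:4) {
    ch <- spa_chain(X, start = 2, k = k)
    expect_false(6L %in% ch)
  }
  expect_warning(spa_chain(cbind(X[, 1], X[, 1], X[, 1]), 1, 3),
                 "truncated")
})

test_that("chains match the brute-force projection oracle", {
  set.seed(42)
  for (rep in 1:20) {
    X <- matrix(rnorm(8 * 6), 8)
    for (s in 1:6)
      expect_equal(spa_chain(X, s, 3), as.integer(oracle_chain(X, s, 3)),
                   info = sprintf("rep %d start %d", rep, s))
  }
})

test_that("noise-free linear targets are recovered exactly", {
  set.seed(3)
  # support columns get dominant norms so the optimum is chain-reachable
  # (SPA only ever sees subsets reachable by its projection chains)
  scl <- c(1, 4, 1, 1, 3, rep(1, 5))
  Xtr <- sweep(matrix(rnorm(40 * 10), 40), 2, scl, `*`)
  Xva <- sweep(matrix(rnorm(20 * 10), 20), 2, scl, `*`)
  f <- function(X) 1 + 2 * X[, 2] - 3 * X[, 5]
  res <- spa_select(Xtr, f(Xtr), Xva, f(Xva), k_min = 1, k_max = 3,
                    wavelengths = seq(400, 850, by = 50))
  expect_lt(res$rmse, 1e-8)
  expect_setequal(res$selected, c(2L, 5L))
  expect_equal(sort(res$selected_nm), c(450, 600))
  # matches the exhaustive-subset oracle
  orc <- oracle_best_subset(Xtr, f(Xtr), Xva, f(Xva), 1:3)
  expect_equal(res$rmse, orc$rmse, tolerance = 1e-8)
  # rmse_path of the winning start is non-increasing here
  path <- res$rmse_path[!is.na(res$rmse_path)]
  expect_true(all(diff(path) <= 1e-9))
})

test_that("k_min = k_max = 1 picks the single informative band", {
  set.seed(4)
  Xtr <- matrix(rnorm(60 * 8, sd = 1), 60)
  ytr <- Xtr[, 6] * 2
  Xva <- matrix(rnorm(30 * 8), 30)
  yva <- Xva[, 6] * 2
  res <- spa_select(Xtr, ytr, Xva, yva, k_min = 1, k_max = 1)
  expect_equal(res$selected, 6L)
})

test_that("selection concentrates at the discriminative absorption peak", {
  tgt <- variety_spec(scatter_sigma = 0, lot_sigma = 0)
  alt <- tgt
  alt$bands$depth[1] <- alt$bands$depth[1] + 0.05  # protein band at 450 nm
  alt$name <- "shifted"
  grid <- seq(400, 1000, by = 10)
  a <- simulate_spectra(tgt, 2, 30, grid, seed = 1, category = "target")
  b <- simulate_spectra(alt, 2, 30, grid, seed = 2)
  st <- bind_spectra(a, b)
  y <- as.numeric(st$meta$category == "target")
  sp <- split_dataset(st$meta, seed = 9)
  res <- spa_select(st$spectra[sp$train, ], y[sp$train],
                    st$spectra[sp$test, ], y[sp$test], k_max = 3,
                    wavelengths = grid)
  fwhm <- 2.355 * tgt$bands$width[1]
  expect_true(any(abs(res$selected_nm - 450) <= 2 * fwhm))
  # restricted to a single band, the discriminative peak must win
  r1 <- spa_select(st$spectra[sp$train, ], y[sp$train],
                   st$spectra[sp$test, ], y[sp$test], k_min = 1, k_max = 1,
                   wavelengths = grid)
  expect_true(abs(r1$selected_nm - 450) <= 2 * fwhm)
})

test_that("SPA results serialize to JSON and Table-2-style CSV", {
  set.seed(5)
  Xtr <- matrix(rnorm(30 * 6), 30)
  res <- spa_select(Xtr, Xtr[, 3], matrix(rnorm(12 * 6), 12),
                    rnorm(12), k_max = 2, wavelengths = 400 + 1:6 * 50)
  dir <- withr::local_tempdir()
  write_spa_json(res, file.path(dir, "spa.json"))
  j <- jsonlite::read_json(file.path(dir, "spa.json"),
                           simplifyVector = TRUE)
  expect_equal(j$selected, res$selected)
  write_spa_csv(res, file.path(dir, "spa.csv"), source = "germ")
  expect_equal(read.csv(file.path(dir, "spa.csv"))$source, "germ")
})
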