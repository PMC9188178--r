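# Shared fixtures, built in code at test time.

# deterministic little cube: values are a known function of (r, c, b)
tiny_cube <- function(nr = 10, nc = 10, wl = c(400, 500, 600, 700, 800)) {
  a <- array(0, c(nr, nc, length(wl)))
  for (b in seq_along(wl))
    a[, , b] <- outer(seq_len(nr), seq_len(nc),
                      function(r, c) (r + 2 * c + 10 * b) / 100)
  hypercube(a, wl)
}

# flat background + rectangular "seed" blobs with given per-blob spectra
blob_cube <- function(blobs, nr = 30, nc = 30,
                      wl = c(450, 550, 650, 750), background = 0.05) {
  a <- array(background, c(nr, nc, length(wl)))
  for (blob in blobs) {
    rr <- blob$rows; cc <- blob$cols
    for (b in seq_along(wl)) a[rr, cc, b] <- blob$spectrum[b]
  }
  hypercube(a, wl)
}

# linearly separable 2-D blobs
sep_data <- function(n_per = 30, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = gap), ncol = 2))
  list(x = x, y = rep(c("target", "non-target"), each = n_per))
}

# draw a filled disc in an RGB image; returns list(image, mask)
disc_image <- function(radius = 20, pad = 8, col = c(0.5, 0.5, 0.5)) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  inside <- outer(seq_len(n), seq_len(n),
                  function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
  img <- array(0, c(n, n, 3))
  for (k in 1:3) img[, , k][inside] <- col[k]
  list(image = img, mask = seed_mask(matrix(as.integer(inside), n, n)),
       inside = inside)
}

# small two-class spectrum table for classifier tests
small_scenario <- function(seed = 1, d = 0.08, lots = 3, per_lot = 12,
                           n_varieties = 3, grid = seq(400, 1000, 20)) {
  cfg <- scenario_config(n_target_lots = lots, seeds_per_lot = per_lot,
                         nontarget_divergence = rep(d, n_varieties))
  suppressWarnings(simulate_scenario(cfg, seed = seed, grid = grid))$train
}

# coarse-but-honest SVM settings for runtime-bounded tests
fast_svm_cfg <- function() list(grid = svm_grid_config(c(-8, 8), 4,
                                                       folds = 3))
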