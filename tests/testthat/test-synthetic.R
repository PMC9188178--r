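# synthetic_data: variety specs, spectra, hypercubes, feature tables

test_that("make_variety_spec is the identity at d = 0 and linear in d", {
  tgt <- variety_spec()
  expect_identical(make_variety_spec(tgt, 0, seed = 1, name = tgt$name),
                   tgt)
  grid <- seq(400, 1000, 4)
  d1 <- make_variety_spec(tgt, 0.02, seed = 9)
  d2 <- make_variety_spec(tgt, 0.04, seed = 9)
  dist1 <- sqrt(sum((mean_spectrum(d1, grid) -
                       mean_spectrum(tgt, grid))^2))
  dist2 <- sqrt(sum((mean_spectrum(d2, grid) -
                       mean_spectrum(tgt, grid))^2))
  expect_equal(dist2 / dist1, 2, tolerance = 1e-12)
  expect_identical(make_variety_spec(tgt, 0.02, seed = 9),
                   make_variety_spec(tgt, 0.02, seed = 9))
  expect_error(make_variety_spec(tgt, -1), "d >= 0")
})

test_that("noise-free lots share one exact curve; all reflectance < 0.8", {
  spec <- variety_spec(lot_sigma = 0, seed_sigma = 0, scatter_sigma = 0)
  st <- simulate_spectra(spec, 2, 5, seq(400, 1000, 10), seed = 1)
  expect_equal(nseeds(st), 10)
  expect_equal(max(apply(st$spectra, 2, function(v) diff(range(v)))), 0)
  expect_equal(unname(st$spectra[1, ]),
               mean_spectrum(spec, seq(400, 1000, 10)))

  big <- suppressWarnings(
    simulate_spectra(variety_spec(), 9, 35, seq(400, 1000, 4), seed = 2))
  expect_true(all(big$spectra < 0.8))
  expect_true(all(big$spectra > 0))
})

test_that("empirical mean converges to the analytic mean (LLN)", {
  spec <- variety_spec(lot_sigma = 0)  # scatter + smooth noise only
  grid <- seq(400, 1000, 10)
  n <- 10000
  st <- simulate_spectra(spec, 1, n, grid, seed = 3)
  sigma_tot <- sqrt(spec$scatter_sigma^2 + spec$seed_sigma^2)
  dev <- abs(colMeans(st$spectra) - mean_spectrum(spec, grid))
  # per-band 3-sigma bound can fail ~0.3% of bands by chance; allow that,
  # and bound everything at 5 sigma
  expect_gte(mean(dev <= 3 * sigma_tot / sqrt(n)), 0.99)
  expect_true(all(dev <= 5 * sigma_tot / sqrt(n)))
})

test_that("generation is reproducible from (config, seed)", {
  cfg <- scenario_config(n_target_lots = 2, seeds_per_lot = 4,
                         nontarget_divergence = c(0.02, 0.05))
  a <- simulate_scenario(cfg, seed = 5, grid = seq(400, 1000, 20))
  b <- simulate_scenario(cfg, seed = 5, grid = seq(400, 1000, 20))
  expect_identical(a$train$spectra, b$train$spectra)
  c_ <- simulate_scenario(cfg, seed = 6, grid = seq(400, 1000, 20))
  expect_false(identical(a$train$spectra, c_$train$spectra))
})

test_that("scenario configs serialize to JSON and back", {
  cfg <- scenario_config(seeds_per_lot = 7,
                         nontarget_divergence = c(0.01, 0.02),
                         n_external_target_lots = 1,
                         external_divergence = 0.03)
  p <- file.path(withr::local_tempdir(), "scenario.json")
  write_scenario_json(cfg, p)
  back <- read_scenario_json(p)
  expect_equal(back$seeds_per_lot, 7)
  expect_equal(back$nontarget_divergence, c(0.01, 0.02))
  a <- simulate_scenario(cfg, seed = 2, grid = seq(400, 1000, 50))
  b <- simulate_scenario(back, seed = 2, grid = seq(400, 1000, 50))
  expect_equal(a$train$spectra, b$train$spectra)
  expect_equal(nseeds(a$external), nseeds(b$external))
})

test_that("hypercube simulation provides exact ground truth", {
  sim <- simulate_hypercube(variety_spec(), n_seeds = 4, seed = 1)
  expect_equal(sim$mask$n_seeds, 4)
  expect_equal(nseeds(sim$table), 4)
  expect_setequal(unique(as.vector(sim$mask$labels)), 0:4)
  # footprints too large for the canvas must error, not overlap
  expect_error(simulate_hypercube(variety_spec(), n_seeds = 9,
                                  image_size = c(20, 20)),
               "do not fit")
})

test_that("feature-table effects control per-feature overlap", {
  zero <- simulate_feature_table(300, effect = 0, seed = 1)
  rep0 <- feature_overlap_report(zero)
  # KDE overlap of two n=300 same-distribution samples: simulated null
  # minimum over 200 reps is ~0.885, mean ~0.93 (sampling tolerance of
  # this estimator)
  expect_true(all(rep0$overlap > 0.85))
  expect_gt(median(rep0$overlap), 0.92)

  shifted <- simulate_feature_table(300, effect = c(R_mean = 6), seed = 1)
  rep6 <- feature_overlap_report(shifted)
  expect_lt(rep6$overlap[rep6$feature == "R_mean"], 0.05)
  expect_true(all(rep6$overlap[rep6$feature != "R_mean"] > 0.8))

  expect_identical(simulate_feature_table(50, seed = 4),
                   simulate_feature_table(50, seed = 4))
  expect_error(simulate_feature_table(10, effect = c(bogus = 1)),
               "unknown features")
})
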