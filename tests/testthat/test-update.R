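# update: external verification and the active-learning loop

# train table + external panel where 3 "confusable" varieties share one
# spectral-shift direction absent from training (low initial recognition)
# and 2 easy varieties plus held-out target lots verify near-perfectly
confusable_scenario <- function(seed, grid = seq(400, 1000, 8),
                                lots = 4, per_lot = 20) {
  cfg <- scenario_config(n_target_lots = lots, seeds_per_lot = per_lot,
                         nontarget_divergence = rep(0.08, 3))
  sim <- suppressWarnings(simulate_scenario(cfg, seed = seed, grid = grid))
  tgt <- cfg$target
  shared_dir_seed <- 424242L  # one direction shared by the confusables
  ext <- list()
  et <- simulate_spectra(tgt, 2, per_lot, grid, seed = seed + 31L,
                         category = "target")
  et$meta$variety <- "target_ext"
  ext[[1]] <- et
  for (i in 1:3) {
    sp <- make_variety_spec(tgt, d = 0.020 + 0.004 * i,
                            seed = shared_dir_seed,
                            name = paste0("confusable_", i))
    ext[[i + 1]] <- simulate_spectra(sp, 1, per_lot, grid,
                                     seed = seed + 100L + i,
                                     category = "non-target")
  }
  for (i in 1:2) {
    # same divergence directions as training varieties, further out:
    # reliably recognized non-targets (the distant-hybrid analog)
    sp <- make_variety_spec(tgt, d = 0.12, seed = seed * 1000L + i,
                            name = paste0("easy_", i))
    ext[[i + 4]] <- suppressWarnings(
      simulate_spectra(sp, 1, per_lot, grid, seed = seed + 200L + i,
                       category = "non-target"))
  }
  list(train = sim$train, external = do.call(bind_spectra, ext))
}

mlp_spec <- function() list(algorithm = "mlp",
                            config = list(hidden = 16, epochs = 200))

test_that("verify_external scores per variety with schema checks", {
  st <- small_scenario(seed = 1, d = 0.15)
  mf <- model_frame(st)
  model <- train_classifier("svm", mf$x, mf$category,
                            config = list(c = 8, g = 0.05), seed = 1)
  # a non-target variety identical to the target: everything called target
  tgt <- scenario_config()$target
  clone <- simulate_spectra(tgt, 1, 35, seq(400, 1000, 20), seed = 5,
                            category = "non-target")
  clone$meta$variety <- "imitation"
  ver <- verify_external(model, clone)
  expect_equal(unname(ver$per_variety["imitation"]), 0)
  expect_equal(unname(ver$n["imitation"]), 35L)

  # a perfect panel: target seeds from known lots plus a distant variety
  far <- suppressWarnings(simulate_spectra(
    make_variety_spec(tgt, 0.3, seed = 2, name = "far"), 1, 20,
    seq(400, 1000, 20), seed = 6, category = "non-target"))
  # trivially perfect case: target seeds the model has already seen
  own <- subset_rows(st, which(st$meta$category == "target")[1:20])
  own$meta$variety <- "target_ext"
  ver2 <- verify_external(model, bind_spectra(own, far))
  expect_equal(unname(ver2$per_variety), c(1, 1))
  expect_equal(ver2$average, 1)

  wrong <- spectrum_table(matrix(0.5, 4, 3), c(500, 600, 700),
                          data.frame(category = rep("target", 4)))
  expect_error(verify_external(model, wrong), "schema")
})

test_that("no-op and boundary paths of active_update", {
  sc <- confusable_scenario(seed = 2)
  # a panel the model already recognizes (drawn from the training lots):
  # nothing to absorb, loop must halt immediately with the model unchanged
  easy_only <- subset_rows(sc$train, seq(1, nseeds(sc$train), by = 3))
  up <- active_update(mlp_spec(), sc$train, easy_only, seed = 1)
  expect_equal(attr(up$log, "status"), "reached_stop")
  expect_equal(nrow(up$log), 1)
  expect_true(is.na(up$log$variety_added[1]))

  up0 <- active_update(mlp_spec(), sc$train, sc$external, max_iter = 0,
                       seed = 1)
  expect_equal(nrow(up0$log), 0)
  expect_s3_class(up0$model, "TrainedModel")
})

test_that("the loop absorbs sub-trigger varieties and conserves seeds", {
  sc <- confusable_scenario(seed = 3)
  up <- active_update(mlp_spec(), sc$train, sc$external, max_iter = 4,
                      seed = 2)
  log <- up$log
  absorbed <- log$variety_added[!is.na(log$variety_added)]
  expect_gte(length(absorbed), 1)
  expect_false(any(duplicated(absorbed)))
  expect_true(all(grepl("confusable", absorbed)))
  # absorbed varieties leave the external pool
  expect_equal(diff(log$n_external[!is.na(log$average_accuracy)]) <= 0,
               rep(TRUE, nrow(log) - 1))
  # each absorption moves exactly that variety's seeds (20 per variety)
  expect_true(all(log$n_added[!is.na(log$variety_added)] == 20))
  hist <- attr(log, "per_variety")
  for (i in seq_along(absorbed))
    expect_false(absorbed[i] %in% names(hist[[i + 1]]))
  expect_true(attr(log, "status") %in%
                c("reached_stop", "stalled", "max_iter",
                  "no_external_left"))
})

test_that("stalled status when nothing is below trigger but stop unmet", {
  sc <- confusable_scenario(seed = 4)
  up <- active_update(mlp_spec(), sc$train, sc$external, trigger = 0.001,
                      stop_at = 1.01, max_iter = 3, seed = 1)
  expect_equal(attr(up$log, "status"), "stalled")
})

test_that("random selection among sub-trigger varieties is seeded", {
  sc <- confusable_scenario(seed = 5)
  a <- active_update(mlp_spec(), sc$train, sc$external, max_iter = 1,
                     seed = 3, selection = "random")
  b <- active_update(mlp_spec(), sc$train, sc$external, max_iter = 1,
                     seed = 3, selection = "random")
  expect_identical(a$log$variety_added, b$log$variety_added)
})

test_that("update logs serialize to CSV + JSON", {
  sc <- confusable_scenario(seed = 6)
  up <- active_update(mlp_spec(), sc$train, sc$external, max_iter = 1,
                      seed = 1)
  base <- file.path(withr::local_tempdir(), "log")
  write_update_log(up$log, base)
  expect_true(file.exists(paste0(base, ".csv")))
  j <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(j$status, attr(up$log, "status"))
})
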