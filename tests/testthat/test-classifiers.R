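# classifiers: splits, grid search, rf/svm/mlp training, evaluation protocol

test_that("3:1 stratified split follows the round(n/4) rule", {
  meta <- data.frame(category = rep("target", 8))
  sp <- split_dataset(meta, seed = 1)
  expect_equal(length(sp$train), 6)
  expect_equal(length(sp$test), 2)

  meta2 <- data.frame(category = rep(c("target", "non-target"),
                                     each = 315))
  sp2 <- split_dataset(meta2, seed = 2)
  expect_equal(length(sp2$train), 472)
  expect_equal(length(sp2$test), 158)
  for (cl in c("target", "non-target"))
    expect_equal(sum(meta2$category[sp2$test] == cl), 79)
  expect_length(intersect(sp2$train, sp2$test), 0)
  expect_setequal(c(sp2$train, sp2$test), 1:630)

  expect_identical(split_dataset(meta2, seed = 7),
                   split_dataset(meta2, seed = 7))
  expect_false(identical(split_dataset(meta2, seed = 7)$test,
                         split_dataset(meta2, seed = 8)$test))
  expect_error(split_dataset(data.frame(category = c("a", "b", "b")),
                             stratify_by = "category"), "fewer than 2")
})

test_that("default SVM grid is 101 x 101 pairs of 2^e values", {
  g <- svm_grid(svm_grid_config())
  expect_length(g$exponents, 101)
  expect_equal(g$exponents[1], -10)
  expect_equal(g$exponents[101], 10)
  expect_equal(g$exponents[2] - g$exponents[1], 0.2)
  expect_equal(g$values, 2^g$exponents)
  expect_equal(length(g$values)^2, 10201)
  expect_error(svm_grid_config(step = 0), "step")
})

test_that("grid search is perfect on separable blobs, chance on noise", {
  d <- sep_data(30, gap = 8, seed = 1)
  gs <- grid_search_svm(d$x, d$y, svm_grid_config(c(-4, 4), 2, folds = 3),
                        seed = 1)
  expect_equal(gs$cv_accuracy, 1)
  expect_equal(dim(gs$surface), c(5, 5))

  # label permutation null: best-of-grid CV accuracy stays near chance
  set.seed(11)
  x <- matrix(rnorm(200 * 4), 200)
  for (rep in 1:2) {
    y <- sample(rep(c("target", "non-target"), each = 100))
    gs0 <- grid_search_svm(x, y, svm_grid_config(c(-6, 6), 3, folds = 5),
                           seed = rep)
    expect_gte(gs0$cv_accuracy, 0.4)
    expect_lte(gs0$cv_accuracy, 0.7)
  }
})

test_that("all three algorithms are exact on separable data", {
  d <- sep_data(25, gap = 8, seed = 2)
  sp <- split_dataset(data.frame(category = d$y), seed = 1)
  for (alg in c("rf", "svm", "mlp")) {
    cfgm <- switch(alg, rf = list(num_trees = 100), svm = list(c = 1, g = 0.5),
                   mlp = list(hidden = 8))
    m <- train_classifier(alg, d$x[sp$train, ], d$y[sp$train],
                          config = cfgm, seed = 3)
    expect_equal(mean(predict(m, d$x[sp$test, ]) == d$y[sp$test]), 1,
                 info = alg)
  }
})

test_that("an 8-unit MLP solves jittered XOR to training accuracy 1", {
  set.seed(5)
  px <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  X <- px[rep(1:4, 50), ] + matrix(rnorm(400, 0, 0.05), 200)
  y <- ifelse(xor(px[rep(1:4, 50), 1] > 0.5, px[rep(1:4, 50), 2] > 0.5),
              "target", "non-target")
  # lr = 0.05: the small default step can park in the XOR saddle; the
  # example probes nonlinear capacity, not the default optimizer step
  accs <- vapply(1:3, function(s) {
    m <- train_classifier("mlp", X, y,
                          config = list(hidden = 8, lr = 0.05), seed = s)
    mean(predict(m, X) == y)
  }, numeric(1))
  expect_equal(mean(accs), 1)
})

test_that("training contracts: single class and NaN features error", {
  x <- matrix(rnorm(20), 10)
  expect_error(train_classifier("svm", x, rep("target", 10),
                                config = list(c = 1, g = 1)),
               "single class")
  xb <- x
  xb[3, 1] <- NaN
  expect_error(train_classifier("mlp", xb,
                                rep(c("target", "non-target"), 5)),
               "NaN")
})

test_that("prediction is schema-aware and permutation invariant", {
  d <- sep_data(20, gap = 8, seed = 3)
  colnames(d$x) <- c("wl_500", "wl_600")
  m <- train_classifier("svm", d$x, d$y, config = list(c = 1, g = 0.5),
                        seed = 1)
  p1 <- predict(m, d$x)
  p2 <- predict(m, d$x[, c(2, 1)])  # permuted columns, named
  expect_identical(p1, p2)
  expect_error(predict(m, matrix(0, 2, 3)), "schema")
})

test_that("evaluate_model implements the ten-run averaged protocol", {
  st <- small_scenario(seed = 6, d = 0.15)
  er <- evaluate_model(list(algorithm = "svm",
                            config = list(c = 8, g = 0.05)),
                      st, runs = 10, seed = 2)
  expect_length(er$run_accuracies, 10)
  expect_equal(er$accuracy, mean(er$run_accuracies))
  # pooled confusion conserves true class counts across the 10 test sets
  mf <- model_frame(st)
  n_test_per_run <- vapply(1:10, function(r)
    length(split_dataset(mf$meta, seed = 2 + r - 1)$test), integer(1))
  expect_equal(sum(er$confusion), sum(n_test_per_run))
  expect_equal(unname(rowSums(er$confusion)),
               c(sum(n_test_per_run) / 2, sum(n_test_per_run) / 2))
  expect_equal(er$accuracy, sum(diag(er$confusion)) / sum(er$confusion),
               tolerance = 0.05)

  # runs = 1 equals the manual split/train/predict composition
  e1 <- evaluate_model(list(algorithm = "svm",
                            config = list(c = 8, g = 0.05)),
                      st, runs = 1, seed = 5)
  sp <- split_dataset(mf$meta, seed = 5)
  m <- train_classifier("svm", mf$x[sp$train, ], mf$category[sp$train],
                        config = list(c = 8, g = 0.05), seed = 5)
  acc <- mean(predict(m, mf$x[sp$test, ]) == mf$category[sp$test])
  expect_equal(e1$accuracy, acc)
})

test_that("chance-level data stays at chance over repeated runs", {
  st <- small_scenario(seed = 7, d = 0, lots = 4, per_lot = 25,
                       n_varieties = 4)
  er <- evaluate_model(list(algorithm = "svm",
                            config = list(c = 2, g = 0.02)),
                      st, runs = 5, seed = 3)
  expect_gte(er$accuracy, 0.35)
  expect_lte(er$accuracy, 0.65)
})

test_that("eval reports serialize", {
  st <- small_scenario(seed = 8, d = 0.15, lots = 2, per_lot = 8,
                       n_varieties = 2)
  er <- evaluate_model(list(algorithm = "mlp",
                            config = list(hidden = 4, epochs = 50)),
                      st, runs = 2, seed = 1)
  p <- file.path(withr::local_tempdir(), "eval.json")
  write_eval_report(er, p)
  j <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(j$accuracy, er$accuracy, tolerance = 1e-12)
  expect_true(file.exists(paste0(p, ".confusion.csv")))
})
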