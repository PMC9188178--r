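#' Extract a model-ready (x, y, meta) view from a data container
#'
#' `SpectrumTable` yields the reflectance matrix (columns named by
#' wavelength); `FeatureTable` yields the 54-feature matrix; a plain list
#' with `x` and `category` passes through.
#'
#' @param data a `SpectrumTable`, `FeatureTable`, or list(x, category, ...).
#' @param surface optional surface filter: `"germ"`, `"non-germ"` or
#'   `"mixed"` (no filter; both surfaces pooled as independent samples).
#' @return list with `x` (matrix), `category` (character), `meta`
#'   (data.frame).
#' @export
model_frame <- function(data, surface = "mixed") {
  if (inherits(data, "SpectrumTable")) {
    x <- data$spectra
    meta <- data$meta
  } else if (inherits(data, "FeatureTable")) {
    x <- feature_matrix(data)
    meta <- as.data.frame(data)[c("category", "variety", "lot", "surface")]
  } else if (is.list(data) && !is.null(data$x)) {
    x <- as.matrix(data$x)
    meta <- if (!is.null(data$meta)) data$meta
            else data.frame(category = data$category)
    if (is.null(meta$category)) meta$category <- data$category
  } else stop("unsupported data container")
  if (!identical(surface, "mixed") && !is.null(meta$surface)) {
    keep <- meta$surface == surface
    x <- x[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  }
  list(x = x, category = as.character(meta$category), meta = meta)
}

#' Stratified 3:1 train/test split
#'
#' Within each stratum the test set gets `round(n / (ratio + 1))` rows
#' (so 8 rows at 3:1 give 6 train / 2 test, and 315-row strata give 236
#' train / 79 test); the remainder trains. Deterministic for a fixed seed.
#'
#' @param meta data.frame with the stratification column(s).
#' @param ratio train:test ratio (default 3, i.e. 3:1).
#' @param stratify_by column name(s) in `meta` (default `"category"`).
#' @param seed RNG seed.
#' @return A `DatasetSplit`: list(train, test, ratio, seed).
#' @export
split_dataset <- function(meta, ratio = 3, stratify_by = "category",
                          seed = 1L) {
  meta <- as.data.frame(meta)
  strata <- interaction(meta[stratify_by], drop = TRUE)
  set.seed(seed)
  test <- integer(0)
  for (s in levels(strata)) {
    i <- which(strata == s)
    if (length(i) < 2)
      stop(sprintf("stratum '%s' has fewer than 2 rows", s))
    n_test <- round(length(i) / (ratio + 1))
    test <- c(test, sample(i, n_test))
  }
  test <- sort(test)
  structure(list(train = setdiff(seq_len(nrow(meta)), test), test = test,
                 ratio = ratio, seed = seed), class = "DatasetSplit")
}

#' Train a binary genuineness classifier
#'
#' Algorithms: `"rf"` (bagged gini trees, majority vote; defaults 500 trees,
#' `sqrt(p)` features per split, no standardization), `"svm"` (RBF C-SVC;
#' `(c, g)` taken from `config$c`/`config$g` or found by
#' [grid_search_svm()] with `config$grid`), `"mlp"` (one sigmoid hidden
#' layer, 2-unit softmax output; width `config$hidden`, default 32).
#' Features for svm/mlp are z-scored with statistics fit on the training
#' rows only; the scaling is stored in the model and re-applied at
#' prediction.
#'
#' @param algorithm `"rf"`, `"svm"` or `"mlp"`.
#' @param x numeric feature matrix (rows = seeds).
#' @param y two-class labels (`"target"` / `"non-target"`).
#' @param config named list of algorithm options (see Details).
#' @param seed RNG seed (initialization, bootstrap, CV folds).
#' @return A `TrainedModel` with a [predict.TrainedModel()] method.
#' @export
train_classifier <- function(algorithm = c("rf", "svm", "mlp"), x, y,
                             config = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features contain NaN/NA/Inf")
  if (length(unique(as.character(y))) < 2)
    stop("training data contains a single class")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  schema <- colnames(x)

  scaling <- NULL
  xs <- x
  if (algorithm %in% c("svm", "mlp")) {
    mu <- colMeans(x)
    sig <- apply(x, 2, sd)
    sig[sig == 0] <- 1
    scaling <- list(center = mu, scale = sig)
    xs <- sweep(sweep(x, 2, mu), 2, sig, `/`)
  }

  set.seed(seed)
  fit <- switch(algorithm,
    rf = {
      num_trees <- config$num_trees %||% 500L
      mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
      y01 <- as.integer(encode_pm1(y) == 1)
      forest <- cpp_rf_train(xs, y01, as.integer(num_trees),
                             as.integer(mtry),
                             as.integer(config$min_node %||% 1L),
                             as.integer(config$max_depth %||% 0L))
      lv <- sort(unique(as.character(y)))
      pos <- if ("target" %in% lv) "target" else lv[2]
      list(forest = forest, positive = pos, negative = setdiff(lv, pos)[1])
    },
    svm = {
      if (is.null(config$c) || is.null(config$g)) {
        gs <- grid_search_svm(xs, y, config$grid %||% svm_grid_config(),
                              seed = seed)
        config$c <- gs$c
        config$g <- gs$g
        config$cv_accuracy <- gs$cv_accuracy
      }
      svm_fit(xs, y, C = config$c, gamma = config$g)
    },
    mlp = mlp_fit(xs, y, hidden = config$hidden %||% 32L,
                  epochs = config$epochs %||% 400L,
                  lr = config$lr %||% 0.01, seed = seed))

  structure(list(algorithm = algorithm, fit = fit, schema = schema,
                 scaling = scaling, config = config, seed = seed),
            class = "TrainedModel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf("TrainedModel: %s, %d features\n", x$algorithm,
              length(x$schema)))
  invisible(x)
}

#' Predict categories with a TrainedModel
#'
#' @param object a [train_classifier()] model.
#' @param newdata matrix whose columns match the training schema (a named
#'   superset is reordered; anything else errors).
#' @param ... unused.
#' @return Character vector of predicted categories.
#' @export
predict.TrainedModel <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$schema))
      stop("newdata does not match the model feature schema")
    colnames(newdata) <- object$schema
  }
  if (!all(object$schema %in% colnames(newdata)))
    stop("newdata does not match the model feature schema")
  newdata <- newdata[, object$schema, drop = FALSE]
  if (!is.null(object$scaling))
    newdata <- sweep(sweep(newdata, 2, object$scaling$center), 2,
                     object$scaling$scale, `/`)
  switch(object$algorithm,
    rf = {
      vote <- cpp_rf_predict(object$fit$forest, newdata)
      ifelse(vote >= 0.5, object$fit$positive, object$fit$negative)
    },
    svm = predict(object$fit, newdata),
    mlp = predict(object$fit, newdata))
}

#' Confusion matrix for the two categories
#'
#' Rows = true, columns = predicted, order (`target`, `non-target`) when
#' those labels are used, otherwise sorted.
#'
#' @param truth,pred label vectors.
#' @return 2x2 integer matrix.
#' @export
confusion_matrix <- function(truth, pred) {
  lv <- unique(c(as.character(truth), as.character(pred)))
  lv <- if (all(c("target", "non-target") %in% lv) && length(lv) == 2)
    c("target", "non-target") else sort(lv)
  table(true = factor(truth, lv), predicted = factor(pred, lv))
}

#' Evaluate a model spec by repeated random splits
#'
#' The standard protocol: for each of `runs` repetitions, draw a fresh
#' stratified 3:1 split, fit the classifier on the training part, and score
#' the held-out part. Reports the per-run accuracies, their mean (the
#' ten-run-averaged accuracy when `runs = 10`), and the confusion matrix
#' pooled over runs.
#'
#' @param model_spec list with `algorithm` and optional `config` (passed to
#'   [train_classifier()]).
#' @param data a container accepted by [model_frame()].
#' @param runs number of repetitions (default 10).
#' @param seed base RNG seed; run r uses `seed + r - 1`.
#' @param surface surface filter passed to [model_frame()].
#' @param ratio train:test ratio.
#' @return An `EvalReport`: list(confusion, accuracy, run_accuracies, runs).
#' @export
evaluate_model <- function(model_spec, data, runs = 10L, seed = 1L,
                           surface = "mixed", ratio = 3) {
  stopifnot(runs >= 1)
  mf <- model_frame(data, surface)
  accs <- numeric(runs)
  conf <- NULL
  for (r in seq_len(runs)) {
    sp <- split_dataset(mf$meta, ratio = ratio, seed = seed + r - 1L)
    model <- train_classifier(model_spec$algorithm,
                              mf$x[sp$train, , drop = FALSE],
                              mf$category[sp$train],
                              config = model_spec$config %||% list(),
                              seed = seed + r - 1L)
    pred <- predict(model, mf$x[sp$test, , drop = FALSE])
    cm <- confusion_matrix(mf$category[sp$test], pred)
    conf <- if (is.null(conf)) cm else conf + cm
    accs[r] <- sum(diag(cm)) / sum(cm)
  }
  structure(list(confusion = conf, accuracy = mean(accs),
                 run_accuracies = accs, runs = runs, seed = seed,
                 algorithm = model_spec$algorithm), class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport (%s): mean accuracy %.3f over %d runs\n",
              x$algorithm, x$accuracy, x$runs))
  print(x$confusion)
  invisible(x)
}

#' Serialize an EvalReport as JSON (and the confusion matrix as CSV)
#' @param x an `EvalReport`.
#' @param path output path (JSON); `<path>.confusion.csv` is written too.
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(list(algorithm = x$algorithm, accuracy = x$accuracy,
                            run_accuracies = x$run_accuracies,
                            runs = x$runs,
                            confusion = as.data.frame.matrix(x$confusion)),
                       path, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame.matrix(x$confusion),
            paste0(path, ".confusion.csv"))
  invisible(path)
}
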