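#' ExperimentConfig: one end-to-end genuineness experiment
#'
#' Exactly one input source must be given: a simulator scenario, a spectra
#' CSV (see [read_spectrum_csv()]), or a feature CSV. The experiment runs
#' extract -> (optional SPA) -> train -> ten-run evaluate -> (optional
#' external verify/update), with every random draw derived from `seed`.
#'
#' @param scenario a [scenario_config()] (simulator source).
#' @param spectra_csv,feature_csv tabular sources (paths).
#' @param surface `"germ"`, `"non-germ"` or `"mixed"` (pool both surfaces).
#' @param feature_mode `"full-spectrum"`, `"spa"` (characteristic
#'   wavelengths), or `"rgb-54"` (feature CSV source only).
#' @param algorithm `"rf"`, `"svm"` or `"mlp"`.
#' @param runs evaluation repetitions (default 10).
#' @param model_config options for [train_classifier()].
#' @param spa_k_max SPA subset-size cap.
#' @param update list(trigger, stop_at, max_iter) to run the active-learning
#'   loop against the scenario's external panel (NULL = skip).
#' @param seed master seed.
#' @return An `ExperimentConfig`.
#' @export
experiment_config <- function(scenario = NULL, spectra_csv = NULL,
                              feature_csv = NULL, surface = "mixed",
                              feature_mode = c("full-spectrum", "spa",
                                               "rgb-54"),
                              algorithm = c("svm", "mlp", "rf"),
                              runs = 10L, model_config = list(),
                              spa_k_max = 30L, update = NULL, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  algorithm <- match.arg(algorithm)
  sources <- !vapply(list(scenario, spectra_csv, feature_csv), is.null,
                     logical(1))
  if (sum(sources) != 1)
    stop("exactly one input source (scenario, spectra_csv or feature_csv) ",
         "must be given")
  if (feature_mode == "rgb-54" && is.null(feature_csv))
    stop("feature_mode 'rgb-54' requires a feature CSV source")
  if (feature_mode == "spa" && !is.null(feature_csv))
    stop("SPA applies to spectra, not the 54-feature table")
  for (p in c(spectra_csv, feature_csv))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(scenario = scenario, spectra_csv = spectra_csv,
                 feature_csv = feature_csv, surface = surface,
                 feature_mode = feature_mode, algorithm = algorithm,
                 runs = runs, model_config = model_config,
                 spa_k_max = spa_k_max, update = update, seed = seed),
            class = "ExperimentConfig")
}

#' Run an experiment end to end
#'
#' @param cfg an [experiment_config()].
#' @param out_dir directory for artifacts (created if missing); NULL keeps
#'   everything in memory.
#' @return list with `eval` (an `EvalReport`), `spa` (`SPAResult` or NULL),
#'   `verify`/`update_log` (when an external panel is in play), and
#'   `manifest`.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  stage <- "load"
  result <- list()
  tryCatch({
    external <- NULL
    if (!is.null(cfg$scenario)) {
      sim <- simulate_scenario(cfg$scenario, seed = cfg$seed)
      data <- sim$train
      external <- sim$external
    } else if (!is.null(cfg$spectra_csv)) {
      data <- read_spectrum_csv(cfg$spectra_csv)
    } else {
      data <- read_feature_csv(cfg$feature_csv)
    }

    spa_res <- NULL
    if (cfg$feature_mode == "spa") {
      stage <- "spa"
      mf <- model_frame(data, cfg$surface)
      sp <- split_dataset(mf$meta, seed = cfg$seed)
      y <- as.numeric(mf$category == "target")
      spa_res <- spa_select(mf$x[sp$train, , drop = FALSE], y[sp$train],
                            mf$x[sp$test, , drop = FALSE], y[sp$test],
                            k_max = cfg$spa_k_max,
                            wavelengths = if (inherits(data,
                                                       "SpectrumTable"))
                              data$wavelengths else NULL)
      data <- restrict_bands(data, spa_res$selected)
      if (!is.null(external))
        external <- restrict_bands(external, spa_res$selected)
    }

    stage <- "evaluate"
    eval_rep <- evaluate_model(list(algorithm = cfg$algorithm,
                                    config = cfg$model_config),
                               data, runs = cfg$runs, seed = cfg$seed,
                               surface = cfg$surface)

    verify_res <- NULL
    update_log <- NULL
    if (!is.null(external)) {
      stage <- "verify"
      mf <- model_frame(data, cfg$surface)
      model <- train_classifier(cfg$algorithm, mf$x, mf$category,
                                config = cfg$model_config, seed = cfg$seed)
      verify_res <- verify_external(model, external)
      if (!is.null(cfg$update)) {
        stage <- "update"
        up <- active_update(list(algorithm = cfg$algorithm,
                                 config = cfg$model_config),
                            data, external,
                            trigger = cfg$update$trigger %||% 0.60,
                            stop_at = cfg$update$stop_at %||% 0.99,
                            max_iter = cfg$update$max_iter %||% 10L,
                            seed = cfg$seed)
        update_log <- up$log
      }
    }

    manifest <- list(
      config = serializable_config(cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("genuseed")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      accuracy = eval_rep$accuracy,
      run_accuracies = eval_rep$run_accuracies,
      spa_selected_nm = spa_res$selected_nm,
      outputs = character(0))

    result <- list(eval = eval_rep, spa = spa_res, verify = verify_res,
                   update_log = update_log, manifest = manifest)

    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c(eval = file.path(out_dir, "eval_report.json"))
      write_eval_report(eval_rep, paths[["eval"]])
      if (!is.null(spa_res)) {
        paths[["spa"]] <- file.path(out_dir, "spa_result.json")
        write_spa_json(spa_res, paths[["spa"]])
      }
      if (!is.null(update_log)) {
        paths[["update"]] <- file.path(out_dir, "update_log")
        write_update_log(update_log, paths[["update"]])
      }
      result$manifest$outputs <- unname(paths)
      jsonlite::write_json(result$manifest,
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    result
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Keep only the selected band columns of a SpectrumTable
#' @param st a [spectrum_table()].
#' @param idx band indices (e.g. `SPAResult$selected`); sorted before use.
#' @return A `SpectrumTable` on the restricted grid.
#' @export
restrict_bands <- function(st, idx) {
  stopifnot(inherits(st, "SpectrumTable"))
  idx <- sort(idx)
  spectrum_table(st$spectra[, idx, drop = FALSE], st$wavelengths[idx],
                 st$meta)
}

serializable_config <- function(cfg) {
  x <- unclass(cfg)
  if (!is.null(x$scenario)) {
    s <- unclass(x$scenario)
    s$target <- unclass(s$target)
    s$target$bands <- as.list(s$target$bands)
    x$scenario <- s
  }
  x
}
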