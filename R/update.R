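#' Per-variety external verification of a trained model
#'
#' Scores each external variety separately: the fraction of its seeds
#' assigned the correct category. The overall figure is the unweighted mean
#' over varieties (each variety contributes equally, as in the conventional
#' per-variety histograms).
#'
#' @param model a [train_classifier()] model.
#' @param vset a container accepted by [model_frame()] whose meta carries
#'   `variety` and `category`.
#' @return list with `per_variety` (named accuracy vector, in first-appearance
#'   order), `average`, and `n` (seeds per variety).
#' @export
verify_external <- function(model, vset) {
  mf <- model_frame(vset)
  if (ncol(mf$x) != length(model$schema) &&
      !all(model$schema %in% colnames(mf$x)))
    stop("verification set does not match the model feature schema")
  pred <- predict(model, mf$x)
  vars <- unique(mf$meta$variety)
  acc <- vapply(vars, function(v) {
    i <- mf$meta$variety == v
    mean(pred[i] == mf$category[i])
  }, numeric(1))
  names(acc) <- vars
  list(per_variety = acc, average = mean(acc),
       n = vapply(vars, function(v) sum(mf$meta$variety == v), integer(1)))
}

#' Accuracy-threshold active-learning model update
#'
#' Iteratively improves a genuineness model on external varieties it was
#' never trained on: verify; if the average per-variety accuracy over the
#' remaining external varieties has reached `stop`, halt; otherwise pick one
#' variety whose accuracy is below `trigger` (lowest accuracy first by
#' default, ties by listed order; `selection = "random"` draws among the
#' sub-trigger varieties), move *all* its seeds into the training table with
#' their correct labels, retrain from scratch, and repeat. Absorbed
#' varieties leave the external pool, so later averages are computed over
#' the remaining varieties only. Halts with status `"stalled"` (not an
#' error) when no variety is below `trigger` yet the average is below
#' `stop`.
#'
#' @param model_spec list(algorithm, config) for [train_classifier()].
#' @param train_table training container ([model_frame()]-compatible).
#' @param vset external verification container with `variety` labels.
#' @param trigger accuracy below which a variety is absorbed (default 0.60).
#' @param stop_at average external accuracy at which to halt (default 0.99).
#' @param max_iter maximum update iterations.
#' @param seed RNG seed (retraining and random selection).
#' @param selection `"lowest"` (default) or `"random"` among sub-trigger
#'   varieties.
#' @return list(model, log) where `log` is an `UpdateLog`: data.frame with
#'   one row per verification pass (iteration, variety_added, n_added,
#'   average_accuracy, n_external, status) with the per-variety accuracy
#'   history in `attr(log, "per_variety")`.
#' @export
active_update <- function(model_spec, train_table, vset, trigger = 0.60,
                          stop_at = 0.99, max_iter = 10L, seed = 1L,
                          selection = c("lowest", "random")) {
  selection <- match.arg(selection)
  tr <- model_frame(train_table)
  ev <- model_frame(vset)
  if (!nrow(ev$x)) stop("verification set is empty")

  fit_current <- function(it) {
    train_classifier(model_spec$algorithm, tr$x, tr$category,
                     config = model_spec$config %||% list(),
                     seed = seed + it)
  }
  model <- fit_current(0L)
  if (max_iter == 0L) {
    log <- data.frame(iteration = integer(0), variety_added = character(0),
                      n_added = integer(0), average_accuracy = numeric(0),
                      n_external = integer(0), status = character(0))
    attr(log, "per_variety") <- list()
    attr(log, "status") <- "max_iter"
    class(log) <- c("UpdateLog", "data.frame")
    return(list(model = model, log = log))
  }
  log_rows <- list()
  history <- list()
  status <- "max_iter"
  iter <- 0L
  repeat {
    ver <- verify_external(model, ev)
    history[[length(history) + 1L]] <- ver$per_variety
    row <- data.frame(iteration = iter, variety_added = NA_character_,
                      n_added = 0L, average_accuracy = ver$average,
                      n_external = length(ver$per_variety),
                      status = "verified")
    if (ver$average >= stop_at) { status <- "reached_stop"; row$status <- status }
    low <- which(ver$per_variety < trigger)
    if (status != "reached_stop" && !length(low) && iter < max_iter) {
      status <- "stalled"
      row$status <- status
    }
    if (status %in% c("reached_stop", "stalled") || iter >= max_iter) {
      if (iter >= max_iter && status == "max_iter") row$status <- "max_iter"
      log_rows[[length(log_rows) + 1L]] <- row
      break
    }
    pick <- if (selection == "lowest") {
      low[order(ver$per_variety[low])][1]  # order() is stable: listed order
    } else {
      set.seed(seed + 1000L + iter)
      low[sample.int(length(low), 1L)]
    }
    vname <- names(ver$per_variety)[pick]
    move <- ev$meta$variety == vname
    tr$x <- rbind(tr$x, ev$x[move, , drop = FALSE])
    tr$category <- c(tr$category, ev$category[move])
    tr$meta <- rbind(tr$meta[, c("category", "variety", "lot", "surface")],
                     ev$meta[move, c("category", "variety", "lot",
                                     "surface")])
    ev$x <- ev$x[!move, , drop = FALSE]
    ev$category <- ev$category[!move]
    ev$meta <- ev$meta[!move, , drop = FALSE]
    row$variety_added <- vname
    row$n_added <- sum(move)
    log_rows[[length(log_rows) + 1L]] <- row
    iter <- iter + 1L
    if (!nrow(ev$x)) { status <- "no_external_left"; break }
    model <- fit_current(iter)
  }
  log <- do.call(rbind, log_rows)
  attr(log, "per_variety") <- history
  attr(log, "status") <- status
  class(log) <- c("UpdateLog", "data.frame")
  list(model = model, log = log)
}

#' Serialize an UpdateLog as JSON and CSV
#' @param log an `UpdateLog`.
#' @param path base path; `<path>.json` and `<path>.csv` are written.
#' @export
write_update_log <- function(log, path) {
  df <- as.data.frame(log)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(log = df, status = attr(log, "status"),
         per_variety = lapply(attr(log, "per_variety"), as.list)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
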