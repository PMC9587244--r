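#' Pipeline run configuration
#'
#' Bundles every stage's options behind one object and one master seed. The
#' master seed fans out to per-stage child seeds by fixed offsets (cohort
#' generation +11, training +23, risk refit +37), so individual stages can
#' be re-run in isolation and reproduce the full run's draws exactly.
#'
#' @param cohort Either an `acr_generator_config` (a cohort is generated) or
#'   a path to a cohort CSV.
#' @param max_order Largest VAR lag order considered by HQIC selection.
#' @param forecast_k Held-out forecast horizon.
#' @param dtw_vars Variables entering the DTW class-separation (the
#'   categorical SOFA channel is excluded by default).
#' @param spec Network specification ([network_spec()]).
#' @param training Training configuration ([training_config()]).
#' @param seed Master seed.
#' @return An object of class `acr_run_config`.
#' @export
run_config <- function(cohort = generator_config(),
                       max_order = 3L, forecast_k = 10L,
                       dtw_vars = c("scd31", "pf_ratio"),
                       spec = network_spec(),
                       training = training_config(),
                       seed = 1L) {
  seed <- as.integer(seed)
  if (inherits(cohort, "acr_generator_config")) cohort$seed <- seed + 11L
  training$seed <- seed + 23L
  cfg <- list(cohort = cohort, max_order = as.integer(max_order),
              forecast_k = as.integer(forecast_k), dtw_vars = dtw_vars,
              spec = spec, training = training, seed = seed)
  class(cfg) <- "acr_run_config"
  cfg
}

# stable hash of the configuration (md5 of its canonical YAML rendering)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass_deep(config)), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Serialize / restore configurations as YAML
#'
#' Generator, network, training and run configurations round-trip through
#' YAML so a run directory fully documents how it was produced.
#'
#' @param config A configuration object.
#' @param path Output path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   the restored list (classed when `class` is stored).
#' @export
write_config_yaml <- function(config, path) {
  lst <- unclass_deep(config)
  lst$.class <- class(config)[1]
  writeLines(yaml::as.yaml(lst), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  restore <- function(l, klass) { class(l) <- klass; l }
  if (!is.null(lst$cohort) && !is.character(lst$cohort)) {
    lst$cohort <- restore(lst$cohort, "acr_generator_config")
  }
  if (!is.null(lst$spec)) lst$spec <- restore(lst$spec, "acr_network_spec")
  if (!is.null(lst$training)) lst$training <- restore(lst$training, "acr_training_config")
  if (!is.null(cls)) class(lst) <- cls
  lst
}

.stage_fail <- function(stage, e) {
  stop(structure(class = c("acr_pipeline_error", "error", "condition"),
                 list(message = sprintf("pipeline stage '%s' failed: %s",
                                        stage, conditionMessage(e)),
                      call = NULL, stage = stage)))
}

.write_json <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

.write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full ACR-risk analysis pipeline
#'
#' Orchestrates, from one configuration and seed: cohort generation (or
#' loading), stationarity / Granger / cointegration diagnostics with
#' lag-order selection, VAR fitting and held-out forecasting, DTW class
#' separation, stratified cross-validated training and evaluation of the
#' temporal classifier, and the per-patient risk table from a final model.
#' Every artifact records the hash of the configuration that produced it;
#' deterministic artifacts are bit-identical across re-runs with the same
#' configuration.
#'
#' Artifacts written to `out_dir`: `cohort.csv`, `diagnostics.json`,
#' `forecast.csv`, `dtw.json`, `eval_report.json`, `history.csv`,
#' `parameter_manifest.json`, `risk_table.csv`, `run_log.txt`, and
#' `run_config.yaml`.
#'
#' @param config An `acr_run_config`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly. Stage failures raise a structured
#'   condition of class `acr_pipeline_error` naming the stage.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "acr_run_config"))
  if (missing(out_dir)) stop("'out_dir' is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  hash <- config_hash(config)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("config hash: %s", hash)
  write_config_yaml(config, file.path(out_dir, "run_config.yaml"))

  # -- stage: cohort ----------------------------------------------------------
  cohort <- tryCatch({
    if (inherits(config$cohort, "acr_generator_config")) {
      generate_cohort(config$cohort)
    } else {
      read_cohort(config$cohort)
    }
  }, error = function(e) .stage_fail("cohort", e))
  .write_csv_hashed(local({
    rec <- cohort$records
    for (j in seq_along(rec)) {
      if (is.double(rec[[j]])) rec[[j]] <- format(rec[[j]], digits = 17, trim = TRUE)
    }
    rec
  }), file.path(out_dir, "cohort.csv"), hash)
  note("cohort: %d patients, %d events", nrow(cohort$records),
       sum(cohort$records$acr))

  # -- stage: diagnostics -----------------------------------------------------
  diag <- tryCatch({
    levels_panel <- pooled_panel(cohort)
    diff_panel <- difference(levels_panel)
    adf_rows <- lapply(levels_panel$variables, function(v) {
      raw <- adf_test(levels_panel$values[, v])
      dif <- adf_test(diff_panel$values[, v])
      list(variable = v,
           adf_stat_raw = raw$statistic, p_raw = raw$p_value,
           adf_stat_diff = dif$statistic, p_diff = dif$p_value,
           lags_raw = raw$n_lags_used, lags_diff = dif$n_lags_used)
    })
    sel <- select_lag_order(diff_panel, config$max_order)
    gmax <- sel$order
    pairs <- expand.grid(cause = levels_panel$variables,
                         effect = levels_panel$variables,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$cause != pairs$effect, ]
    granger_rows <- lapply(seq_len(nrow(pairs)), function(i) {
      g <- granger_test(diff_panel, pairs$cause[i], pairs$effect[i], gmax)
      list(cause = g$cause, effect = g$effect, max_lag = g$max_lag,
           f_statistic = g$f_statistic, p_value = g$p_value,
           rejects_at_0.05 = g$p_value < 0.05)
    })
    coint <- cointegration_screen(levels_panel, list(
      c("scd31", "pf_ratio"),
      c("scd31", "resp_sofa"),
      c("pf_ratio", "resp_sofa"),
      c("scd31", "pf_ratio", "resp_sofa")
    ))
    var_fit <- fit_var(diff_panel, sel$order)
    list(adf = adf_rows, selected_order = sel$order,
         information_criteria = sel$criteria,
         granger = granger_rows,
         cointegration = coint,
         durbin_watson = as.list(var_fit$dw_statistics),
         panel = diff_panel, var_fit = var_fit)
  }, error = function(e) .stage_fail("diagnostics", e))
  .write_json(diag[c("adf", "selected_order", "information_criteria",
                     "granger", "cointegration", "durbin_watson")],
              file.path(out_dir, "diagnostics.json"), hash)
  note("diagnostics: selected VAR order %d", diag$selected_order)

  # -- stage: forecast --------------------------------------------------------
  fc_df <- withCallingHandlers(tryCatch({
    k <- config$forecast_k
    dp <- diag$panel
    T_d <- nrow(dp$values)
    if (k >= T_d) stop("forecast horizon k must be smaller than the differenced series length")
    train_panel <- dp
    train_panel$values <- dp$values[seq_len(T_d - k), , drop = FALSE]
    if (!is.null(train_panel$groups)) train_panel$groups <- dp$groups[seq_len(T_d - k)]
    fit <- fit_var(train_panel, diag$selected_order)
    ref <- dp$scale_reference
    anchor_row <- ref$level_index[T_d - k]
    actual <- ref$values[anchor_row + seq_len(k), , drop = FALSE]
    fc <- var_forecast(fit, train_panel, k, actual = actual)
    long <- do.call(rbind, lapply(seq_len(ncol(actual)), function(j) {
      data.frame(record = "forecast", step = seq_len(k),
                 variable = colnames(fc$forecast)[j],
                 forecast = fc$forecast[, j], actual = actual[, j],
                 rmse = NA_real_, mae = NA_real_, mape = NA_real_,
                 corr = NA_real_, stringsAsFactors = FALSE)
    }))
    acc <- fc$accuracy
    acc_rows <- data.frame(record = "accuracy", step = NA_integer_,
                           variable = acc$variable, forecast = NA_real_,
                           actual = NA_real_, rmse = acc$rmse, mae = acc$mae,
                           mape = acc$mape, corr = acc$corr,
                           stringsAsFactors = FALSE)
    rbind(long, acc_rows)
  }, error = function(e) .stage_fail("forecast", e)),
  warning = function(w) {
    note("forecast: warning: %s", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  .write_csv_hashed(fc_df, file.path(out_dir, "forecast.csv"), hash)
  note("forecast: horizon %d", config$forecast_k)

  # -- stage: dtw -------------------------------------------------------------
  dtw_out <- tryCatch({
    series <- cohort_class_series(cohort, vars = config$dtw_vars)
    sep <- class_separation(series)
    list(variables = config$dtw_vars,
         normalized_distance = sep$normalized_distance,
         distance = sep$distance,
         path_length = nrow(sep$dtw$path),
         n_non_acr = length(series$non_acr), n_acr = length(series$acr))
  }, error = function(e) .stage_fail("dtw", e))
  .write_json(dtw_out, file.path(out_dir, "dtw.json"), hash)
  note("dtw: normalized class separation %.4f", dtw_out$normalized_distance)

  # -- stage: train -----------------------------------------------------------
  trained <- tryCatch({
    mats <- cohort_segments(cohort)
    y <- attr(mats, "acr")
    cv <- cross_validate(mats, y, spec = config$spec, config = config$training)
    hist <- do.call(rbind, lapply(seq_along(cv$fold_models), function(f) {
      h <- cv$fold_models[[f]]$history
      h$fold <- f
      h
    }))
    list(cv = cv, history = hist, mats = mats, y = y)
  }, error = function(e) .stage_fail("train", e))
  rep <- trained$cv$report
  .write_json(list(accuracy = rep$accuracy,
                   auc = rep$auc, cohen_kappa = rep$cohen_kappa,
                   kl_divergence = rep$kl_divergence, loss = rep$loss,
                   confusion_matrix = as.data.frame(unclass(rep$confusion_matrix)),
                   per_class = rep$per_class, n = rep$n),
              file.path(out_dir, "eval_report.json"), hash)
  .write_csv_hashed(trained$history, file.path(out_dir, "history.csv"), hash)
  .write_json(list(layers = parameter_manifest(config$spec)),
              file.path(out_dir, "parameter_manifest.json"), hash)
  note("train: cross-validated accuracy %.3f, minority recall %s",
       rep$accuracy,
       format(rep$per_class$class_1["recall"], digits = 3))

  # -- stage: risk ------------------------------------------------------------
  risk <- tryCatch({
    cfg_final <- config$training
    cfg_final$seed <- config$seed + 37L
    std <- standardize_segments(trained$mats)
    final <- train_classifier(std$segments, trained$y,
                              spec = config$spec, config = cfg_final)
    risk_table(final, trained$mats, stats = std$stats)
  }, error = function(e) .stage_fail("risk", e))
  .write_csv_hashed(local({
    r <- risk
    for (j in seq_along(r)) {
      if (is.double(r[[j]])) r[[j]] <- format(r[[j]], digits = 17, trim = TRUE)
    }
    r
  }), file.path(out_dir, "risk_table.csv"), hash)
  note("risk: %d patients scored", nrow(risk))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

.required_artifacts <- c("cohort.csv", "diagnostics.json", "forecast.csv",
                         "dtw.json", "eval_report.json", "history.csv",
                         "parameter_manifest.json", "risk_table.csv")

.artifact_hash <- function(path) {
  if (grepl("[.]json$", path)) {
    jsonlite::read_json(path)$config_hash
  } else {
    first <- readLines(path, n = 1L)
    sub("^# config_hash: ", "", first)
  }
}

#' Summarize a completed pipeline run
#'
#' Produces a deterministic one-page markdown summary of a run directory:
#' cohort composition, selected VAR lag order, Granger decisions at the 0.05
#' level, DTW class separation, cross-validated confusion matrix, trainable
#' parameter total, and the highest-risk patients. Refuses directories whose
#' artifacts carry inconsistent configuration hashes.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return Character vector of markdown lines (also printed invisibly
#'   reusable with `writeLines`).
#' @export
pipeline_report <- function(run_dir) {
  paths <- file.path(run_dir, .required_artifacts)
  missing <- .required_artifacts[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("run directory is missing artifact(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hashes <- vapply(paths, .artifact_hash, character(1))
  if (length(unique(hashes)) != 1L) {
    stop("artifacts carry mixed config hashes; refusing to summarize", call. = FALSE)
  }
  diagj <- jsonlite::read_json(file.path(run_dir, "diagnostics.json"))
  dtwj <- jsonlite::read_json(file.path(run_dir, "dtw.json"))
  evalj <- jsonlite::read_json(file.path(run_dir, "eval_report.json"))
  manif <- jsonlite::read_json(file.path(run_dir, "parameter_manifest.json"))
  cohort <- utils::read.csv(file.path(run_dir, "cohort.csv"), comment.char = "#")
  risk <- utils::read.csv(file.path(run_dir, "risk_table.csv"), comment.char = "#")

  total <- vapply(manif$layers, function(l) as.integer(l$params), integer(1))
  total <- total[vapply(manif$layers, function(l) l$layer == "total", logical(1))]
  granger_lines <- vapply(diagj$granger, function(g) {
    sprintf("- %s -> %s: F = %.3f, p = %.4g (%s at 0.05)",
            g$cause, g$effect, g$f_statistic, g$p_value,
            if (isTRUE(g$rejects_at_0.05)) "rejects" else "retains")
  }, character(1))
  cm <- evalj$confusion_matrix
  top <- utils::head(risk[order(-risk$risk_percentile, risk$patient_id), ], 5L)

  lines <- c(
    "# Pipeline run summary",
    "",
    sprintf("Config hash: `%s`", hashes[[1]]),
    "",
    "## Cohort",
    sprintf("- %d patients, %d ACR events (prevalence %.1f%%)",
            nrow(cohort), sum(cohort$acr), 100 * mean(cohort$acr)),
    "",
    "## Vector autoregression",
    sprintf("- Selected lag order (HQIC): %d", diagj$selected_order),
    "- Granger decisions:",
    granger_lines,
    "",
    "## DTW class separation",
    sprintf("- Normalized distance between class representatives: %.4f",
            dtwj$normalized_distance),
    "",
    "## Classifier",
    sprintf("- Trainable parameters: %d", total),
    sprintf("- Cross-validated accuracy %.3f, AUC %s, Cohen's kappa %.3f",
            evalj$accuracy,
            if (is.null(evalj$auc)) "NA" else sprintf("%.3f", evalj$auc),
            evalj$cohen_kappa),
    sprintf("- Confusion matrix [actual x predicted]: [[%s, %s], [%s, %s]]",
            cm$X0[[1]], cm$X1[[1]], cm$X0[[2]], cm$X1[[2]]),
    "",
    "## Highest-risk patients",
    sprintf("- %s: risk percentile %.1f (p = %.3f)",
            top$patient_id, top$risk_percentile, top$probability)
  )
  lines
}
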