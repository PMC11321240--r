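.datatable.aware <- TRUE

#' Run configuration
#'
#' Bundles generator, pipeline, and stats settings with the output seed into
#' a single validated object that round-trips losslessly through YAML.
#'
#' @param generator named list of overrides for [generator_params()].
#' @param alpha significance level for the pairwise contrasts.
#' @param velocity_window seconds after the cue for the peak-velocity search.
#' @param seed master seed (overrides any seed inside `generator`).
#' @param null_effects force all condition effects to neutral (calibration
#'   runs).
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = list(), alpha = 0.05,
                       velocity_window = 1.5, seed = 1L,
                       null_effects = FALSE) {
  known <- names(formals(generator_params))
  bad <- setdiff(names(generator), known)
  if (length(bad) > 0L) {
    stop("unknown generator parameter(s) in config: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- list(generator = generator, alpha = alpha,
              velocity_window = velocity_window, seed = as.integer(seed),
              null_effects = isTRUE(null_effects))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_params <- function(cfg) {
  args <- cfg$generator
  args$seed <- cfg$seed
  if (cfg$null_effects) args$condition_effects <- null_condition_effects()
  do.call(generator_params, args)
}

#' Read / write a run configuration (YAML)
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns the `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Write a synthetic cohort to a directory
#'
#' Serializes a cohort as plain tabular text: `session.csv` (one row per
#' trial with schedule and detection bookkeeping), per-trial EMG files
#' (`<participant>_T<trial>_emg.csv`: sample, agonist, antagonist), per-trial
#' marker files (`..._mocap.csv`: sample, wrist_x, wrist_y, elbow_x,
#' elbow_y), and `config.json` echoing the generator parameters.
#'
#' @param cohort `emd_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create dataset directory: ", dir, call. = FALSE)
  }
  meta <- data.table::rbindlist(lapply(cohort$trials, function(tr) {
    data.table::data.table(
      participant = tr$participant_id, trial = tr$trial,
      block = NA_integer_, order_position = tr$order_position,
      condition = tr$condition, phase = tr$phase, cue_time = tr$cue_time,
      emg_rate = tr$emg_rate, mocap_rate = tr$mocap_rate,
      cue_index = tr$cue_index, cue_index_mocap = tr$cue_index_mocap,
      rest_start = tr$rest_window[1], rest_end = tr$rest_window[2],
      rest_max = tr$rest_max, threshold = tr$threshold,
      trigger_index = tr$trigger_index,
      true_onset_index = tr$true_onset_index,
      voluntary = tr$voluntary, missed_trigger = tr$missed_trigger,
      pull_start = if (is.null(tr$pull)) NA_real_ else tr$pull$start_time,
      pull_duration = if (is.null(tr$pull)) NA_real_ else tr$pull$duration,
      pull_direction = if (is.null(tr$pull)) NA_integer_ else
        tr$pull$direction
    )
  }))
  data.table::fwrite(meta, file.path(dir, "session.csv"))
  for (tr in cohort$trials) {
    stem <- sprintf("%s_T%03d", tr$participant_id, tr$trial)
    data.table::fwrite(
      data.table::data.table(sample = seq_along(tr$agonist_emg),
                             agonist = tr$agonist_emg,
                             antagonist = tr$antagonist_emg),
      file.path(dir, paste0(stem, "_emg.csv")))
    data.table::fwrite(
      data.table::data.table(sample = seq_len(nrow(tr$wrist_xy)),
                             wrist_x = tr$wrist_xy[, 1],
                             wrist_y = tr$wrist_xy[, 2],
                             elbow_x = tr$elbow_xy[, 1],
                             elbow_y = tr$elbow_xy[, 2]),
      file.path(dir, paste0(stem, "_mocap.csv")))
  }
  cfg <- unclass(cohort$params)
  cfg$condition_effects <- NULL
  jsonlite::write_json(
    list(params = cfg,
         condition_effects = cohort$params$condition_effects),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort dataset from a directory
#'
#' Inverse of [write_dataset()]. Validates the schema and reports the
#' offending file/column on mismatch.
#'
#' @param dir dataset directory.
#' @return list with `trials` (list of trial records) and `meta` (the
#'   session table).
#' @export
read_dataset <- function(dir) {
  sess <- file.path(dir, "session.csv")
  if (!file.exists(sess)) {
    stop("not a dataset directory (missing session.csv): ", dir,
         call. = FALSE)
  }
  meta <- as.data.frame(data.table::fread(sess))
  need <- c("participant", "trial", "order_position", "condition", "phase",
            "cue_time", "emg_rate", "mocap_rate", "cue_index",
            "cue_index_mocap", "rest_start", "rest_end", "rest_max",
            "trigger_index", "true_onset_index", "voluntary",
            "missed_trigger")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop("session.csv is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    stem <- sprintf("%s_T%03d", m$participant, m$trial)
    emg_path <- file.path(dir, paste0(stem, "_emg.csv"))
    moc_path <- file.path(dir, paste0(stem, "_mocap.csv"))
    for (p in c(emg_path, moc_path)) {
      if (!file.exists(p)) stop("missing trial file: ", p, call. = FALSE)
    }
    emg <- data.table::fread(emg_path)
    if (!all(c("agonist", "antagonist") %in% names(emg))) {
      stop("bad EMG schema in ", emg_path, call. = FALSE)
    }
    moc <- data.table::fread(moc_path)
    if (!all(c("wrist_x", "wrist_y", "elbow_x", "elbow_y") %in% names(moc))) {
      stop("bad marker schema in ", moc_path, call. = FALSE)
    }
    pull <- NULL
    if ("pull_start" %in% names(meta) && is.finite(m$pull_start)) {
      pull <- list(start_time = m$pull_start, duration = m$pull_duration,
                   angular_speed = PULL_ANGULAR_SPEED,
                   direction = m$pull_direction)
    }
    structure(list(
      participant_id = m$participant, condition = m$condition,
      phase = m$phase, trial = m$trial, order_position = m$order_position,
      cue_time = m$cue_time, emg_rate = m$emg_rate,
      mocap_rate = m$mocap_rate, cue_index = m$cue_index,
      cue_index_mocap = m$cue_index_mocap,
      agonist_emg = emg$agonist, antagonist_emg = emg$antagonist,
      wrist_xy = cbind(moc$wrist_x, moc$wrist_y),
      elbow_xy = cbind(moc$elbow_x, moc$elbow_y),
      pull = pull,
      true_onset_index = m$true_onset_index,
      rest_window = c(m$rest_start, m$rest_end),
      rest_max = m$rest_max,
      threshold = if ("threshold" %in% names(meta)) m$threshold else NULL,
      trigger_index = m$trigger_index,
      voluntary = as.logical(m$voluntary),
      missed_trigger = as.logical(m$missed_trigger)
    ), class = "emd_trial")
  })
  list(trials = trials, meta = meta)
}

#' Per-condition outcome summary
#'
#' Mean and SD of every outcome per condition over pulled-phase trials, in
#' the style of a bar-plot summary.
#'
#' @param metrics tidy metrics table.
#' @return data frame: condition, outcome, mean, sd, n.
#' @export
condition_summary <- function(metrics) {
  m <- metrics[metrics$phase == "pulled", ]
  rows <- list()
  for (oc in names(OUTCOME_COLUMNS)) {
    col <- OUTCOME_COLUMNS[[oc]]
    if (!col %in% names(m)) next
    agg <- stats::aggregate(m[[col]], list(condition = m$condition),
                            function(v) c(mean = mean(v, na.rm = TRUE),
                                          sd = stats::sd(v, na.rm = TRUE),
                                          n = sum(is.finite(v))))
    rows[[oc]] <- data.frame(condition = agg$condition, outcome = oc,
                             mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                             n = agg$x[, "n"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary bar figure of condition means
#'
#' Simple bar-and-errorbar figure of the per-condition outcome summaries
#' (mean +/- SD). Requires ggplot2.
#'
#' @param metrics tidy metrics table.
#' @return a ggplot object.
#' @export
plot_condition_summary <- function(metrics) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_condition_summary requires ggplot2", call. = FALSE)
  }
  s <- condition_summary(metrics)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = "mean +/- SD")
}

#' Simulate a cohort and write it to disk
#'
#' @param cfg `run_config`.
#' @param out_dir output directory.
#' @return the dataset directory, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  params <- config_params(cfg)
  cohort <- generate_cohort(params)
  write_dataset(cohort, out_dir)
  message(sprintf("wrote %d trials for %d participants to %s",
                  length(cohort$trials), params$n_participants, out_dir))
  invisible(out_dir)
}

#' Analyse a dataset directory
#'
#' Reads a serialized cohort, computes per-trial metrics, fits the four
#' outcome models, and writes `metrics.csv`, `contrasts.csv`, `models.csv`,
#' `summary.csv` and a plain-text `report.txt` to `out_dir`.
#'
#' @param data_dir dataset directory (see [write_dataset()]).
#' @param out_dir output directory.
#' @param alpha significance level.
#' @param velocity_window passed to [compute_metrics()].
#' @return list with `metrics` and `results`, invisibly.
#' @export
run_analyze <- function(data_dir, out_dir, alpha = 0.05,
                        velocity_window = 1.5) {
  ds <- read_dataset(data_dir)
  if (length(ds$trials) == 0L) stop("dataset contains no trials",
                                    call. = FALSE)
  metrics <- compute_metrics(ds$trials, velocity_window = velocity_window)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  data.table::fwrite(metrics, file.path(out_dir, "metrics.csv"))
  data.table::fwrite(condition_summary(metrics),
                     file.path(out_dir, "summary.csv"))

  conds <- unique(metrics$condition[metrics$phase == "pulled"])
  if (length(setdiff(conds, "passive")) < 2L) {
    warning("fewer than two non-passive conditions; skipping the mixed-model",
            " stage", call. = FALSE)
    return(invisible(list(metrics = metrics, results = NULL)))
  }
  results <- analyze_outcomes(metrics, alpha = alpha)
  write_results(results, out_dir)
  invisible(list(metrics = metrics, results = results))
}

write_results <- function(results, out_dir) {
  models <- do.call(rbind, lapply(results, function(r) {
    data.frame(outcome = r$outcome, lrt_chi2 = r$lrt_chi2,
               lrt_df = r$lrt_df, lrt_p = r$lrt_p,
               n_participants = r$n_participants, singular = r$singular,
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(models, file.path(out_dir, "models.csv"))
  contrasts <- do.call(rbind, lapply(results, function(r) {
    cbind(outcome = r$outcome, r$contrasts)
  }))
  data.table::fwrite(contrasts, file.path(out_dir, "contrasts.csv"))
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(results)
  invisible(NULL)
}

#' Run the full pipeline: simulate, analyse, report
#'
#' @param cfg `run_config`.
#' @param out_dir output directory; the dataset goes to
#'   `<out_dir>/dataset`, analysis outputs to `<out_dir>/analysis`.
#' @param keep_dataset write the cohort signals to disk (default `TRUE`);
#'   with `FALSE` the cohort is analysed in memory and only the analysis
#'   outputs are written.
#' @return list with `metrics` and `results`, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, keep_dataset = TRUE) {
  if (keep_dataset) {
    data_dir <- file.path(out_dir, "dataset")
    run_simulate(cfg, data_dir)
    return(run_analyze(data_dir, file.path(out_dir, "analysis"),
                       alpha = cfg$alpha,
                       velocity_window = cfg$velocity_window))
  }
  params <- config_params(cfg)
  metrics <- simulate_metrics(params,
                              phases = c("pre", "pulled", "post"))
  an_dir <- file.path(out_dir, "analysis")
  if (!dir.exists(an_dir) && !dir.create(an_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", an_dir, call. = FALSE)
  }
  data.table::fwrite(metrics, file.path(an_dir, "metrics.csv"))
  data.table::fwrite(condition_summary(metrics),
                     file.path(an_dir, "summary.csv"))
  results <- analyze_outcomes(metrics, alpha = cfg$alpha)
  write_results(results, an_dir)
  invisible(list(metrics = metrics, results = results))
}
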