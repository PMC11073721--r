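# Formats, validation, and the end-to-end pipeline orchestration.

trial_columns <- c("participant_id", "session", "block", "trial",
                   "congruency", "digit_left", "digit_right", "distance",
                   "correct_side", "response", "rt_s", "stimulation",
                   "order_group", "coil_dev_mm", "is_contaminant")

#' Write a trial table as CSV
#'
#' Comma-separated, UTF-8, header row, "." decimal, empty string for
#' missing values — the dialect used by every artifact of the pipeline.
#'
#' @param trials Trial data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table CSV
#'
#' @param path CSV file written by [write_trials()] (or with the same
#'   schema).
#' @return Trial data frame with numeric columns restored and empty
#'   strings read back as `NA`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  for (col in intersect(c("rt_s", "coil_dev_mm", "true_v", "true_a", "true_t0"),
                        names(df)))
    df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(c("block", "trial", "digit_left", "digit_right",
                          "distance", "is_contaminant"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' Validate a trial table against the pipeline schema
#'
#' Strict schema check: required columns present; enums matched exactly
#' and case-sensitively (`session`, `congruency`, `correct_side`,
#' `response`, `stimulation`, `order_group`); digits within 1-9;
#' `distance` in 1-8 and consistent with the digits; RTs non-negative.
#' Violations are listed with their row numbers.
#'
#' @param x Path to a trial CSV, or a trial data frame.
#' @return Object of class `"table_validation"`: `violations` data frame
#'   (`row`, `column`, `message`), `n_rows`, `n_cols`, `valid`.
#' @export
validate_table <- function(x) {
  df <- if (is.character(x)) read_trials(x) else as.data.frame(x)
  viols <- list()
  add <- function(rows, column, message) {
    if (length(rows))
      viols[[length(viols) + 1L]] <<-
        data.frame(row = rows, column = column, message = message,
                   stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(trial_columns, names(df))
  add(rep(0L, length(missing_cols)), missing_cols, "required column missing")
  enum_check <- function(col, levels, allow_na = FALSE) {
    if (!col %in% names(df)) return()
    bad <- !(df[[col]] %in% levels)
    if (allow_na) bad <- bad & !is.na(df[[col]])
    add(which(bad), col, paste0("value not in {",
                                paste(levels, collapse = ", "), "}"))
  }
  enum_check("session", c("practice1", "mri", "practice2", "tms"))
  enum_check("congruency", c("congruent", "incongruent", "neutral"))
  enum_check("correct_side", c("left", "right"))
  enum_check("response", c("left", "right", "none"), allow_na = TRUE)
  enum_check("stimulation", c("active", "sham", "none"))
  enum_check("order_group", c("active_first", "sham_first"))
  range_check <- function(col, lo, hi, what) {
    if (!col %in% names(df)) return()
    v <- df[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    add(which(bad), col, what)
  }
  range_check("digit_left", 1, 9, "digit outside 1-9")
  range_check("digit_right", 1, 9, "digit outside 1-9")
  range_check("distance", 1, 8, "distance outside 1-8")
  range_check("rt_s", 0, Inf, "negative reaction time")
  if (all(c("digit_left", "digit_right", "distance") %in% names(df))) {
    bad <- !is.na(df$distance) &
      abs(df$digit_left - df$digit_right) != df$distance
    add(which(bad), "distance", "distance inconsistent with digit pair")
  }
  violations <- if (length(viols)) do.call(rbind, viols)
  else data.frame(row = integer(), column = character(),
                  message = character(), stringsAsFactors = FALSE)
  structure(list(violations = violations, n_rows = nrow(df),
                 n_cols = ncol(df), valid = nrow(violations) == 0L),
            class = "table_validation")
}

#' @export
print.table_validation <- function(x, ...) {
  cat(sprintf("Trial table: %d rows x %d columns; %d violation(s)\n",
              x$n_rows, x$n_cols, nrow(x$violations)))
  if (nrow(x$violations)) print(utils::head(x$violations, 20), row.names = FALSE)
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects everything [run_pipeline()] needs: input (a trial CSV or a
#' simulation request), the cleaning, fitting and analysis options, the
#' seed, and the output directory.  A configuration can be written to and
#' read from YAML with [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir Output directory for all artifacts.
#' @param input Path to an existing trial CSV, or `NULL` to simulate.
#' @param simulate List with `config` ([design_config()]) and `truth`
#'   ([generative_truth()]) used when `input` is `NULL`.
#' @param seed Integer seed stamped into every artifact.
#' @param cleaning List: `sd_mult`, `sd_basis`, `coil_max_mm`.
#' @param fit List: `p_c`, `n_restarts`, `min_trials`.
#' @param arms Analysis arms to run: subset of
#'   `c("practice", "rtms", "sce", "distance")`.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, input = NULL,
                            simulate = list(config = design_config(),
                                            truth = generative_truth()),
                            seed = 1L,
                            cleaning = list(sd_mult = 2.5,
                                            sd_basis = "participant",
                                            coil_max_mm = 3),
                            fit = list(p_c = 0.05, n_restarts = 5L,
                                       min_trials = 20L),
                            arms = c("practice", "rtms", "sce", "distance")) {
  if (any(!arms %in% c("practice", "rtms", "sce", "distance")))
    stop("unknown analysis arm(s)")
  if (cleaning$sd_mult <= 0 || cleaning$coil_max_mm <= 0)
    stop("cleaning thresholds must be positive")
  structure(list(out_dir = out_dir, input = input, simulate = simulate,
                 seed = as.integer(seed), cleaning = cleaning, fit = fit,
                 arms = arms),
            class = "pipeline_config")
}

# config fingerprint: md5 of the canonical JSON serialisation
config_hash <- function(config) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_stamped_json <- function(x, path, stamp) {
  x$meta <- stamp
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

stage_guard <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", stage,
                                          conditionMessage(e)),
                        call = NULL, stage = stage))))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (if no input table) -> clean -> fit -> infer ->
#' analyze -> report, writing every artifact under `config$out_dir`:
#' the trial table, cleaned tables and cleaning reports, the
#' per-participant fit table, the drift-rate inference JSON, the
#' classical-analysis JSON, and a markdown report.  Every JSON artifact
#' is stamped with the configuration hash and seed, so re-running with an
#' identical configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of artifact paths plus the in-memory
#'   results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = config$seed, config_hash = config_hash(config))
  paths <- list()

  trials <- stage_guard("simulate", {
    if (is.null(config$input)) {
      simulate_study(config$simulate$config, config$simulate$truth,
                     seed = config$seed)
    } else {
      if (!file.exists(config$input))
        stop("input table not found and no simulation requested: ",
             config$input)
      read_trials(config$input)
    }
  })
  paths$trials <- file.path(config$out_dir, "trials.csv")
  write_trials(trials, paths$trials)

  cl <- config$cleaning
  cleaned <- stage_guard("clean", {
    prac <- trials[trials$session %in% c("practice1", "mri", "practice2"), ]
    tms <- trials[trials$session == "tms", ]
    list(practice = clean_practice(prac, sd_mult = cl$sd_mult,
                                   sd_basis = cl$sd_basis),
         tms = clean_tms(tms, coil_max_mm = cl$coil_max_mm,
                         sd_mult = cl$sd_mult, sd_basis = cl$sd_basis),
         tms_acc = clean_tms(tms, coil_max_mm = cl$coil_max_mm,
                             sd_mult = cl$sd_mult, sd_basis = cl$sd_basis,
                             track = "accuracy"))
  })
  paths$cleaned_practice <- file.path(config$out_dir, "cleaned_practice.csv")
  paths$cleaned_tms <- file.path(config$out_dir, "cleaned_tms.csv")
  write_trials(cleaned$practice$trials, paths$cleaned_practice)
  write_trials(cleaned$tms$trials, paths$cleaned_tms)
  paths$cleaning_report <- file.path(config$out_dir, "cleaning_report.json")
  write_stamped_json(
    list(practice = cleaned$practice$report$stages,
         tms = cleaned$tms$report$stages,
         warnings = c(cleaned$practice$report$warnings,
                      cleaned$tms$report$warnings)),
    paths$cleaning_report, stamp)

  fits <- stage_guard("fit", {
    by_pid <- split(cleaned$tms$trials, cleaned$tms$trials$participant_id)
    stats::setNames(lapply(seq_along(by_pid), function(i)
      fit_participant(by_pid[[i]], p_c = config$fit$p_c,
                      n_restarts = config$fit$n_restarts,
                      min_trials = config$fit$min_trials,
                      seed = config$seed + 101L * i)),
      names(by_pid))
  })
  fit_tab <- do.call(rbind, lapply(names(fits), function(pid)
    cbind(participant = pid, fits[[pid]]$drift)))
  paths$fits <- file.path(config$out_dir, "fits.csv")
  utils::write.csv(fit_tab, paths$fits, row.names = FALSE, na = "")

  infer <- stage_guard("infer", {
    dtab <- drift_table(fits)
    list(drift = dtab, anova = drift_anova(dtab), posthoc = posthoc_drift(dtab))
  })
  paths$drift_inference <- file.path(config$out_dir, "drift_inference.json")
  write_stamped_json(list(anova = as.data.frame(infer$anova),
                          posthoc = infer$posthoc),
                     paths$drift_inference, stamp)

  analysis <- stage_guard("analyze", run_analysis_arms(trials, cleaned, config))
  paths$classical <- file.path(config$out_dir, "classical.json")
  write_stamped_json(analysis$json, paths$classical, stamp)

  paths$report <- file.path(config$out_dir, "report.md")
  stage_guard("report",
              write_report(paths$report, cleaned, infer, analysis, stamp))
  invisible(list(paths = paths, trials = trials, cleaned = cleaned,
                 fits = fits, inference = infer, analysis = analysis))
}

# per-arm classical analyses on the cleaned tables
run_analysis_arms <- function(trials, cleaned, config) {
  out <- list(); json <- list()
  tmsrt <- cleaned$tms$trials
  if ("practice" %in% config$arms) {
    prac <- cleaned$practice$trials
    prac <- prac[prac$congruency %in% c("congruent", "incongruent"), ]
    prac$timepoint <- factor(practice_timepoint(prac$session, prac$block))
    out$practice <- lmm_rt(prac, fixed = c("congruency", "timepoint"))
    json$practice <- list(anova = out$practice$anova,
                          ddf_method = out$practice$ddf_method)
  }
  if ("rtms" %in% config$arms) {
    out$rtms <- lmm_rt(tmsrt, fixed = c("stimulation", "congruency",
                                        "order_group"))
    json$rtms <- list(anova = out$rtms$anova,
                      ddf_method = out$rtms$ddf_method)
    json$rtms$cell_summary <- condition_summary(cleaned$tms_acc$trials)
  }
  if ("sce" %in% config$arms) {
    agg <- stats::aggregate(rt_s ~ participant_id + congruency + stimulation,
                            data = tmsrt, FUN = mean)
    agg$mean_rt_ms <- agg$rt_s * 1000
    wide <- stats::reshape(
      agg[, c("participant_id", "congruency", "stimulation", "mean_rt_ms")],
      idvar = c("participant_id", "stimulation"), timevar = "congruency",
      direction = "wide")
    names(wide) <- sub("^mean_rt_ms\\.", "", names(wide))
    comp <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
      ds <- derived_stats(wide$congruent[i], wide$incongruent[i],
                          wide$neutral[i])
      data.frame(participant_id = wide$participant_id[i],
                 stimulation = wide$stimulation[i], sce = ds$sce,
                 facilitation = ds$facilitation,
                 interference = ds$interference)
    }))
    ord <- unique(tmsrt[, c("participant_id", "order_group")])
    comp <- merge(comp, ord, by = "participant_id")
    # exclusion by extreme SCE (participant average over stimulation)
    psce <- tapply(comp$sce, comp$participant_id, mean)
    excl <- exclude_participants_sce(psce)
    comp_kept <- comp[!comp$participant_id %in% excl, ]
    sce_tests <- lapply(
      stats::setNames(c("sce", "facilitation", "interference"),
                      c("sce", "facilitation", "interference")),
      function(m) as.data.frame(rm_anova_mixed(
        comp_kept, dv = m, within = "stimulation", between = "order_group",
        id = "participant_id")))
    rt_ps <- tapply(tmsrt$rt_s * 1000,
                    list(tmsrt$participant_id, tmsrt$stimulation), mean)
    out$sce <- list(components = comp, excluded = excl, anovas = sce_tests,
                    rtms_effect_pct = rtms_effect_percent(rt_ps[, "active"],
                                                          rt_ps[, "sham"]))
    json$sce <- list(excluded = excl, anovas = sce_tests,
                     rtms_effect_pct = as.list(out$sce$rtms_effect_pct))
  }
  if ("distance" %in% config$arms) {
    out$distance <- distance_analysis(tmsrt)
    json$distance <- list(anova = as.data.frame(out$distance$anova))
  }
  out$json <- json
  out
}

write_report <- function(path, cleaned, infer, analysis, stamp) {
  lines <- c("# Pipeline report", "",
             sprintf("seed: %d; config: %s", stamp$seed, stamp$config_hash),
             "", "## Cleaning (TMS session)", "",
             "| stage | rows in | removed | fraction |",
             "|---|---|---|---|")
  st <- cleaned$tms$report$stages
  lines <- c(lines, sprintf("| %s | %d | %d | %.3f |", st$stage, st$rows_in,
                            st$rows_removed, st$fraction_removed))
  an <- as.data.frame(infer$anova)
  lines <- c(lines, "", "## Drift-rate ANOVA", "",
             "| term | F | df | p |", "|---|---|---|---|",
             sprintf("| %s | %.3f | (%d, %d) | %.4g |", an$term, an$F,
                     an$df_num, an$df_den, an$p))
  if (!is.null(analysis$json$rtms$cell_summary)) {
    cs <- analysis$json$rtms$cell_summary
    lines <- c(lines, "", "## Cell means (mean ± SEM, ms)", "",
               "| congruency | stimulation | RT | accuracy |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %.0f ± %.0f | %.3f |",
                       cs$congruency, cs$stimulation, cs$mean_rt_ms,
                       cs$sem_rt_ms, cs$accuracy))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"` object.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$simulate$truth
  truth <- structure(list(
    cells = as.data.frame(lapply(tr$cells, unlist),
                          stringsAsFactors = FALSE),
    practice_v_factor = unlist(tr$practice_v_factor),
    practice_t0_factor = unlist(tr$practice_t0_factor),
    miss_rate = tr$miss_rate, coil_sd_mm = tr$coil_sd_mm,
    coil_exceed_rate = tr$coil_exceed_rate, p_c = tr$p_c,
    contaminant_rt_window = unlist(tr$contaminant_rt_window),
    between_participant_sd = unlist(tr$between_participant_sd)),
    class = "generative_truth")
  sim <- list(config = do.call(design_config, y$simulate$config),
              truth = truth)
  pipeline_config(out_dir = y$out_dir, input = y$input, simulate = sim,
                  seed = y$seed, cleaning = y$cleaning,
                  fit = y$fit, arms = unlist(y$arms))
}
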