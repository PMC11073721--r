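# Classical reaction-time analysis arm: derived statistics, mixed models,
# mixed/repeated-measures ANOVA, the numerical-distance analysis, and the
# exploratory backward-selection covariate regression.

#' Per-cell condition summaries
#'
#' Mean RT, its standard error, accuracy and trial counts per condition
#' cell.  RT summaries use correct trials only; accuracy is computed over
#' all responded trials.
#'
#' @param trials Cleaned-for-accuracy trial table (missed removed) with
#'   `participant_id`, `response`, `correct_side`, `rt_s` and the
#'   grouping columns.
#' @param by Character vector of grouping columns (default congruency by
#'   stimulation).
#' @return Data frame with `mean_rt_ms`, `sem_rt_ms`, `accuracy`,
#'   `n_trials` per cell.
#' @export
condition_summary <- function(trials, by = c("congruency", "stimulation")) {
  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  correct <- trials$response == trials$correct_side
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- trials[key == k, , drop = FALSE]
    okc <- sub$response == sub$correct_side
    rt <- sub$rt_s[okc] * 1000
    cbind(unique(sub[by])[1, , drop = FALSE],
          data.frame(mean_rt_ms = mean(rt),
                     sem_rt_ms = stats::sd(rt) / sqrt(length(rt)),
                     accuracy = mean(okc), n_trials = nrow(sub)))
  }))
  rownames(out) <- NULL
  out
}

#' Size congruency effect and its components
#'
#' From cell mean RTs (ms): `SCE = RT(incongruent) - RT(congruent)`,
#' facilitation `= RT(neutral) - RT(congruent)`, interference
#' `= RT(incongruent) - RT(neutral)`; the components sum to the SCE by
#' construction.  Without a neutral mean the components are `NA`.
#'
#' @param congruent,incongruent Cell mean RTs in ms.
#' @param neutral Neutral-cell mean RT in ms (optional).
#' @return Object of class `"derived_stats"`: list with `sce`,
#'   `facilitation`, `interference` (ms).
#' @examples
#' derived_stats(congruent = 439, incongruent = 492, neutral = 457)
#' @export
derived_stats <- function(congruent, incongruent, neutral = NULL) {
  if (missing(congruent) || missing(incongruent) ||
      !is.finite(congruent) || !is.finite(incongruent))
    stop("both congruent and incongruent means are required")
  sce <- incongruent - congruent
  if (is.null(neutral) || !is.finite(neutral)) {
    fac <- NA_real_; int <- NA_real_
  } else {
    fac <- neutral - congruent
    int <- incongruent - neutral
  }
  structure(list(sce = sce, facilitation = fac, interference = int),
            class = "derived_stats")
}

#' @export
print.derived_stats <- function(x, ...) {
  cat(sprintf("SCE %.1f ms = facilitation %.1f ms + interference %.1f ms\n",
              x$sce, x$facilitation, x$interference))
  invisible(x)
}

#' rTMS effect as a percentage of sham reaction time
#'
#' `100 * (active - sham) / sham`; negative values mean faster responding
#' under active stimulation.
#'
#' @param rt_active,rt_sham Mean RTs (ms) under active and sham rTMS;
#'   `rt_sham` must be positive.
#' @return Percentage (numeric, vectorised).
#' @examples
#' rtms_effect_percent(400, 500)  # -20
#' @export
rtms_effect_percent <- function(rt_active, rt_sham) {
  if (any(!is.finite(rt_sham)) || any(rt_sham <= 0))
    stop("'rt_sham' must be positive")
  100 * (rt_active - rt_sham) / rt_sham
}

#' Linear mixed model on correct reaction times
#'
#' Fits `rt_ms ~ fixed1 * fixed2 * ... + (1 | participant)` on
#' correct-trial RTs with [lmerTest::lmer()], reports Type-III omnibus
#' F-tests with Satterthwaite denominator degrees of freedom (the method
#' is recorded in the output), and Bonferroni-corrected pairwise post-hoc
#' contrasts per fixed factor via emmeans.
#'
#' @param trials Cleaned trial table (correct trials; `rt_s` in seconds).
#' @param fixed Character vector of fixed-effect factor columns, crossed.
#' @param random Participant column used as the random intercept.
#' @return Object of class `"lmm_rt"`: `anova` table (term, F, df, p),
#'   `posthoc` list of Bonferroni-adjusted pairwise contrasts, `ddf_method`,
#'   and the fitted `model`.
#' @export
lmm_rt <- function(trials, fixed, random = "participant_id") {
  miss <- setdiff(c(fixed, random, "rt_s"), names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dat <- as.data.frame(trials)
  dat$rt_ms <- dat$rt_s * 1000
  if (length(unique(dat[[random]])) < 2)
    stop("need more than one participant for a random-intercept model")
  for (f in fixed) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2)
      stop("fixed factor with a single level (aliased term): ", f)
  }
  contr <- stats::setNames(rep(list(stats::contr.sum), length(fixed)), fixed)
  form <- stats::as.formula(paste(
    "rt_ms ~", paste(fixed, collapse = " * "), "+ (1 |", random, ")"))
  model <- lmerTest::lmer(form, data = dat, contrasts = contr)
  if (any(is.na(lme4::fixef(model))))
    stop("rank-deficient design: aliased terms ",
         paste(names(lme4::fixef(model))[is.na(lme4::fixef(model))],
               collapse = ", "))
  at <- stats::anova(model, type = 3, ddf = "Satterthwaite")
  anova_tab <- data.frame(term = rownames(at), F = at$`F value`,
                          df_num = at$NumDF, df_den = at$DenDF,
                          p = at$`Pr(>F)`, stringsAsFactors = FALSE)
  posthoc <- lapply(stats::setNames(fixed, fixed), function(f) {
    em <- emmeans::emmeans(model, stats::as.formula(paste("~", f)))
    as.data.frame(emmeans::contrast(em, method = "pairwise",
                                    adjust = "bonferroni"))
  })
  structure(list(anova = anova_tab, posthoc = posthoc,
                 ddf_method = "Satterthwaite", model = model),
            class = "lmm_rt")
}

#' @export
print.lmm_rt <- function(x, ...) {
  cat(sprintf("Linear mixed model on correct RTs (ms); Type III, %s df\n",
              x$ddf_method))
  tab <- x$anova
  tab$F <- round(tab$F, 3); tab$df_den <- round(tab$df_den, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Numerical-distance analysis
#'
#' Categorises trials into small (distance 1-3) and large (distance 4-8)
#' numerical distance, computes per-participant cell mean RTs, and runs a
#' 2x2 within-subject ANOVA of Numerical Distance by Stimulation on them.
#'
#' @param trials Cleaned TMS trials with `distance`, `stimulation`,
#'   `participant_id`, `rt_s`.
#' @return List with `cell_means` (per participant) and `anova`
#'   (an `"rm_anova"` table).
#' @export
distance_analysis <- function(trials) {
  miss <- setdiff(c("participant_id", "distance", "stimulation", "rt_s"),
                  names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(trials$distance < 1 | trials$distance > 8))
    stop("distance outside 1-8")
  dat <- as.data.frame(trials)
  dat$distance_cat <- ifelse(dat$distance <= 3, "small", "large")
  agg <- stats::aggregate(rt_s ~ participant_id + distance_cat + stimulation,
                          data = dat, FUN = mean)
  agg$mean_rt_ms <- agg$rt_s * 1000
  an <- rm_anova_within(agg, dv = "mean_rt_ms",
                        within = c("distance_cat", "stimulation"),
                        id = "participant_id")
  list(cell_means = agg[, c("participant_id", "distance_cat", "stimulation",
                            "mean_rt_ms")],
       anova = an)
}

#' Backward-selection linear regression
#'
#' Ordinary least squares with iterative backward elimination: while any
#' retained predictor's coefficient p-value is at or above `p_out`
#' (default 0.10), the least significant one is removed; the final model
#' keeps only predictors with `p < p_out`.  Constant or aliased
#' (perfectly collinear) predictors are dropped with a warning before
#' selection starts.
#'
#' @param data Data frame holding outcome and predictors (one row per
#'   participant).
#' @param outcome Outcome column name (e.g. the per-participant
#'   rTMS-effect percentage).
#' @param predictors Character vector of candidate predictor columns.
#' @param p_out Removal threshold: predictors with `p >= p_out` are
#'   candidates for elimination.
#' @return Object of class `"backward_lm"`: `retained` predictors,
#'   `dropped` (in removal order), overall `F`, `df`, `p`,
#'   `adj_r_squared` (as a percentage), `coefficients`, and the final
#'   `model` (an `lm`).
#' @export
backward_regression <- function(data, outcome, predictors, p_out = 0.10) {
  data <- as.data.frame(data)
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(data) <= 2) stop("need more than 2 observations")
  keep <- predictors
  const <- keep[vapply(keep, function(p) stats::var(data[[p]]) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant predictor(s): ", paste(const, collapse = ", "))
    keep <- setdiff(keep, const)
  }
  dropped <- const
  fit_now <- function(vars) {
    f <- if (length(vars))
      stats::as.formula(paste(outcome, "~", paste(vars, collapse = " + ")))
    else stats::as.formula(paste(outcome, "~ 1"))
    stats::lm(f, data = data)
  }
  model <- fit_now(keep)
  aliased <- names(which(is.na(stats::coef(model))))
  if (length(aliased)) {
    warning("dropping aliased predictor(s): ", paste(aliased, collapse = ", "))
    keep <- setdiff(keep, aliased)
    dropped <- c(dropped, aliased)
    model <- fit_now(keep)
  }
  repeat {
    if (!length(keep)) break
    ct <- summary(model)$coefficients
    rows <- setdiff(rownames(ct), "(Intercept)")
    pv <- stats::setNames(ct[rows, 4], rows)
    if (!length(pv) || max(pv) < p_out) break
    worst <- names(which.max(pv))
    keep <- setdiff(keep, worst)
    dropped <- c(dropped, worst)
    model <- fit_now(keep)
  }
  sm <- summary(model)
  fs <- sm$fstatistic
  structure(list(
    retained = keep, dropped = dropped,
    F = if (is.null(fs)) NA_real_ else unname(fs[1]),
    df = if (is.null(fs)) c(NA, NA) else unname(fs[2:3]),
    p = if (is.null(fs)) NA_real_ else
      unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    adj_r_squared = 100 * sm$adj.r.squared,
    coefficients = sm$coefficients, p_out = p_out, model = model),
    class = "backward_lm")
}

#' @export
print.backward_lm <- function(x, ...) {
  cat("Backward-selection linear regression (p_out =", x$p_out, ")\n")
  if (length(x$retained)) {
    cat("retained:", paste(x$retained, collapse = ", "), "\n")
    cat(sprintf("final model F(%g, %g) = %.3f, p = %.4g, adjusted R^2 = %.1f%%\n",
                x$df[1], x$df[2], x$F, x$p, x$adj_r_squared))
  } else cat("intercept-only model retained\n")
  invisible(x)
}

#' Pearson correlation between two participant-level covariates
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, with
#'   non-zero variance).
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
correlate_covariate <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
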