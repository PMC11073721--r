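#' EZ-style moment inversion for initial parameter values
#'
#' Closed-form mapping from accuracy and the mean and variance of response
#' times to `(v, a, t0)` under the simple unbiased diffusion (unit
#' diffusion scale).  Used to seed the maximum-likelihood search and as a
#' moment-matching cross-check.  Accuracies of exactly 0 or 1 are
#' edge-corrected to `1/(2n)` from the boundary when `n` is supplied;
#' an exact 0.5 takes the zero-drift limiting branch, in which the
#' boundary comes from the driftless decision-time variance `a^4 / 24`.
#'
#' @param accuracy Proportion correct in (0, 1) (0/1 allowed with `n`).
#' @param mean_rt Mean response time (s).
#' @param var_rt Response-time variance (s^2), > 0.
#' @param n Trial count used for the edge correction (optional).
#' @param p_c Contaminant proportion stored on the returned parameters.
#' @return A [ddm_params()] object with `w = 0.5`.
#' @examples
#' ez_moments_init(accuracy = 0.85, mean_rt = 0.5, var_rt = 0.02)
#' @export
ez_moments_init <- function(accuracy, mean_rt, var_rt, n = NULL, p_c = 0) {
  if (!is.numeric(var_rt) || length(var_rt) != 1L || !is.finite(var_rt) ||
      var_rt <= 0)
    stop("'var_rt' must be a single positive number")
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 1)
    stop("'accuracy' must be a proportion")
  if (accuracy %in% c(0, 1)) {
    if (is.null(n) || n < 1) {
      # no trial count to edge-correct with: fall back to defaults
      return(ddm_params(v = 1, a = 1, t0 = max(mean_rt - 0.25, 0), p_c = p_c))
    }
    accuracy <- abs(accuracy - 1 / (2 * n))
  }
  if (abs(accuracy - 0.5) < 1e-12) {
    a <- (24 * var_rt)^0.25
    t0 <- max(mean_rt - a^2 / 4, 0)
    return(ddm_params(v = 0, a = a, t0 = t0, p_c = p_c))
  }
  L <- stats::qlogis(accuracy)
  x <- L * (L * accuracy^2 - L * accuracy + accuracy - 0.5) / var_rt
  v <- sign(accuracy - 0.5) * x^0.25
  a <- L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a)) / (1 + exp(-v * a))
  t0 <- max(mean_rt - mdt, 0)
  ddm_params(v = v, a = a, t0 = t0, p_c = p_c)
}

fit_control <- function(p_c = 0.05, n_restarts = 5L, min_trials = 20L,
                        reltol = 1e-6, maxit = 500L, jitter_sd = 0.3) {
  list(p_c = p_c, n_restarts = as.integer(n_restarts),
       min_trials = as.integer(min_trials), reltol = reltol,
       maxit = as.integer(maxit), jitter_sd = jitter_sd)
}

#' Fit the drift-diffusion model to one condition cell
#'
#' Maximum-likelihood estimation of `(v, a, t0)` from trial-level choices
#' and response times, with the start point fixed at `w = 0.5` and the
#' contaminant proportion fixed at `p_c` (default 0.05, not estimated).
#' The summed [trial_loglik()] is maximised by a multi-start Nelder-Mead
#' simplex: one start at the [ez_moments_init()] solution plus jittered
#' restarts, on a smooth reparameterisation that enforces `a > 0` and
#' keeps `t0` inside its admissible range (below the smallest observed RT
#' when `p_c = 0`; bounded by the largest observed RT otherwise, since
#' contaminant trials may legitimately undercut the true `t0`).
#'
#' @param choice Character (`"correct"`/`"error"`) or logical vector.
#' @param rt Response times in seconds (missed trials must already be
#'   excluded).
#' @param p_c Fixed contaminant proportion.
#' @param n_restarts Number of simplex starts (1 EZ-seeded + jittered).
#' @param min_trials Refuse to fit cells with fewer trials than this.
#' @param rt_window Contaminant support; defaults to the observed RT range.
#' @param seed Integer seed controlling the restart jitter.
#' @param control Optional list from `fit_control()` overriding the above.
#' @param cell Optional label (e.g. `"congruent:active"`) carried in the
#'   result.
#' @return An object of class `"ddm_fit"` with components `params`
#'   (the [ddm_params()] estimate), `loglik`, `n_trials`, `converged`,
#'   `n_restarts_used`, `rt_window`, `cell`, and the data used.  Cells in
#'   which every response is on the same side are fit but flagged
#'   (`one_sided = TRUE`): the drift magnitude is weakly identified there.
#' @examples
#' sim <- simulate_ddm(ddm_params(v = 2, a = 1, t0 = 0.3), 200, seed = 2)
#' fit <- ddm_fit(sim$choice, sim$rt, p_c = 0, seed = 1)
#' coef(fit)
#' @export
ddm_fit <- function(choice, rt, p_c = 0.05, n_restarts = 5L,
                    min_trials = 20L, rt_window = NULL, seed = 1L,
                    control = NULL, cell = NULL) {
  if (is.null(control))
    control <- fit_control(p_c = p_c, n_restarts = n_restarts,
                           min_trials = min_trials)
  upper <- if (is.logical(choice)) choice else choice == "correct"
  keep <- is.finite(rt)
  upper <- upper[keep]; rt <- rt[keep]
  n <- length(rt)
  if (n < control$min_trials)
    stop(sprintf("insufficient data: %d trials, need at least %d",
                 n, control$min_trials))
  if (is.null(rt_window)) rt_window <- range(rt)
  if (diff(rt_window) <= 0) rt_window <- rt_window + c(-0.05, 0.05)
  one_sided <- length(unique(upper)) == 1L

  acc <- mean(upper)
  init <- ez_moments_init(acc, mean(rt), max(stats::var(rt), 1e-6), n = n,
                          p_c = control$p_c)
  t0_max <- if (control$p_c == 0) min(rt) - 1e-6 else max(rt) - 1e-6
  t0_max <- max(t0_max, 0.05)

  to_theta <- function(v, a, t0) {
    t0 <- min(max(t0, 1e-4), t0_max * 0.999)
    c(v, log(a), stats::qlogis(t0 / t0_max))
  }
  from_theta <- function(th)
    list(v = th[1], a = exp(th[2]), t0 = stats::plogis(th[3]) * t0_max)

  negll <- function(th) {
    p <- from_theta(th)
    if (!is.finite(p$a) || p$a <= 0 || p$a > 50) return(1e10)
    .wfpt_nll_cpp(rt, upper, p$v, p$a, p$t0, 0.5, control$p_c,
                  rt_window[1], rt_window[2])
  }

  th0 <- to_theta(init$v, min(max(init$a, 0.2), 5), init$t0)
  starts <- list(th0)
  if (control$n_restarts > 1L) {
    rs <- local_seed(seed, {
      lapply(seq_len(control$n_restarts - 1L), function(i)
        th0 + stats::rnorm(3, 0, control$jitter_sd))
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  for (th in starts) {
    opt <- stats::optim(th, negll, method = "Nelder-Mead",
                        control = list(reltol = control$reltol,
                                       maxit = control$maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  est <- from_theta(best$par)
  params <- ddm_params(v = est$v, a = est$a, t0 = est$t0, w = 0.5,
                       p_c = control$p_c)
  structure(list(
    params = params,
    coefficients = c(v = est$v, a = est$a, t0 = est$t0),
    loglik = -best$value,
    n_trials = n,
    converged = best$convergence == 0L,
    n_restarts_used = length(starts),
    one_sided = one_sided,
    rt_window = rt_window,
    cell = cell,
    data = data.frame(choice = ifelse(upper, "correct", "error"), rt = rt,
                      stringsAsFactors = FALSE),
    call = match.call()
  ), class = "ddm_fit")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Drift-diffusion fit",
      if (!is.null(x$cell)) sprintf("(cell %s)", x$cell) else "", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("logLik %.2f on %d trials; p_c fixed at %.3g; %s\n",
              x$loglik, x$n_trials, x$params$p_c,
              if (x$converged) "converged" else "NOT converged"))
  if (x$one_sided)
    cat("note: all responses on one side; drift weakly identified\n")
  invisible(x)
}

#' @export
coef.ddm_fit <- function(object, ...) object$coefficients

#' @export
logLik.ddm_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n_trials, class = "logLik")
}

#' @export
summary.ddm_fit <- function(object, ...) {
  acc <- mean(object$data$choice == "correct")
  structure(list(fit = object, accuracy = acc,
                 mean_rt = mean(object$data$rt),
                 pred_accuracy = absorption_probability(object$params),
                 pred_mean_rt = object$params$t0 +
                   mean_decision_time(object$params)),
            class = "summary.ddm_fit")
}

#' @export
print.summary.ddm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("observed accuracy %.3f (model %.3f); observed mean RT %.3f s (model %.3f)\n",
              x$accuracy, x$pred_accuracy, x$mean_rt, x$pred_mean_rt))
  invisible(x)
}

#' @export
simulate.ddm_fit <- function(object, nsim = object$n_trials, seed = NULL, ...) {
  simulate_ddm(object$params, n = nsim, seed = seed)
}

#' Predicted first-passage density or CDF from a fitted model
#'
#' @param object A `"ddm_fit"` object.
#' @param times Response times (s) at which to evaluate.
#' @param boundary `"correct"` or `"error"`.
#' @param type `"density"` or `"cdf"`.
#' @param ... Unused.
#' @return Numeric vector of defective densities or probabilities.
#' @export
predict.ddm_fit <- function(object, times, boundary = c("correct", "error"),
                            type = c("density", "cdf"), ...) {
  boundary <- match.arg(boundary)
  type <- match.arg(type)
  if (type == "density") wfpt_density(times, boundary, object$params)
  else wfpt_cdf(times, boundary, object$params)
}

#' @export
plot.ddm_fit <- function(x, breaks = 30, ...) {
  rt_c <- x$data$rt[x$data$choice == "correct"]
  h <- graphics::hist(rt_c, breaks = breaks, plot = FALSE)
  p_up <- absorption_probability(x$params)
  tt <- seq(max(min(rt_c) * 0.8, x$params$t0 + 1e-3), max(rt_c), length.out = 200)
  # conditional density of correct RTs under the fitted mixture
  dens <- ((1 - x$params$p_c) * wfpt_density(tt, "correct", x$params) +
             x$params$p_c * 0.5 * stats::dunif(tt, x$rt_window[1], x$rt_window[2])) /
    ((1 - x$params$p_c) * p_up + x$params$p_c * 0.5)
  graphics::plot(h, freq = FALSE, xlab = "correct RT (s)",
                 main = "Observed correct RTs vs fitted density", ...)
  graphics::lines(tt, dens, lwd = 2)
  invisible(x)
}

#' Fit all six congruency-by-stimulation cells for one participant
#'
#' Splits a participant's cleaned TMS-session trials into the six cells
#' (congruent/incongruent/neutral crossed with active/sham), fits each
#' independently with [ddm_fit()], and collects the per-cell drift rates
#' for group inference.
#'
#' @param trials Data frame of one participant's cleaned TMS trials with
#'   columns `congruency`, `stimulation`, `response`, `correct_side`,
#'   `rt_s` (missed trials already removed).
#' @param p_c,n_restarts,min_trials,seed Passed to [ddm_fit()].
#' @return An object of class `"ddm_fit_set"`: a list of six `"ddm_fit"`
#'   objects plus a `drift` table (`congruency`, `stimulation`, `v`, `a`,
#'   `t0`, `loglik`, `n_trials`, `converged`).
#' @export
fit_participant <- function(trials, p_c = 0.05, n_restarts = 5L,
                            min_trials = 20L, seed = 1L) {
  need <- c("congruency", "stimulation", "response", "correct_side", "rt_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cells <- expand.grid(congruency = c("congruent", "incongruent", "neutral"),
                       stimulation = c("active", "sham"),
                       stringsAsFactors = FALSE)
  fits <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- trials$congruency == cells$congruency[i] &
      trials$stimulation == cells$stimulation[i]
    if (!any(sel))
      stop(sprintf("no trials for cell %s:%s", cells$congruency[i],
                   cells$stimulation[i]))
    sub <- trials[sel, , drop = FALSE]
    fits[[i]] <- ddm_fit(sub$response == sub$correct_side, sub$rt_s,
                         p_c = p_c, n_restarts = n_restarts,
                         min_trials = min_trials, seed = seed + i,
                         cell = paste(cells$congruency[i],
                                      cells$stimulation[i], sep = ":"))
  }
  drift <- cbind(cells, do.call(rbind, lapply(fits, function(f)
    data.frame(v = f$coefficients[["v"]], a = f$coefficients[["a"]],
               t0 = f$coefficients[["t0"]], loglik = f$loglik,
               n_trials = f$n_trials, converged = f$converged))))
  structure(list(fits = fits, drift = drift), class = "ddm_fit_set")
}

#' @export
print.ddm_fit_set <- function(x, ...) {
  cat("Per-cell drift-diffusion fits (6 congruency x stimulation cells):\n")
  print(x$drift, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Collect participant-level drift tables for group inference
#'
#' @param fit_sets Named list of `"ddm_fit_set"` objects (names are
#'   participant ids) or a list of per-participant drift data frames.
#' @return Long data frame `participant`, `congruency`, `stimulation`, `v`.
#' @export
drift_table <- function(fit_sets) {
  ids <- names(fit_sets)
  if (is.null(ids)) ids <- as.character(seq_along(fit_sets))
  do.call(rbind, lapply(seq_along(fit_sets), function(i) {
    d <- if (inherits(fit_sets[[i]], "ddm_fit_set")) fit_sets[[i]]$drift
         else fit_sets[[i]]
    data.frame(participant = ids[i], congruency = d$congruency,
               stimulation = d$stimulation, v = d$v,
               stringsAsFactors = FALSE)
  }))
}
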