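#' Drift-diffusion parameter set
#'
#' Bundles the parameters of the two-boundary Wiener diffusion used
#' throughout the package, on the unit-diffusion scale (the diffusion
#' coefficient is fixed at 1, which resolves the usual scaling degeneracy;
#' all parameters are reported on that scale).  The upper boundary is the
#' correct response, so `v > 0` means evidence accumulates toward the
#' correct answer.
#'
#' @param v Drift rate (evidence units per second, signed toward the
#'   correct boundary).
#' @param a Boundary separation (> 0).
#' @param t0 Non-decision time in seconds (>= 0): stimulus encoding plus
#'   motor execution, added to the decision time.
#' @param w Relative start point in (0, 1); 0.5 (unbiased) by default —
#'   the three-parameter model has no bias parameter.
#' @param p_c Contaminant proportion in \[0, 1): the fixed probability that
#'   a trial arises from the outlier process rather than the diffusion.
#'
#' @return An object of class `"ddm_params"`: a named list with elements
#'   `v`, `a`, `t0`, `w`, `p_c`.
#' @examples
#' ddm_params(v = 1, a = 1.5, t0 = 0.2)
#' @export
ddm_params <- function(v, a, t0, w = 0.5, p_c = 0) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' (boundary separation) must be a single positive number")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0)
    stop("'t0' (non-decision time) must be a single non-negative number")
  if (!is.numeric(w) || length(w) != 1L || w <= 0 || w >= 1)
    stop("'w' (relative start point) must lie strictly between 0 and 1")
  if (!is.numeric(p_c) || length(p_c) != 1L || p_c < 0 || p_c >= 1)
    stop("'p_c' (contaminant proportion) must lie in [0, 1)")
  structure(list(v = v, a = a, t0 = t0, w = w, p_c = p_c),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "Wiener diffusion parameters: v = %.4g, a = %.4g, t0 = %.4g s, w = %.3g, p_c = %.3g\n",
    x$v, x$a, x$t0, x$w, x$p_c))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(ddm_params(v = x$v, a = x$a, t0 = x$t0,
                      w = if (is.null(x$w)) 0.5 else x$w,
                      p_c = if (is.null(x$p_c)) 0 else x$p_c))
  }
  stop("cannot interpret 'params' as ddm_params")
}

#' First-passage-time density of the Wiener diffusion
#'
#' Defective density of the response time `t` at the indicated boundary
#' (correct = upper).  Computed as the series expansion of the standardised
#' density with an adaptive number of terms, switching between the
#' small-time and large-time expansions by the fewer-terms rule; the
#' absolute error of the returned value is bounded by 1e-7 (the internal
#' tolerance is 1e-9).  Returns 0 for `t <= t0`.
#'
#' @param t Response times in seconds (decision time is `t - t0`);
#'   vectorised.
#' @param boundary `"correct"` (upper) or `"error"` (lower); recycled
#'   against `t`.
#' @param params A [ddm_params()] object (or coercible list).
#' @return Numeric vector of densities (1/s).  These are *defective*
#'   densities: each boundary's density integrates to that boundary's
#'   absorption probability, the two summing to 1.
#' @examples
#' p <- ddm_params(v = 1, a = 1.5, t0 = 0.2)
#' wfpt_density(c(0.1, 0.4, 0.8), "correct", p)
#' @export
wfpt_density <- function(t, boundary = c("correct", "error"), params) {
  boundary <- match.arg(boundary, several.ok = TRUE)
  params <- as_ddm_params(params)
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric")
  upper <- rep_len(boundary == "correct", length(t))
  .wfpt_pdf_cpp(as.numeric(t), upper, params$v, params$a, params$t0,
                params$w, 1e-9)
}

#' Cumulative first-passage distribution
#'
#' Defective CDF at the indicated boundary, by adaptive quadrature of
#' [wfpt_density()].
#'
#' @inheritParams wfpt_density
#' @param q Response times in seconds; vectorised.
#' @return Numeric vector of defective probabilities.
#' @export
wfpt_cdf <- function(q, boundary = c("correct", "error"), params) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  vapply(q, function(qi) {
    if (qi <= params$t0) return(0)
    stats::integrate(function(x) wfpt_density(x, boundary, params),
                     lower = params$t0, upper = qi,
                     rel.tol = 1e-8, abs.tol = 1e-10,
                     subdivisions = 500L)$value
  }, numeric(1))
}

#' Probability of absorption at the correct boundary
#'
#' Closed-form probability that the diffusion terminates at the upper
#' (correct) boundary: for unit diffusion, start `z = a*w`,
#' `P = (1 - exp(-2*v*z)) / (1 - exp(-2*v*a))`, with the `v -> 0` limit
#' `P = w` (so 0.5 for an unbiased start).
#'
#' @inheritParams wfpt_density
#' @return A single probability.
#' @examples
#' absorption_probability(ddm_params(v = 1, a = 2, t0 = 0))
#' @export
absorption_probability <- function(params) {
  params <- as_ddm_params(params)
  if (abs(params$v) < 1e-10) return(params$w)
  expm1(-2 * params$v * params$a * params$w) / expm1(-2 * params$v * params$a)
}

# Unconditional mean decision time (closed form, sigma = 1):
# solves 0.5 m'' + v m' = -1 with absorbing ends, giving
# m(z) = (a * P_upper - z) / v for v != 0 and z * (a - z) at v = 0.
mean_decision_time <- function(params) {
  params <- as_ddm_params(params)
  z <- params$a * params$w
  if (abs(params$v) < 1e-10) return(z * (params$a - z))
  (params$a * absorption_probability(params) - z) / params$v
}

#' Simulate the Wiener diffusion by Euler-Maruyama
#'
#' Reference forward sampler: the diffusion is discretised with step `dt`
#' and run to absorption; the response time is the hitting time plus `t0`.
#' The contaminant proportion `p_c` is ignored here — contaminant trials
#' are injected by the synthetic-data generator, not the sampler.
#'
#' @inheritParams wfpt_density
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; the same seed yields an identical sequence.
#'   If `NULL`, a seed is drawn from R's RNG stream.
#' @param dt Euler time step in seconds (must be positive; <= 1e-3 for the
#'   reference sampler).
#' @param max_t Safety cap on the simulated decision time; paths not yet
#'   absorbed are returned as `NA` with a warning.
#' @return A data frame with columns `choice` (`"correct"`/`"error"`) and
#'   `rt` (seconds).
#' @examples
#' simulate_ddm(ddm_params(v = 2, a = 1, t0 = 0.3), n = 5, seed = 1)
#' @export
simulate_ddm <- function(params, n, seed = NULL, dt = 1e-3, max_t = 30) {
  params <- as_ddm_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive time step")
  n <- as.integer(n)
  if (is.null(seed)) seed <- stats::runif(1, 0, 2^31)
  sim <- .ddm_simulate_cpp(rep(params$v, n), rep(params$a, n),
                           rep(params$t0, n), params$w, dt,
                           as.numeric(seed), max_t)
  if (anyNA(sim$choice))
    warning(sum(is.na(sim$choice)), " path(s) not absorbed within max_t")
  data.frame(choice = ifelse(sim$choice == 1L, "correct", "error"),
             rt = sim$rt, stringsAsFactors = FALSE)
}

#' Log-likelihood of one or more trials under the contaminant mixture
#'
#' Each trial contributes
#' `log((1 - p_c) * f(rt, choice) + p_c * 0.5 * dunif(rt; rt_window))`,
#' the standard "different process" reading of contaminant trials: a
#' uniform RT over the cell's observed response window with either
#' response equally likely.  The mixture density is floored at 1e-29
#' before the log so zero-density RTs (e.g. `rt <= t0` diffusion trials)
#' cannot yield `-Inf`.
#'
#' @param choice Character vector, `"correct"` or `"error"` per trial
#'   (logical `TRUE` = correct also accepted).
#' @param rt Response times in seconds.
#' @param params A [ddm_params()] object; its `p_c` is the mixture weight.
#' @param rt_window Length-2 numeric, the cell's observed RT span used as
#'   the contaminant uniform's support.
#' @param sum If `TRUE` (default) return the summed log-likelihood,
#'   otherwise per-trial contributions.
#' @return Summed log-likelihood (or per-trial vector).
#' @export
trial_loglik <- function(choice, rt, params, rt_window, sum = TRUE) {
  params <- as_ddm_params(params)
  if (length(rt_window) != 2L || !all(is.finite(rt_window)) ||
      diff(rt_window) <= 0 || rt_window[1] < 0)
    stop("'rt_window' must be a positive-length interval with lower bound >= 0")
  upper <- if (is.logical(choice)) choice else choice == "correct"
  if (length(upper) != length(rt)) stop("'choice' and 'rt' lengths differ")
  if (sum) {
    -.wfpt_nll_cpp(as.numeric(rt), upper, params$v, params$a, params$t0,
                   params$w, params$p_c, rt_window[1], rt_window[2])
  } else {
    f <- .wfpt_pdf_cpp(as.numeric(rt), upper, params$v, params$a, params$t0,
                       params$w, 1e-9)
    mix <- (1 - params$p_c) * f
    inwin <- rt >= rt_window[1] & rt <= rt_window[2]
    mix[inwin] <- mix[inwin] + params$p_c * 0.5 / diff(rt_window)
    log(pmax(mix, 1e-29))
  }
}

# Standardised lower-boundary density, exposed for series diagnostics
# (method: "auto", "small", "large").
.wfpt_f0 <- function(u, w, eps = 1e-10, method = c("auto", "small", "large")) {
  method <- match.arg(method)
  .wfpt_f0_cpp(as.numeric(u), w, eps, match(method, c("auto", "small", "large")) - 1L)
}
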