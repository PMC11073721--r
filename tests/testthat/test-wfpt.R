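test_that("parameter validation rejects degenerate values", {
  expect_error(ddm_params(v = 1, a = -1, t0 = 0.2), "boundary")
  expect_error(ddm_params(v = 1, a = 1, t0 = -0.1), "non-decision")
  expect_error(ddm_params(v = 1, a = 1, t0 = 0.2, w = 1), "start point")
  expect_error(ddm_params(v = 1, a = 1, t0 = 0.2, p_c = 1), "contaminant")
})

test_that("density is zero before the non-decision time and symmetric at zero drift", {
  p <- ddm_params(v = 1, a = 1.5, t0 = 0.3)
  expect_identical(wfpt_density(c(0.1, 0.2, 0.3), "correct", p), c(0, 0, 0))
  p0 <- ddm_params(v = 0, a = 1.2, t0 = 0.2, w = 0.5)
  tt <- seq(0.25, 2, by = 0.05)
  expect_equal(wfpt_density(tt, "correct", p0), wfpt_density(tt, "error", p0),
               tolerance = 1e-10)
})

test_that("small-time and large-time series agree in their overlap region", {
  for (w in c(0.3, 0.5, 0.7)) {
    u <- seq(0.1, 1.5, by = 0.05)
    fs <- stroopddm:::.wfpt_f0(u, w, eps = 1e-12, method = "small")
    fl <- stroopddm:::.wfpt_f0(u, w, eps = 1e-12, method = "large")
    expect_lt(max(abs(fs - fl)), 1e-6)
  }
})

test_that("series density matches an independent fixed-term series", {
  p <- ddm_params(v = 1.3, a = 1.8, t0 = 0.25, w = 0.4)
  for (t in c(0.3, 0.5, 0.9, 1.6)) {
    for (up in c(TRUE, FALSE)) {
      expect_equal(wfpt_density(t, if (up) "correct" else "error", p),
                   oracle_wfpt_density(t, up, p$v, p$a, p$t0, p$w),
                   tolerance = 1e-8)
    }
  }
})

test_that("defective densities integrate to the absorption probabilities", {
  for (v in c(-1, 0.5, 2)) {
    for (w in c(0.4, 0.5)) {
      p <- ddm_params(v = v, a = 1.4, t0 = 0.2, w = w)
      up <- integrate(function(t) wfpt_density(t, "correct", p), p$t0, Inf,
                      rel.tol = 1e-9)$value
      lo <- integrate(function(t) wfpt_density(t, "error", p), p$t0, Inf,
                      rel.tol = 1e-9)$value
      expect_lt(abs(up - absorption_probability(p)), 1e-4)
      expect_lt(abs(up + lo - 1), 1e-4)
    }
  }
})

test_that("absorption probability has the closed form and the driftless limit", {
  p <- ddm_params(v = 1, a = 2, t0 = 0, w = 0.5)
  # hard-coded closed form: P = (1 - e^{-2 v a w}) / (1 - e^{-2 v a})
  expect_equal(absorption_probability(p),
               (1 - exp(-2 * 1 * 2 * 0.5)) / (1 - exp(-2 * 1 * 2)),
               tolerance = 1e-12)
  expect_equal(absorption_probability(ddm_params(v = 0, a = 2, t0 = 0)), 0.5)
  expect_equal(absorption_probability(ddm_params(v = 0, a = 2, t0 = 0, w = 0.3)),
               0.3)
})

test_that("simulator is seed-deterministic and matches closed forms", {
  p <- ddm_params(v = 1, a = 2, t0 = 0.3, w = 0.5)
  s1 <- simulate_ddm(p, 500, seed = 11, dt = 1e-3)
  s2 <- simulate_ddm(p, 500, seed = 11, dt = 1e-3)
  expect_identical(s1, s2)
  expect_error(simulate_ddm(p, 10, seed = 1, dt = 0), "dt")

  n <- 2e4
  s <- simulate_ddm(p, n, seed = 5, dt = 2e-4)
  pc <- absorption_probability(p)
  se <- sqrt(pc * (1 - pc) / n)
  expect_lt(abs(mean(s$choice == "correct") - pc), 3 * se)

  # driftless symmetric diffusion: mean decision time a^2 * w * (1 - w).
  # Discretely monitored paths overshoot, placing the effective boundary
  # 0.5826 * sqrt(dt) beyond each true boundary (continuity correction),
  # so allow that first-order bias on top of the Monte-Carlo error.
  p0 <- ddm_params(v = 0, a = 2, t0 = 0.3, w = 0.5)
  dt <- 2e-4
  s0 <- simulate_ddm(p0, n, seed = 6, dt = dt)
  b <- p0$a / 2
  euler_bias <- (b + 0.5826 * sqrt(dt))^2 - b^2
  expect_lt(abs(mean(s0$rt) - (0.3 + 2^2 * 0.25)),
            3 * sd(s0$rt) / sqrt(n) + euler_bias)
})

test_that("contaminant mixture log-likelihood degenerates and floors correctly", {
  p <- ddm_params(v = 1.5, a = 1.2, t0 = 0.25, p_c = 0)
  win <- c(0.2, 3)
  rts <- c(0.4, 0.6, 1.1)
  expect_equal(trial_loglik(rep("correct", 3), rts, p, win, sum = FALSE),
               log(wfpt_density(rts, "correct", p)))
  # below t0 the diffusion density is 0: only the contaminant term remains
  p5 <- ddm_params(v = 1.5, a = 1.2, t0 = 0.25, p_c = 0.05)
  expect_equal(trial_loglik("correct", 0.22, p5, win, sum = FALSE),
               log(0.05 * 0.5 / diff(win)))
  # with p_c = 0 a pre-t0 RT hits the floor rather than -Inf
  expect_equal(trial_loglik("correct", 0.1, p, win, sum = FALSE), log(1e-29))
  expect_error(trial_loglik("correct", 0.4, p, c(1, 1)), "rt_window")
})

test_that("mixture log-likelihood matches term-by-term independent computation", {
  p <- ddm_params(v = 1.2, a = 1.4, t0 = 0.22, p_c = 0.05)
  win <- c(0.2, 2.5)
  set.seed(3)
  rts <- runif(20, 0.3, 2)
  chs <- sample(c("correct", "error"), 20, replace = TRUE)
  expected <- vapply(seq_along(rts), function(i) {
    f <- oracle_wfpt_density(rts[i], chs[i] == "correct", p$v, p$a, p$t0, p$w)
    log((1 - 0.05) * f + 0.05 * 0.5 / diff(win))
  }, numeric(1))
  expect_equal(trial_loglik(chs, rts, p, win, sum = FALSE), expected,
               tolerance = 1e-7)
  expect_equal(trial_loglik(chs, rts, p, win), sum(expected),
               tolerance = 1e-7)
})

test_that("simulated RTs are distributed as the model CDF (KS, alpha = 0.01)", {
  p <- ddm_params(v = 1.5, a = 1.2, t0 = 0.25)
  n <- 1e4
  s <- simulate_ddm(p, n, seed = 99, dt = 1e-4)
  rt_c <- s$rt[s$choice == "correct"]
  grid <- seq(p$t0, max(rt_c) + 0.5, length.out = 3000)
  dens <- wfpt_density(grid, "correct", p)
  cdf <- cumsum(c(0, diff(grid) * (head(dens, -1) + tail(dens, -1)) / 2))
  cdf_fun <- approxfun(grid, cdf / absorption_probability(p), rule = 2)
  ks <- suppressWarnings(ks.test(rt_c, cdf_fun))
  expect_gt(ks$p.value, 0.01)
})
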