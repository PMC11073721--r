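test_that("derived statistics follow the printed subtraction formulas", {
  # the study's group means: incongruent 492, congruent 439, neutral 457 ms
  ds <- derived_stats(congruent = 439, incongruent = 492, neutral = 457)
  expect_equal(ds$sce, 53)
  expect_equal(ds$facilitation, 18)
  expect_equal(ds$interference, 35)
  ds0 <- derived_stats(450, 450, 450)
  expect_equal(unlist(ds0[c("sce", "facilitation", "interference")]),
               c(sce = 0, facilitation = 0, interference = 0))
  expect_error(derived_stats(incongruent = 492), "required")
  expect_true(is.na(derived_stats(439, 492)$facilitation))
})

test_that("SCE always equals facilitation plus interference", {
  set.seed(4)
  for (i in 1:50) {
    m <- rnorm(3, 470, 40)
    ds <- derived_stats(m[1], m[2], m[3])
    expect_equal(ds$sce, ds$facilitation + ds$interference, tolerance = 1e-12)
  }
})

test_that("rTMS-effect percentage is a signed sham-relative change", {
  expect_equal(rtms_effect_percent(500, 500), 0)
  expect_equal(rtms_effect_percent(400, 500), -20)
  expect_equal(rtms_effect_percent(505, 500), 1)
  expect_error(rtms_effect_percent(400, 0), "positive")
})

make_practice_trials <- function(n_participants = 10, cong_gap_ms = 70,
                                 tp_eff_ms = 0, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_participants)),
                   congruency = c("congruent", "incongruent"),
                   timepoint = 1:6, rep = 1:20, stringsAsFactors = FALSE)
  subj <- rnorm(n_participants, 0, 30)
  names(subj) <- sprintf("P%02d", seq_len(n_participants))
  g$rt_s <- (500 + subj[g$participant_id] +
               cong_gap_ms * (g$congruency == "incongruent") +
               tp_eff_ms * g$timepoint + rnorm(nrow(g), 0, 60)) / 1000
  g
}

test_that("mixed model detects a congruency gap and not a null timepoint effect", {
  tr <- make_practice_trials(cong_gap_ms = 70, tp_eff_ms = 0, seed = 2)
  m <- lmm_rt(tr, fixed = c("congruency", "timepoint"))
  tab <- m$anova
  expect_lt(tab$p[tab$term == "congruency"], 0.001)
  expect_gt(tab$p[tab$term == "timepoint"], 0.05)
  expect_equal(m$ddf_method, "Satterthwaite")
  expect_true(all(c("congruency", "timepoint") %in% names(m$posthoc)))
})

test_that("mixed model is invariant to participant relabelling and guards inputs", {
  tr <- make_practice_trials(seed = 3)
  m1 <- lmm_rt(tr, fixed = c("congruency", "timepoint"))
  relab <- setNames(sample(unique(tr$participant_id)),
                    unique(tr$participant_id))
  tr2 <- tr
  tr2$participant_id <- unname(relab[tr$participant_id])
  m2 <- lmm_rt(tr2, fixed = c("congruency", "timepoint"))
  expect_equal(as.numeric(logLik(m1$model)), as.numeric(logLik(m2$model)),
               tolerance = 1e-8)
  expect_equal(m1$anova$F, m2$anova$F, tolerance = 1e-6)
  one <- tr[tr$participant_id == "P01", ]
  expect_error(lmm_rt(one, fixed = "congruency"), "participant")
  tr3 <- tr[tr$congruency == "congruent", ]
  expect_error(lmm_rt(tr3, fixed = c("congruency", "timepoint")),
               "single level")
})

test_that("distance analysis categorises at the 3/4 boundary and finds the effect", {
  set.seed(5)
  g <- expand.grid(participant_id = sprintf("P%02d", 1:8),
                   stimulation = c("active", "sham"), rep = 1:40,
                   stringsAsFactors = FALSE)
  g$distance <- sample(1:8, nrow(g), replace = TRUE)
  g$rt_s <- (480 - 23 * (g$distance >= 4) + rnorm(nrow(g), 0, 40)) / 1000
  res <- distance_analysis(g)
  expect_setequal(unique(res$cell_means$distance_cat), c("small", "large"))
  # boundary mapping: 3 -> small, 4 -> large
  g2 <- g; g2$distance <- sample(c(3L, 4L), nrow(g2), replace = TRUE)
  res2 <- distance_analysis(g2)
  cm <- res2$cell_means
  expect_setequal(unique(cm$distance_cat), c("small", "large"))
  small3 <- mean(g2$rt_s[g2$distance == 3]) * 1000
  agg_small <- cm$mean_rt_ms[cm$distance_cat == "small"]
  expect_true(abs(mean(agg_small) - small3) < 30)  # only distance-3 trials feed "small"
  an <- as.data.frame(res$anova)
  expect_lt(an$p[an$term == "distance_cat"], 0.01)
  small <- mean(res$cell_means$mean_rt_ms[res$cell_means$distance_cat == "small"])
  large <- mean(res$cell_means$mean_rt_ms[res$cell_means$distance_cat == "large"])
  expect_lt(large, small)
  g$distance[1] <- 9
  expect_error(distance_analysis(g), "distance")
})

test_that("backward selection keeps signal, drops noise, and honours p_out limits", {
  set.seed(6)
  n <- 30
  dat <- data.frame(intensity = rnorm(n, 128, 20), age = rnorm(n, 39, 14),
                    scd = rnorm(n, 14, 2), act = rnorm(n),
                    sack = rnorm(n, 20, 5), days = rnorm(n, 30, 10))
  dat$y <- 0.15 * dat$intensity + rnorm(n, 0, 1)
  preds <- c("intensity", "age", "scd", "act", "sack", "days")
  br <- backward_regression(dat, "y", preds)
  expect_true("intensity" %in% br$retained)
  expect_lt(br$p, 0.01)
  full <- backward_regression(dat, "y", preds, p_out = 1.0)
  expect_setequal(full$retained, preds)
  none <- backward_regression(dat, "y", preds, p_out = 0)
  expect_length(none$retained, 0)
  # aliased duplicate and constant predictors are dropped with warnings
  dat$dup <- dat$intensity
  expect_warning(br2 <- backward_regression(dat, "y", c(preds, "dup")),
                 "aliased")
  expect_false("dup" %in% br2$retained)
  dat$const <- 1
  expect_warning(br3 <- backward_regression(dat, "y", c("intensity", "const")),
                 "constant")
  expect_false("const" %in% br3$retained)
  expect_error(backward_regression(dat[1:2, ], "y", "intensity"), "more than 2")
})

test_that("intercept-only outcomes emerge from pure-noise predictors", {
  keep_counts <- vapply(1:40, function(i) {
    set.seed(200 + i)
    n <- 15
    dat <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                      x3 = rnorm(n))
    length(backward_regression(dat, "y", c("x1", "x2", "x3"))$retained)
  }, numeric(1))
  expect_gt(mean(keep_counts == 0), 0.5)
})

test_that("covariate correlation matches the closed form and guards input", {
  x <- c(1, 3, 4, 6, 8); y <- c(2, 3, 5, 6, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_covariate(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(correlate_covariate(x, x)$r, 1)
  expect_error(correlate_covariate(x, rep(1, 5)), "zero variance")
  expect_error(correlate_covariate(1:2, 1:2), "3 pairs")
})

test_that("condition summaries report correct-trial RT and overall accuracy", {
  tr <- data.frame(participant_id = "P01",
                   congruency = rep(c("congruent", "incongruent"), each = 4),
                   stimulation = "active",
                   response = c("left", "left", "left", "right",
                                rep("left", 4)),
                   correct_side = "left",
                   rt_s = c(0.4, 0.5, 0.6, 0.9, 0.5, 0.6, 0.7, 0.8),
                   stringsAsFactors = FALSE)
  cs <- condition_summary(tr)
  cong <- cs[cs$congruency == "congruent", ]
  expect_equal(cong$accuracy, 0.75)
  expect_equal(cong$mean_rt_ms, mean(c(0.4, 0.5, 0.6)) * 1000)
  expect_equal(cong$n_trials, 4)
})
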