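test_that("configuration invariants are enforced", {
  expect_error(design_config(tms_block_trials = 70), "divisible by 3")
  expect_error(design_config(practice_trials_v1 = 47), "even")
  expect_error(design_config(max_distance = 9), "max_distance")
  expect_error(design_config(digit_low = 5, digit_high = 5), "digit_high")
  expect_error(design_config(pulse_offsets_ms = c(420, 320, 220)), "ordered")
})

test_that("default schedule reproduces the study block compositions", {
  d <- build_design(design_config(n_participants = 1))
  p1 <- d[d$session == "practice1", ]
  expect_equal(nrow(p1), 48)
  expect_equal(as.integer(table(p1$congruency)[c("congruent", "incongruent")]),
               c(24L, 24L))
  expect_false("neutral" %in% p1$congruency)
  expect_false("neutral" %in% d$congruency[d$session == "mri"])
  for (b in 1:4) {
    blk <- d[d$session == "tms" & d$block == b, ]
    expect_equal(nrow(blk), 72)
    expect_equal(as.integer(table(blk$congruency)), c(24L, 24L, 24L))
  }
  expect_equal(length(unique(d$block[d$session == "mri"])), 4)
  expect_equal(attr(d, "pulse_offsets_ms"), c(220L, 320L, 420L))
})

test_that("digit pairs respect the distance geometry", {
  d <- build_design(design_config(n_participants = 2))
  dist <- abs(d$digit_left - d$digit_right)
  expect_true(all(dist == d$distance))
  expect_true(all(dist >= 1 & dist <= 8))
  expect_true(all(d$digit_left %in% 1:9 & d$digit_right %in% 1:9))
  larger <- ifelse(d$digit_left > d$digit_right, "left", "right")
  expect_identical(larger, d$correct_side)
  d1 <- build_design(design_config(n_participants = 1, max_distance = 1))
  expect_true(all(d1$distance == 1))
})

test_that("schedules are deterministic and order groups counterbalanced", {
  cfg <- design_config(n_participants = 5, seed = 77)
  expect_identical(build_design(cfg), build_design(cfg))
  d <- build_design(cfg)
  og <- tapply(d$order_group, d$participant_id, function(x) x[1])
  expect_lte(abs(sum(og == "active_first") - sum(og == "sham_first")), 1)
  # stimulation labels follow the order group, blockwise
  for (pid in unique(d$participant_id)) {
    tms <- d[d$session == "tms" & d$participant_id == pid, ]
    first_arm <- unique(tms$stimulation[tms$block <= 2])
    second_arm <- unique(tms$stimulation[tms$block >= 3])
    expect_length(first_arm, 1)
    expect_length(second_arm, 1)
    expect_false(first_arm == second_arm)
    expect_equal(first_arm,
                 if (og[[pid]] == "active_first") "active" else "sham")
  }
})

test_that("generate_dataset conserves the schedule and honours the truth", {
  cfg <- design_config(n_participants = 2, seed = 4)
  sch <- build_design(cfg)
  tr <- generate_dataset(sch, generative_truth(), seed = 8)
  expect_equal(nrow(tr), nrow(sch))
  expect_identical(tr[, c("participant_id", "session", "block", "trial",
                          "congruency")],
                   sch[, c("participant_id", "session", "block", "trial",
                           "congruency")])
  expect_identical(generate_dataset(sch, generative_truth(), seed = 8), tr)
  # miss_rate = 0 leaves no unanswered trials
  tr0 <- generate_dataset(sch, generative_truth(miss_rate = 0), seed = 9)
  expect_false(any(tr0$response == "none"))
  expect_true(all(is.finite(tr0$rt_s)))
  # coil deviation only in TMS blocks
  expect_true(all(is.na(tr$coil_dev_mm[tr$session != "tms"])))
  expect_true(all(is.finite(tr$coil_dev_mm[tr$session == "tms"])))
  # a schedule cell the truth does not know is a configuration error
  bad <- sch
  bad$stimulation[1] <- "verum"
  expect_error(generate_dataset(bad, generative_truth(), seed = 1),
               "configuration error")
})

test_that("generative truth validates probabilities, windows and schedules", {
  expect_error(generative_truth(p_c = 1.2), "probabilities")
  expect_error(generative_truth(contaminant_rt_window = c(2, 1)), "window")
  expect_error(generative_truth(practice_v_factor = rep(-1, 6)), "positive")
  expect_error(generative_truth(practice_v_factor = c(1, 1)), "6 timepoints")
})

test_that("cell accuracy converges to the analytic absorption probability", {
  truth <- generative_truth(miss_rate = 0, p_c = 0,
                            between_participant_sd = c(v = 0, a = 0, t0 = 0))
  cfg <- design_config(n_participants = 1, tms_block_trials = 900,
                       practice_trials_v1 = 2, mri_blocks = 0, seed = 10)
  tr <- generate_dataset(build_design(cfg), truth, seed = 11, dt = 2e-4)
  tms <- tr[tr$session == "tms", ]
  for (cell in split(tms, paste(tms$congruency, tms$stimulation))) {
    pars <- truth$cells[truth$cells$congruency == cell$congruency[1] &
                          truth$cells$stimulation == cell$stimulation[1], ]
    pexp <- absorption_probability(ddm_params(pars$v, pars$a, pars$t0))
    pobs <- mean(cell$response == cell$correct_side)
    se <- sqrt(pexp * (1 - pexp) / nrow(cell))
    expect_lt(abs(pobs - pexp), 3 * se + 0.01)
  }
})

test_that("practice schedule produces non-increasing block mean RTs", {
  truth <- generative_truth(miss_rate = 0, p_c = 0)
  # analytic expectation: mean RT = t0*f_t0 + mean decision time at v*f_v
  base <- truth$cells[truth$cells$stimulation == "none" &
                        truth$cells$congruency == "congruent", ]
  exp_rt <- vapply(1:6, function(tp) {
    p <- ddm_params(base$v * truth$practice_v_factor[tp], base$a,
                    base$t0 * truth$practice_t0_factor[tp])
    p$t0 + stroopddm:::mean_decision_time(p)
  }, numeric(1))
  expect_true(all(diff(exp_rt) < 0))
  # empirical check at moderate n
  cfg <- design_config(n_participants = 6, tms_blocks_per_arm = 1,
                       tms_block_trials = 6, seed = 2)
  tr <- generate_dataset(build_design(cfg), truth, seed = 3)
  prac <- tr[tr$session != "tms", ]
  tp <- stroopddm:::practice_timepoint(prac$session, prac$block)
  means <- tapply(prac$rt_s, tp, mean)
  expect_true(all(diff(means) < 0.015))
  expect_lt(means[[6]], means[[1]])
})
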