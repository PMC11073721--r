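#' Design configuration for a synthetic numerical-Stroop rTMS study
#'
#' Encodes the two-visit design: a 48-trial practice block (half
#' congruent, half incongruent — no neutral trials outside visit 2), four
#' in-scanner blocks, a visit-2 practice block and four visit-2
#' stimulation blocks of 72 trials in equal congruent/incongruent/neutral
#' thirds, delivered under active or sham 10 Hz rTMS with a pulse triplet
#' at 220/320/420 ms after stimulus onset and the arm order
#' counterbalanced between participants.  Digit pairs are single digits
#' 1-9 whose numerical distance lies in 1-8.
#'
#' @param n_participants Number of participants.
#' @param practice_trials_v1 Visit-1 practice block length (even; half
#'   congruent, half incongruent).
#' @param mri_blocks,mri_block_trials In-scanner blocks and their length.
#' @param tms_blocks_per_arm Stimulation blocks per arm (active and sham
#'   each get this many).
#' @param tms_block_trials Visit-2 block length; must be divisible by 3
#'   (equal congruent/incongruent/neutral thirds).  Also used for the
#'   visit-2 practice block.
#' @param digit_low,digit_high Inclusive bounds of the single digits.
#' @param max_distance Largest admissible |d1 - d2|.
#' @param pulse_offsets_ms Ordered triple of rTMS pulse offsets (ms).
#' @param order_counterbalanced If `TRUE`, participants alternate between
#'   the active-first and sham-first order groups (sizes differ by at most
#'   one).
#' @param seed Integer seed making [build_design()] deterministic.
#' @return Object of class `"design_config"` (a validated named list).
#' @examples
#' design_config(n_participants = 2)
#' @export
design_config <- function(n_participants = 15L, practice_trials_v1 = 48L,
                          mri_blocks = 4L, mri_block_trials = 48L,
                          tms_blocks_per_arm = 2L, tms_block_trials = 72L,
                          digit_low = 1L, digit_high = 9L, max_distance = 8L,
                          pulse_offsets_ms = c(220L, 320L, 420L),
                          order_counterbalanced = TRUE, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              practice_trials_v1 = as.integer(practice_trials_v1),
              mri_blocks = as.integer(mri_blocks),
              mri_block_trials = as.integer(mri_block_trials),
              tms_blocks_per_arm = as.integer(tms_blocks_per_arm),
              tms_block_trials = as.integer(tms_block_trials),
              digit_low = as.integer(digit_low),
              digit_high = as.integer(digit_high),
              max_distance = as.integer(max_distance),
              pulse_offsets_ms = as.integer(pulse_offsets_ms),
              order_counterbalanced = isTRUE(order_counterbalanced),
              seed = as.integer(seed))
  if (cfg$n_participants < 1) stop("configuration error: need >= 1 participant")
  if (cfg$tms_block_trials %% 3L != 0L)
    stop("configuration error: tms_block_trials must be divisible by 3")
  if (cfg$practice_trials_v1 %% 2L != 0L || cfg$mri_block_trials %% 2L != 0L)
    stop("configuration error: two-condition blocks must have even length")
  if (cfg$digit_high <= cfg$digit_low)
    stop("configuration error: digit_high must exceed digit_low")
  if (cfg$max_distance < 1L ||
      cfg$max_distance > cfg$digit_high - cfg$digit_low)
    stop("configuration error: max_distance outside realizable range")
  if (length(cfg$pulse_offsets_ms) != 3L || is.unsorted(cfg$pulse_offsets_ms))
    stop("configuration error: pulse_offsets_ms must be an ordered triple")
  structure(cfg, class = "design_config")
}

# all admissible (d1 < d2) digit pairs at the configured distances
admissible_pairs <- function(cfg) {
  g <- expand.grid(d1 = cfg$digit_low:cfg$digit_high,
                   d2 = cfg$digit_low:cfg$digit_high)
  g <- g[g$d2 > g$d1 & (g$d2 - g$d1) <= cfg$max_distance, ]
  g
}

# one block's rows: congruency composition shuffled, digit pairs uniform
# over admissible pairs, side assignment randomized
make_block <- function(cfg, pid, session, block, congruency_pool,
                       stimulation, order_group, pairs) {
  nt <- length(congruency_pool)
  congruency <- sample(congruency_pool)
  idx <- sample.int(nrow(pairs), nt, replace = TRUE)
  d1 <- pairs$d1[idx]; d2 <- pairs$d2[idx]   # d2 is the larger digit
  left_is_larger <- sample(c(TRUE, FALSE), nt, replace = TRUE)
  data.frame(
    participant_id = pid, session = session, block = block,
    trial = seq_len(nt), congruency = congruency,
    digit_left = ifelse(left_is_larger, d2, d1),
    digit_right = ifelse(left_is_larger, d1, d2),
    distance = d2 - d1,
    correct_side = ifelse(left_is_larger, "left", "right"),
    response = NA_character_, rt_s = NA_real_,
    stimulation = stimulation, order_group = order_group,
    coil_dev_mm = NA_real_, is_contaminant = NA_integer_,
    stringsAsFactors = FALSE)
}

#' Build the full trial schedule of a synthetic study
#'
#' Produces every trial for every participant, in order, across the
#' visit-1 practice block, the in-scanner blocks, the visit-2 practice
#' block and the visit-2 stimulation blocks — without responses (those
#' are added by [generate_dataset()]).  Stimulation labels follow the
#' participant's order group (all active blocks then all sham, or vice
#' versa); neutral trials occur only in visit 2; digit pairs are drawn
#' uniformly over the admissible pairs, with the larger digit's screen
#' side randomised.  Deterministic given `config$seed`.
#'
#' @param config A [design_config()] object.
#' @return Data frame of trials (one row each) with the schedule columns
#'   (`participant_id`, `session` in `practice1/mri/practice2/tms`,
#'   `block`, `trial`, `congruency`, digits, `distance`, `correct_side`,
#'   `stimulation`, `order_group`) and empty response columns.  The pulse
#'   offsets are carried as attribute `pulse_offsets_ms`.
#' @export
build_design <- function(config) {
  if (!inherits(config, "design_config")) config <- do.call(design_config, config)
  pairs <- admissible_pairs(config)
  third <- config$tms_block_trials / 3L
  half_p <- config$practice_trials_v1 / 2L
  half_m <- config$mri_block_trials / 2L
  local_seed(config$seed, {
    rows <- lapply(seq_len(config$n_participants), function(p) {
      pid <- sprintf("P%02d", p)
      og <- if (config$order_counterbalanced) {
        if (p %% 2L == 1L) "active_first" else "sham_first"
      } else sample(c("active_first", "sham_first"), 1L)
      arm1 <- if (og == "active_first") "active" else "sham"
      arm2 <- if (og == "active_first") "sham" else "active"
      blocks <- list(
        make_block(config, pid, "practice1", 1L,
                   rep(c("congruent", "incongruent"), each = half_p),
                   "none", og, pairs))
      for (b in seq_len(config$mri_blocks))
        blocks <- c(blocks, list(make_block(
          config, pid, "mri", b,
          rep(c("congruent", "incongruent"), each = half_m),
          "none", og, pairs)))
      blocks <- c(blocks, list(make_block(
        config, pid, "practice2", 1L,
        rep(c("congruent", "incongruent", "neutral"), each = third),
        "none", og, pairs)))
      n_arm <- config$tms_blocks_per_arm
      for (b in seq_len(2L * n_arm)) {
        stim <- if (b <= n_arm) arm1 else arm2
        blocks <- c(blocks, list(make_block(
          config, pid, "tms", b,
          rep(c("congruent", "incongruent", "neutral"), each = third),
          stim, og, pairs)))
      }
      do.call(rbind, blocks)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "pulse_offsets_ms") <- config$pulse_offsets_ms
    attr(out, "config") <- config
    out
  })
}

#' Generative truth for a synthetic study
#'
#' The known data-generating process behind [generate_dataset()]: per-cell
#' diffusion parameters for the six congruency-by-stimulation cells
#' (practice trials use the `none`-stimulation cells, equal to the sham
#' cells by default), a practice schedule of multiplicative factors on
#' drift and non-decision time across the six pre-stimulation timepoints,
#' miss and contaminant processes, coil-deviation jitter, and
#' between-participant parameter spread.
#'
#' Defaults echo the study being emulated: congruent trials fastest and
#' incongruent slowest (about 440/460/490 ms cell means), visit-2 accuracy
#' near 88%, a +0.5 drift elevation under active stimulation for congruent
#' trials only, 5% contaminant trials, about 2.1% of TMS trials with coil
#' deviation at or beyond 3 mm, and the practice factors reproducing the
#' gradual speed-up across the six practice timepoints.
#'
#' @param v Named drift rates per congruency level (sham/no-stimulation
#'   baseline).
#' @param a,t0 Baseline boundary separation and non-decision time (s).
#' @param active_v_shift Named additive drift change under active rTMS.
#' @param active_a_shift,active_t0_shift Additive changes of `a` and `t0`
#'   under active rTMS (scalars, applied to all congruency levels).
#' @param practice_v_factor,practice_t0_factor Positive multiplicative
#'   factors on `v` and `t0` for the six practice timepoints (visit-1
#'   practice, the four scanner blocks, visit-2 practice).
#' @param miss_rate Probability a trial receives no response.
#' @param coil_sd_mm Spread of the sub-threshold coil-to-target deviation.
#' @param coil_exceed_rate Probability a TMS trial's deviation is >= 3 mm.
#' @param p_c Contaminant proportion.
#' @param contaminant_rt_window Uniform RT support of contaminant trials
#'   (s); positive length, lower bound >= 0.
#' @param between_participant_sd Named SDs (`v`, `a`, `t0`) of the
#'   participant-level additive offsets; offsets are truncated so that
#'   `a > 0` and `t0 >= 0`.
#' @return Object of class `"generative_truth"` with a `cells` data frame
#'   (congruency x stimulation incl. `none`) and the process parameters.
#' @export
generative_truth <- function(
    v = c(congruent = 3.4, incongruent = 2.0, neutral = 2.8),
    a = 1.0, t0 = 0.30,
    active_v_shift = c(congruent = 0.5, incongruent = 0, neutral = 0),
    active_a_shift = 0, active_t0_shift = 0,
    practice_v_factor = c(0.75, 0.80, 0.85, 0.90, 0.95, 1.0),
    practice_t0_factor = c(1.30, 1.24, 1.18, 1.12, 1.06, 1.0),
    miss_rate = 0.04, coil_sd_mm = 1.2, coil_exceed_rate = 0.021,
    p_c = 0.05, contaminant_rt_window = c(0.2, 3.0),
    between_participant_sd = c(v = 0.3, a = 0.1, t0 = 0.03)) {
  levs <- c("congruent", "incongruent", "neutral")
  if (!all(levs %in% names(v))) stop("'v' needs congruent/incongruent/neutral")
  if (!all(levs %in% names(active_v_shift)))
    stop("'active_v_shift' needs congruent/incongruent/neutral")
  for (p in c(miss_rate, coil_exceed_rate, p_c))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (p_c >= 1) stop("'p_c' must be < 1")
  if (length(contaminant_rt_window) != 2L ||
      diff(contaminant_rt_window) <= 0 || contaminant_rt_window[1] < 0)
    stop("contaminant window must have positive length and lower bound >= 0")
  if (any(practice_v_factor <= 0) || any(practice_t0_factor <= 0))
    stop("practice schedule factors must be positive")
  if (length(practice_v_factor) != 6L || length(practice_t0_factor) != 6L)
    stop("practice schedule needs 6 timepoints")
  if (a <= 0 || t0 < 0) stop("'a' must be > 0 and 't0' >= 0")
  if (!all(c("v", "a", "t0") %in% names(between_participant_sd)))
    stop("'between_participant_sd' needs v, a, t0")

  cells <- expand.grid(congruency = levs,
                       stimulation = c("active", "sham", "none"),
                       stringsAsFactors = FALSE)
  attr(cells, "out.attrs") <- NULL
  cells$v <- v[cells$congruency] +
    ifelse(cells$stimulation == "active", active_v_shift[cells$congruency], 0)
  cells$a <- a + ifelse(cells$stimulation == "active", active_a_shift, 0)
  cells$t0 <- t0 + ifelse(cells$stimulation == "active", active_t0_shift, 0)
  if (any(cells$a <= 0) || any(cells$t0 < 0))
    stop("cell parameters violate a > 0 / t0 >= 0")
  structure(list(cells = cells,
                 practice_v_factor = practice_v_factor,
                 practice_t0_factor = practice_t0_factor,
                 miss_rate = miss_rate, coil_sd_mm = coil_sd_mm,
                 coil_exceed_rate = coil_exceed_rate, p_c = p_c,
                 contaminant_rt_window = contaminant_rt_window,
                 between_participant_sd = between_participant_sd),
            class = "generative_truth")
}

# practice timepoint index 1..6 (visit-1 practice, MRI 1-4, visit-2 practice);
# NA for stimulation blocks
practice_timepoint <- function(session, block) {
  ifelse(session == "practice1", 1L,
         ifelse(session == "mri", 1L + block,
                ifelse(session == "practice2", 6L, NA_integer_)))
}

#' Simulate responses for a trial schedule
#'
#' Forward model: every non-contaminant, non-missed trial's (choice, RT)
#' is drawn from the participant- and cell-specific diffusion process via
#' the Euler-Maruyama sampler (RT = decision time + t0); contaminant
#' trials (probability `p_c`) get a uniform RT on the contaminant window
#' and a random correct/incorrect response; missed trials are flagged with
#' no response; coil deviation is sampled per TMS trial.  Ground-truth
#' flags (`is_contaminant`, true cell parameters) are stored alongside so
#' recovery can be checked.
#'
#' @param schedule Trial schedule from [build_design()].
#' @param truth A [generative_truth()] object.
#' @param seed Integer seed (all sampling is deterministic given it).
#' @param dt Euler step for the diffusion sampler (s).
#' @return The schedule with `response`, `rt_s`, `coil_dev_mm`,
#'   `is_contaminant` filled in and true parameters in `true_v`, `true_a`,
#'   `true_t0`.  Row count and order are exactly those of `schedule`.
#' @export
generate_dataset <- function(schedule, truth, seed = 1L, dt = 1e-3) {
  if (!inherits(truth, "generative_truth"))
    stop("'truth' must be a generative_truth object")
  need <- c("participant_id", "session", "block", "congruency", "stimulation",
            "correct_side")
  miss <- setdiff(need, names(schedule))
  if (length(miss)) stop("schedule is missing columns: ",
                         paste(miss, collapse = ", "))
  cellkey <- function(cg, st) paste(cg, st, sep = ":")
  truthkey <- cellkey(truth$cells$congruency, truth$cells$stimulation)
  sched_cells <- unique(cellkey(schedule$congruency, schedule$stimulation))
  absent <- setdiff(sched_cells, truthkey)
  if (length(absent))
    stop("configuration error: truth has no cell(s) ", paste(absent, collapse = ", "))

  n <- nrow(schedule)
  out <- schedule
  local_seed(seed, {
    pids <- unique(schedule$participant_id)
    bsd <- truth$between_participant_sd
    offs <- data.frame(participant_id = pids,
                       dv = stats::rnorm(length(pids), 0, bsd[["v"]]),
                       da = stats::rnorm(length(pids), 0, bsd[["a"]]),
                       dt0 = stats::rnorm(length(pids), 0, bsd[["t0"]]))
    i <- match(schedule$participant_id, offs$participant_id)
    j <- match(cellkey(schedule$congruency, schedule$stimulation), truthkey)
    v <- truth$cells$v[j] + offs$dv[i]
    a <- pmax(truth$cells$a[j] + offs$da[i], 0.1)   # truncate: a > 0
    t0 <- pmax(truth$cells$t0[j] + offs$dt0[i], 0)  # truncate: t0 >= 0
    tp <- practice_timepoint(schedule$session, schedule$block)
    prac <- !is.na(tp)
    v[prac] <- v[prac] * truth$practice_v_factor[tp[prac]]
    t0[prac] <- t0[prac] * truth$practice_t0_factor[tp[prac]]
    out$true_v <- v; out$true_a <- a; out$true_t0 <- t0

    missed <- stats::runif(n) < truth$miss_rate
    contam <- !missed & stats::runif(n) < truth$p_c
    diffu <- !missed & !contam
    out$is_contaminant <- as.integer(contam)

    if (any(diffu)) {
      sim <- .ddm_simulate_cpp(v[diffu], a[diffu], t0[diffu], 0.5, dt,
                               stats::runif(1, 0, 2^31), 30)
      correct <- sim$choice == 1L
      out$rt_s[diffu] <- sim$rt
      out$response[diffu] <- ifelse(
        correct, schedule$correct_side[diffu],
        ifelse(schedule$correct_side[diffu] == "left", "right", "left"))
    }
    if (any(contam)) {
      w <- truth$contaminant_rt_window
      out$rt_s[contam] <- stats::runif(sum(contam), w[1], w[2])
      ok <- stats::runif(sum(contam)) < 0.5
      out$response[contam] <- ifelse(
        ok, schedule$correct_side[contam],
        ifelse(schedule$correct_side[contam] == "left", "right", "left"))
    }
    out$response[missed] <- "none"
    out$rt_s[missed] <- NA_real_

    tms <- schedule$session == "tms"
    if (any(tms)) {
      nt <- sum(tms)
      exceed <- stats::runif(nt) < truth$coil_exceed_rate
      dev <- numeric(nt)
      dev[exceed] <- stats::runif(sum(exceed), 3, 6)
      # |N(0, sd)| conditioned on < 3 mm, by inverse-CDF
      p3 <- 2 * stats::pnorm(3, sd = truth$coil_sd_mm) - 1
      u <- stats::runif(sum(!exceed), 0, p3)
      dev[!exceed] <- stats::qnorm((1 + u) / 2) * truth$coil_sd_mm
      out$coil_dev_mm[tms] <- dev
    }
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: [build_design()] followed by [generate_dataset()].
#'
#' @param config A [design_config()]; its `seed` drives the schedule.
#' @param truth A [generative_truth()].
#' @param seed Seed for the response-generation stage.
#' @param dt Euler step (s).
#' @return Trial table with responses (see [generate_dataset()]).
#' @export
simulate_study <- function(config = design_config(),
                           truth = generative_truth(), seed = 1L, dt = 1e-3) {
  generate_dataset(build_design(config), truth, seed = seed, dt = dt)
}
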