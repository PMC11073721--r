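# Independent oracles used across tests.  These deliberately share no code
# with the package: sums of squares by explicit cell-mean arithmetic, and a
# fixed-term large-time series for the standardised first-passage density.

# Two-way fully within-subject ANOVA by explicit sums of squares.
oracle_within_anova <- function(y, A, B, S) {
  A <- factor(A); B <- factor(B); S <- factor(S)
  na <- nlevels(A); nb <- nlevels(B); ns <- nlevels(S)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  SS_A <- nb * ns * sum((mA - g)^2)
  SS_B <- na * ns * sum((mB - g)^2)
  SS_S <- na * nb * sum((mS - g)^2)
  SS_AB <- ns * sum((sweep(sweep(mAB, 1, mA), 2, mB) + g)^2)
  SS_AS <- nb * sum((sweep(sweep(mAS, 1, mA), 2, mS) + g)^2)
  SS_BS <- na * sum((sweep(sweep(mBS, 1, mB), 2, mS) + g)^2)
  SS_T <- sum((y - g)^2)
  SS_ABS <- SS_T - SS_A - SS_B - SS_S - SS_AB - SS_AS - SS_BS
  f <- function(ss_eff, df_eff, ss_err, df_err)
    list(F = (ss_eff / df_eff) / (ss_err / df_err),
         p = pf((ss_eff / df_eff) / (ss_err / df_err), df_eff, df_err,
                lower.tail = FALSE))
  list(
    A = c(ss = SS_A, unlist(f(SS_A, na - 1, SS_AS, (na - 1) * (ns - 1)))),
    B = c(ss = SS_B, unlist(f(SS_B, nb - 1, SS_BS, (nb - 1) * (ns - 1)))),
    AB = c(ss = SS_AB,
           unlist(f(SS_AB, (na - 1) * (nb - 1), SS_ABS,
                    (na - 1) * (nb - 1) * (ns - 1)))))
}

# Mixed (one within W, one between G) ANOVA by explicit sums of squares;
# assumes balanced groups.
oracle_mixed_anova <- function(y, W, G, S) {
  W <- factor(W); G <- factor(G); S <- factor(S)
  k <- nlevels(W); ng <- nlevels(G); N <- nlevels(S)
  g <- mean(y)
  mS <- tapply(y, S, mean)
  grp <- tapply(as.character(G), S, function(x) x[1])
  n_g <- table(grp)
  mG <- tapply(y, G, mean); mW <- tapply(y, W, mean)
  mGW <- tapply(y, list(G, W), mean)
  SS_bs <- k * sum((mS - g)^2)
  SS_G <- k * sum(n_g[levels(G)] * (mG - g)^2)
  SS_SG <- SS_bs - SS_G
  SS_W <- N * sum((mW - g)^2)
  SS_cells <- sum(outer(n_g[levels(G)], rep(1, k)) * (mGW - g)^2)
  SS_GW <- SS_cells - SS_G - SS_W
  SS_T <- sum((y - g)^2)
  SS_WS <- SS_T - SS_bs - SS_W - SS_GW
  f <- function(ss_eff, df_eff, ss_err, df_err)
    (ss_eff / df_eff) / (ss_err / df_err)
  list(G = c(ss = SS_G, F = f(SS_G, ng - 1, SS_SG, N - ng)),
       W = c(ss = SS_W, F = f(SS_W, k - 1, SS_WS, (N - ng) * (k - 1))),
       GW = c(ss = SS_GW,
              F = f(SS_GW, (ng - 1) * (k - 1), SS_WS, (N - ng) * (k - 1))))
}

# Independent large-time series for the standardised lower-boundary
# first-passage density, with a fixed (large) number of terms.
oracle_f0_large <- function(u, w, terms = 300) {
  k <- seq_len(terms)
  pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
}

oracle_wfpt_density <- function(t, upper, v, a, t0, w = 0.5) {
  if (t <= t0) return(0)
  tt <- t - t0
  if (upper) { v <- -v; w <- 1 - w }
  exp(-v * a * w - v^2 * tt / 2) / a^2 * oracle_f0_large(tt / a^2, w)
}

# Hand-rolled paired t statistic.
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Toy trial-table builder for cleaning tests.
toy_trials <- function(rt, response = NULL, correct_side = "left",
                       participant = "P01", congruency = "congruent",
                       coil = NULL) {
  n <- length(rt)
  if (is.null(response)) response <- rep("left", n)
  df <- data.frame(participant_id = rep(participant, length.out = n),
                   congruency = rep(congruency, length.out = n),
                   response = response,
                   correct_side = rep(correct_side, length.out = n),
                   rt_s = rt, stringsAsFactors = FALSE)
  if (!is.null(coil)) df$coil_dev_mm <- coil
  df
}

digest_file <- function(path) unname(tools::md5sum(path))

# Simulated trials with injected uniform contaminants, for fit tests.
sim_cell_trials <- function(params, n, p_c, seed, dt = 2e-4,
                            window = c(0.2, 3.0)) {
  set.seed(seed)
  nc <- rbinom(1, n, p_c)
  sim <- simulate_ddm(params, n - nc, seed = seed + 1000L, dt = dt)
  if (nc > 0) {
    crt <- runif(nc, window[1], window[2])
    cch <- ifelse(runif(nc) < 0.5, "correct", "error")
    data.frame(choice = c(sim$choice, cch), rt = c(sim$rt, crt),
               stringsAsFactors = FALSE)
  } else sim
}
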