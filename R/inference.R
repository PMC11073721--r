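# Repeated-measures inference engines shared by the drift-rate analysis
# (congruency x stimulation, both within) and the classical analyses
# (stimulation within x order between; distance x stimulation within).

ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C %*% diag(1 / sqrt(colSums(C^2)), ncol(C))
}

# Greenhouse-Geisser epsilon for one within effect: E = M' S M with S the
# sample covariance of the cell scores and M the effect's orthonormal
# contrast matrix; epsilon = tr(E)^2 / (df * tr(E^2)).
gg_epsilon <- function(S, M) {
  E <- t(M) %*% S %*% M
  d <- ncol(M)
  tr <- sum(diag(E))
  if (tr <= 0) return(1)
  min(tr^2 / (d * sum(E * E)), 1)
}

# Pull (df, SS) rows out of one stratum of a summary.aovlist.
stratum_table <- function(s, stratum) {
  nm <- names(s)
  hit <- which(trimws(sub("^Error:", "", nm)) == stratum)
  if (!length(hit)) stop("ANOVA stratum not found: ", stratum)
  tab <- s[[hit]][[1]]
  data.frame(term = trimws(rownames(tab)), df = tab$Df, ss = tab$`Sum Sq`,
             stringsAsFactors = FALSE)
}

row_of <- function(tab, term) {
  i <- match(term, tab$term)
  if (is.na(tab$term[1]) || is.na(i)) stop("term not found in ANOVA table: ", term)
  tab[i, ]
}

# F, p, partial eta^2 for one effect against its stratum residual, with the
# degenerate 0/0 case (no effect variance at all) reported as F = 0, p = 1.
effect_stats <- function(eff, res) {
  if (eff$ss < 1e-12) return(list(F = 0, p = 1, pes = 0))
  if (res$ss < 1e-12) return(list(F = Inf, p = 0, pes = 1))
  Fv <- (eff$ss / eff$df) / (res$ss / res$df)
  list(F = Fv, p = stats::pf(Fv, eff$df, res$df, lower.tail = FALSE),
       pes = eff$ss / (eff$ss + res$ss))
}

#' Fully within-subject repeated-measures ANOVA
#'
#' One- or two-factor within-subject ANOVA on a complete, balanced
#' participant-by-cell table, with F, degrees of freedom, p, partial eta
#' squared, and a Greenhouse-Geisser sphericity-corrected p for every
#' effect with more than one numerator df.
#'
#' @param data Long data frame.
#' @param dv Name of the response column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param id Name of the participant column.
#' @return Object of class `"rm_anova"`: a data frame with one row per
#'   effect (`term`, `df_num`, `df_den`, `ss`, `F`, `p`, `pes`,
#'   `gg_epsilon`, `p_gg`).
#' @export
rm_anova_within <- function(data, dv = "v", within, id = "participant") {
  stopifnot(length(within) %in% 1:2)
  data <- as.data.frame(data)
  for (col in c(dv, within, id))
    if (!col %in% names(data)) stop("missing column: ", col)
  data[[id]] <- factor(data[[id]])
  for (f in within) data[[f]] <- factor(data[[f]])
  cellf <- if (length(within) == 2L)
    interaction(data[[within[1]]], data[[within[2]]], lex.order = TRUE)
  else data[[within[1]]]
  counts <- table(data[[id]], cellf)
  if (any(counts != 1))
    stop("incomplete table: each participant needs exactly one value per cell")

  form <- stats::as.formula(paste(
    dv, "~", paste(within, collapse = "*"),
    "+ Error(", id, "/(", paste(within, collapse = "*"), "))"))
  s <- summary(stats::aov(form, data = data))

  # cell-score matrix (participants x cells, first factor major) for GG
  Y <- tapply(data[[dv]], list(data[[id]], cellf), identity)
  S <- stats::cov(Y)
  ks <- vapply(within, function(f) nlevels(data[[f]]), integer(1))
  Cs <- lapply(ks, ortho_contrasts)
  js <- lapply(ks, function(k) matrix(1 / sqrt(k), k, 1))
  effect_M <- if (length(within) == 2L) {
    list(kronecker(Cs[[1]], js[[2]]), kronecker(js[[1]], Cs[[2]]),
         kronecker(Cs[[1]], Cs[[2]]))
  } else list(Cs[[1]])
  terms <- if (length(within) == 2L)
    c(within, paste(within, collapse = ":")) else within

  out <- do.call(rbind, lapply(seq_along(terms), function(i) {
    term <- terms[i]
    strat <- stratum_table(s, paste(id, gsub(":", ":", term), sep = ":"))
    eff <- row_of(strat, term)
    res <- row_of(strat, "Residuals")
    st <- effect_stats(eff, res)
    eps <- if (eff$df > 1) gg_epsilon(S, effect_M[[i]]) else 1
    p_gg <- if (is.finite(st$F) && st$F > 0)
      stats::pf(st$F, eps * eff$df, eps * res$df, lower.tail = FALSE)
    else st$p
    data.frame(term = term, df_num = eff$df, df_den = res$df, ss = eff$ss,
               F = st$F, p = st$p, pes = st$pes, gg_epsilon = eps,
               p_gg = p_gg, stringsAsFactors = FALSE)
  }))
  structure(out, class = c("rm_anova", "data.frame"),
            design = "within", n = nlevels(data[[id]]))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s design, n = %d participants)\n",
              attr(x, "design"), attr(x, "n")))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$pes <- round(df$pes, 3)
  df$gg_epsilon <- round(df$gg_epsilon, 3)
  df$p <- signif(df$p, 3); df$p_gg <- signif(df$p_gg, 3)
  df$ss <- signif(df$ss, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Group-level ANOVA on fitted drift rates
#'
#' Two-way fully within-subject repeated-measures ANOVA on the
#' participant-by-cell drift-rate table, with Congruency (3 levels) and
#' Stimulation (2 levels) as within-subject factors.  This is the
#' inference stage behind the headline congruency-by-stimulation
#' interaction on the drift rate.
#'
#' @param drift Long data frame with columns `participant`, `congruency`,
#'   `stimulation`, `v` — e.g. from [drift_table()].
#' @return An `"rm_anova"` table (see [rm_anova_within()]); the
#'   `congruency:stimulation` row is the interaction of interest.
#' @export
drift_anova <- function(drift) {
  need <- c("participant", "congruency", "stimulation", "v")
  miss <- setdiff(need, names(drift))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rm_anova_within(drift, dv = "v", within = c("congruency", "stimulation"),
                  id = "participant")
}

#' Post-hoc active-vs-sham drift comparisons within each congruency level
#'
#' Paired t-test of active vs sham drift within each congruency level,
#' with `df = n_participants - 1`.  Both the unadjusted p (the
#' paper-comparable value for this design) and the Holm-adjusted p across
#' the three congruency levels are reported.
#'
#' @inheritParams drift_anova
#' @return Data frame with one row per congruency level: `congruency`,
#'   `mean_diff` (active minus sham), `t`, `df`, `p`, `p_holm`.
#' @export
posthoc_drift <- function(drift) {
  need <- c("participant", "congruency", "stimulation", "v")
  miss <- setdiff(need, names(drift))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- length(unique(drift$participant))
  if (n < 3) stop("need at least 3 participants for paired comparisons")
  levs <- unique(drift$congruency)
  rows <- lapply(levs, function(cg) {
    a <- drift[drift$congruency == cg & drift$stimulation == "active", ]
    s <- drift[drift$congruency == cg & drift$stimulation == "sham", ]
    m <- merge(a[, c("participant", "v")], s[, c("participant", "v")],
               by = "participant", suffixes = c("_active", "_sham"))
    d <- m$v_active - m$v_sham
    if (stats::sd(d) < 1e-14) {
      data.frame(congruency = cg, mean_diff = mean(d), t = 0,
                 df = nrow(m) - 1L, p = 1, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(m$v_active, m$v_sham, paired = TRUE)
      data.frame(congruency = cg, mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Mixed within-between repeated-measures ANOVA
#'
#' One within-subject factor (e.g. Stimulation: active/sham) crossed with
#' one between-subject factor (e.g. Order of stimulation), the design used
#' for the size-congruency-effect analyses.
#'
#' @param data Long data frame, one row per participant-by-within-level.
#' @param dv Response column name.
#' @param within Within-subject factor column.
#' @param between Between-subject factor column.
#' @param id Participant column.
#' @return An `"rm_anova"` table with rows for the between main effect,
#'   the within main effect, and their interaction.
#' @export
rm_anova_mixed <- function(data, dv = "value", within = "stimulation",
                           between = "order_group", id = "participant") {
  data <- as.data.frame(data)
  for (col in c(dv, within, between, id))
    if (!col %in% names(data)) stop("missing column: ", col)
  data[[id]] <- factor(data[[id]])
  data[[within]] <- factor(data[[within]])
  data[[between]] <- factor(data[[between]])
  counts <- table(data[[id]], data[[within]])
  if (any(counts != 1))
    stop("each participant needs exactly one value per within-factor level")
  grp <- tapply(data[[between]], data[[id]], function(g) as.character(g[1]))
  if (length(unique(grp)) < 2 || any(table(grp) < 2))
    stop("each between-subject group needs at least 2 participants")

  form <- stats::as.formula(paste(
    dv, "~", between, "*", within, "+ Error(", id, "/", within, ")"))
  s <- summary(stats::aov(form, data = data))

  btab <- stratum_table(s, id)
  wtab <- stratum_table(s, paste(id, within, sep = ":"))
  kw <- nlevels(data[[within]])
  # GG from the pooled within-group covariance of cell scores
  Y <- tapply(data[[dv]], list(data[[id]], data[[within]]), identity)
  Spool <- Reduce(`+`, lapply(split(seq_len(nrow(Y)), grp[rownames(Y)]),
                              function(ix) stats::cov(Y[ix, , drop = FALSE]) *
                                (length(ix) - 1))) /
    (nrow(Y) - length(unique(grp)))

  mk <- function(term, tab, M = NULL) {
    eff <- row_of(tab, term)
    res <- row_of(tab, "Residuals")
    st <- effect_stats(eff, res)
    eps <- if (eff$df > 1 && !is.null(M)) gg_epsilon(Spool, M) else 1
    p_gg <- if (is.finite(st$F) && st$F > 0)
      stats::pf(st$F, eps * eff$df, eps * res$df, lower.tail = FALSE)
    else st$p
    data.frame(term = term, df_num = eff$df, df_den = res$df, ss = eff$ss,
               F = st$F, p = st$p, pes = st$pes, gg_epsilon = eps,
               p_gg = p_gg, stringsAsFactors = FALSE)
  }
  Cw <- ortho_contrasts(kw)
  # terms appear in aov output in formula order
  wterm_int <- grep(":", wtab$term, value = TRUE)[1]
  out <- rbind(mk(between, btab),
               mk(within, wtab, Cw),
               mk(wterm_int, wtab, Cw))
  structure(out, class = c("rm_anova", "data.frame"),
            design = "mixed", n = nlevels(data[[id]]))
}
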