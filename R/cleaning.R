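# Staged trial-exclusion cascades with full per-stage accounting, and the
# participant-level exclusion rules.

new_cleaning_report <- function(stages, warnings = character()) {
  structure(list(stages = stages, warnings = warnings),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning cascade:\n")
  df <- x$stages
  df$fraction_removed <- sprintf("%.3f", df$fraction_removed)
  print(df, row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

stage_missed <- function(tr) tr$response != "none" & !is.na(tr$rt_s)
stage_incorrect <- function(tr) tr$response == tr$correct_side

# RT > mean + mult*SD, moments per the configured basis over the rows
# still in play at this stage
stage_rt_outlier <- function(tr, sd_mult, sd_basis) {
  grp <- switch(sd_basis,
                global = rep(1L, nrow(tr)),
                participant = tr$participant_id,
                participant_condition = paste(tr$participant_id, tr$congruency))
  mu <- stats::ave(tr$rt_s, grp, FUN = mean)
  sdv <- stats::ave(tr$rt_s, grp, FUN = stats::sd)
  sdv[is.na(sdv)] <- 0
  tr$rt_s <= mu + sd_mult * sdv
}

run_cascade <- function(trials, stages, sd_mult, sd_basis, min_after = 5L) {
  rows <- list()
  warnings <- character()
  cur <- trials
  for (st in names(stages)) {
    n_in <- nrow(cur)
    keep <- stages[[st]](cur)
    n_rm <- sum(!keep)
    rows[[st]] <- data.frame(stage = st, rows_in = n_in, rows_removed = n_rm,
                             fraction_removed = if (n_in) n_rm / n_in else 0,
                             stringsAsFactors = FALSE)
    cur <- cur[keep, , drop = FALSE]
    if (st == "incorrect") {
      few <- table(cur$participant_id)
      few <- names(few)[few < min_after]
      if (length(few))
        warnings <- c(warnings, sprintf(
          "participant %s has fewer than %d trials after accuracy filtering",
          few, min_after))
    }
  }
  rownames(cur) <- NULL
  list(trials = cur,
       report = new_cleaning_report(do.call(rbind, c(rows, make.row.names = FALSE)),
                                    warnings))
}

#' Clean practice-session trials
#'
#' Ordered exclusion cascade for the non-stimulation sessions:
#' (1) remove missed trials (no response); (2) for RT analyses, remove
#' incorrect trials; (3) remove trials with RT above mean + `sd_mult` x SD,
#' the moments computed over the rows remaining at that stage on the
#' configured basis (per participant by default).  Accuracy analyses keep
#' incorrect trials: use `track = "accuracy"` to skip stage 2.  Every
#' stage's row accounting is reported.
#'
#' @param trials Trial data frame with `participant_id`, `congruency`,
#'   `response`, `correct_side`, `rt_s`.
#' @param sd_mult Trial-level outlier multiplier (2.5 by default).
#' @param sd_basis Moment pooling for the RT filter: `"participant"`
#'   (default), `"global"`, or `"participant_condition"`.
#' @param track `"rt"` (full cascade) or `"accuracy"` (missed trials
#'   only).
#' @param cascade Stage order (a permutation of the applicable stages);
#'   row accounting always reflects the order actually applied.
#' @return A list with `trials` (the retained rows) and `report`
#'   (a `"cleaning_report"`).
#' @export
clean_practice <- function(trials, sd_mult = 2.5,
                           sd_basis = c("participant", "global",
                                        "participant_condition"),
                           track = c("rt", "accuracy"),
                           cascade = c("missed", "incorrect", "rt_outlier")) {
  sd_basis <- match.arg(sd_basis)
  track <- match.arg(track)
  if (!nrow(trials)) stop("empty trial table")
  all_stages <- list(missed = stage_missed,
                     incorrect = stage_incorrect,
                     rt_outlier = function(tr) stage_rt_outlier(tr, sd_mult, sd_basis))
  if (track == "accuracy") cascade <- "missed"
  if (!all(cascade %in% names(all_stages)))
    stop("unknown cascade stage(s): ",
         paste(setdiff(cascade, names(all_stages)), collapse = ", "))
  run_cascade(trials, all_stages[cascade], sd_mult, sd_basis)
}

#' Clean TMS-session trials
#'
#' As [clean_practice()], with one additional first stage: trials on which
#' the coil had drifted 3 mm or more from the target (`coil_dev_mm >= 3`,
#' threshold inclusive) are removed before the missed / incorrect /
#' RT-outlier stages.
#'
#' @inheritParams clean_practice
#' @param coil_max_mm Coil-deviation threshold in mm (inclusive).
#' @return A list with `trials` and `report`.
#' @export
clean_tms <- function(trials, coil_max_mm = 3, sd_mult = 2.5,
                      sd_basis = c("participant", "global",
                                   "participant_condition"),
                      track = c("rt", "accuracy"),
                      cascade = c("missed", "incorrect", "rt_outlier")) {
  sd_basis <- match.arg(sd_basis)
  track <- match.arg(track)
  if (!nrow(trials)) stop("empty trial table")
  if (!"coil_dev_mm" %in% names(trials) || all(is.na(trials$coil_dev_mm)))
    stop("'coil_dev_mm' column missing or empty: not a TMS-session table")
  all_stages <- list(
    coil = function(tr) tr$coil_dev_mm < coil_max_mm,
    missed = stage_missed,
    incorrect = stage_incorrect,
    rt_outlier = function(tr) stage_rt_outlier(tr, sd_mult, sd_basis))
  if (track == "accuracy") cascade <- "missed"
  stages <- c("coil", cascade)
  if (!all(stages %in% names(all_stages)))
    stop("unknown cascade stage(s): ",
         paste(setdiff(stages, names(all_stages)), collapse = ", "))
  run_cascade(trials, all_stages[stages], sd_mult, sd_basis)
}

#' Participant exclusion by slow cell means
#'
#' Flags participants whose mean RT exceeds the group mean by more than
#' `sd_mult` group SDs in at least `min_cells` of the six
#' congruency-by-stimulation cells.  Group statistics are computed per
#' cell over all participants, including the candidate (leave-none-out;
#' set `leave_one_out = TRUE` to exclude the candidate from the group
#' moments).
#'
#' @param cell_means Data frame `participant`, `congruency`,
#'   `stimulation`, `mean_rt` (complete: 6 cells per participant), or a
#'   participants-by-cells matrix with participant row names.
#' @param sd_mult Group-SD multiplier (2 by default).
#' @param min_cells Number of offending cells required (4 of 6 by
#'   default).
#' @param leave_one_out Use leave-one-out group moments.
#' @return Character vector of excluded participant ids (possibly empty).
#' @export
exclude_participants_rt <- function(cell_means, sd_mult = 2, min_cells = 4L,
                                    leave_one_out = FALSE) {
  if (is.data.frame(cell_means)) {
    need <- c("participant", "congruency", "stimulation", "mean_rt")
    miss <- setdiff(need, names(cell_means))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    M <- tapply(cell_means$mean_rt,
                list(cell_means$participant,
                     paste(cell_means$congruency, cell_means$stimulation)),
                identity)
  } else M <- as.matrix(cell_means)
  if (anyNA(M)) stop("incomplete cell-mean table")
  if (nrow(M) < 3) stop("need at least 3 participants for group statistics")
  flag <- matrix(FALSE, nrow(M), ncol(M))
  for (j in seq_len(ncol(M))) {
    for (i in seq_len(nrow(M))) {
      ref <- if (leave_one_out) M[-i, j] else M[, j]
      flag[i, j] <- M[i, j] > mean(ref) + sd_mult * stats::sd(ref)
    }
  }
  rownames(M)[rowSums(flag) >= min_cells]
}

#' Participant exclusion by extreme size-congruency effect
#'
#' Flags participants whose SCE strictly exceeds the group mean plus
#' `sd_mult` group SDs (values exactly at the threshold are kept).
#'
#' @param sce Named numeric vector of per-participant SCE values (ms).
#' @param sd_mult Group-SD multiplier (2.5 by default).
#' @param leave_one_out Use leave-one-out group moments.
#' @return Character vector of excluded participant ids.
#' @export
exclude_participants_sce <- function(sce, sd_mult = 2.5,
                                     leave_one_out = FALSE) {
  if (length(sce) < 3) stop("need at least 3 participants for group statistics")
  ids <- names(sce)
  if (is.null(ids)) ids <- as.character(seq_along(sce))
  flagged <- vapply(seq_along(sce), function(i) {
    ref <- if (leave_one_out) sce[-i] else sce
    sce[i] > mean(ref) + sd_mult * stats::sd(ref)
  }, logical(1))
  ids[flagged]
}
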