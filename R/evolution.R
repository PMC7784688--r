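#' @importFrom stats approx sd t.test
#' @importFrom utils head tail
NULL

#' Area under a capsule-loss trajectory
#'
#' Trapezoidal integral of the capsulated-clone fraction over the first
#' `window` days of an evolution experiment — the early phase where most
#' capsule loss takes place. A missing day 0 defaults to a fully capsulated
#' founder (fraction 1); missing interior days are linearly interpolated
#' (with a message). Days beyond the window are ignored.
#'
#' @param days integer vector of observation days (>= 0).
#' @param fractions capsulated fractions in `[0, 1]`, same length.
#' @param window integration window in days (default 5).
#' @return AUC in `[0, window]` (days; a constant fraction f gives
#'   `f * window`).
#' @examples
#' capsuleAuc(0:5, rep(1, 6))                 # 5
#' capsuleAuc(0:5, seq(1, 0, length.out = 6)) # 2.5
#' capsuleAuc(0:5, c(1, 1, 0, 0, 0, 0))       # 1.5
#' @export
capsuleAuc <- function(days, fractions, window = 5) {
  if (length(days) != length(fractions)) stop("days/fractions length mismatch")
  if (anyDuplicated(days)) stop("duplicated days")
  if (any(fractions < 0 | fractions > 1)) stop("fractions out of [0, 1]")
  o <- order(days)
  days <- days[o]; fractions <- fractions[o]
  if (!0 %in% days) {
    days <- c(0, days)
    fractions <- c(1, fractions)  # founders are fully capsulated
  }
  keep <- days <= window
  days <- days[keep]; fractions <- fractions[keep]
  if (length(days) < 2L) stop("fewer than 2 points in the AUC window")
  full <- seq(min(days), max(days))
  if (!all(full %in% days)) {
    message("interior day(s) missing; linearly interpolating")
    fractions <- approx(days, fractions, xout = full)$y
    days <- full
  }
  if (max(days) < window)
    stop(sprintf("trajectory ends at day %d, before the window end %d",
                 max(days), window))
  sum(diff(days) * (head(fractions, -1) + tail(fractions, -1)) / 2)
}

#' Per-population AUCs of a trajectory table
#'
#' @param trajectories data.frame as from [readTrajectories()] or
#'   [generateTrajectories()].
#' @param window integration window in days (default 5).
#' @return data.frame `population_id, strain_id, treatment, auc, window`.
#' @export
capsuleAucTable <- function(trajectories, window = 5) {
  sp <- split(trajectories, trajectories$population_id)
  out <- do.call(rbind, lapply(sp, function(tr) {
    data.frame(population_id = tr$population_id[1L],
               strain_id = tr$strain_id[1L],
               treatment = tr$treatment[1L],
               auc = capsuleAuc(tr$day, tr$capsulated_fraction, window),
               window = window, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare per-population AUCs between two treatments
#'
#' Two-sided Mann-Whitney U test: exact for combined sample size <= 20,
#' normal approximation with continuity and tie correction otherwise. A
#' Welch t test is available behind `parametric = TRUE`.
#'
#' @param aucsA,aucsB numeric vectors of per-population AUCs (>= 3 each).
#' @param parametric use Welch's t test instead (default `FALSE`).
#' @return list with `statistic` (U, or t), `p`.
#' @export
compareTreatmentAucs <- function(aucsA, aucsB, parametric = FALSE) {
  if (length(aucsA) < 3L || length(aucsB) < 3L)
    stop("need at least 3 populations per group")
  if (parametric) {
    tt <- t.test(aucsA, aucsB)
    return(list(statistic = unname(tt$statistic), p = tt$p.value))
  }
  nTot <- length(aucsA) + length(aucsB)
  wt <- suppressWarnings(
    wilcox.test(aucsA, aucsB, exact = nTot <= 20L, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Mean and spread of AUCs per strain x treatment group
#'
#' @param aucTable data.frame from [capsuleAucTable()].
#' @return data.frame `strain_id, treatment, n_populations, mean_auc,
#'   sd_auc` (sd `NA` for single populations).
#' @export
lossRateSummary <- function(aucTable) {
  key <- interaction(aucTable$strain_id, aucTable$treatment, drop = TRUE)
  sp <- split(aucTable, key)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(strain_id = g$strain_id[1L], treatment = g$treatment[1L],
               n_populations = nrow(g), mean_auc = mean(g$auc),
               sd_auc = if (nrow(g) > 1L) sd(g$auc) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$strain_id, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
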