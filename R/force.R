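#' Maximal isometric tetanic torque from a frequency sweep
#'
#' Reduces a stimulation-frequency torque sweep (typically 10-150 Hz) to its
#' maximum, and flags whether the torque-frequency response reached a
#' plateau: the torques at the two highest stimulation frequencies differ by
#' less than `plateau_tol` (relative to the larger of the two).
#'
#' @param sweep Data frame with columns `frequency_hz` and `torque_nmm`
#'   (or a two-column matrix in that order).
#' @param plateau_tol Relative tolerance for the plateau flag (default 0.05).
#' @return List with `max_torque` (Nmm), `at_frequency` (Hz), `plateau`
#'   (logical; FALSE for single-point sweeps).
#' @export
max_tetanic_torque <- function(sweep, plateau_tol = 0.05) {
  sweep <- as.data.frame(sweep)
  if (ncol(sweep) == 2 && !all(c("frequency_hz", "torque_nmm") %in% names(sweep)))
    names(sweep) <- c("frequency_hz", "torque_nmm")
  if (nrow(sweep) == 0)
    rg_stop("empty torque sweep", "ratgait_error_empty")
  if (any(sweep$torque_nmm < 0))
    rg_stop("torques must be nonnegative", "ratgait_error_contract")
  ord <- order(sweep$frequency_hz)
  f <- sweep$frequency_hz[ord]
  tq <- sweep$torque_nmm[ord]
  k <- which.max(tq)
  plateau <- FALSE
  if (length(tq) >= 2) {
    top2 <- tq[(length(tq) - 1):length(tq)]
    plateau <- abs(diff(top2)) / max(top2) < plateau_tol
  }
  list(max_torque = tq[k], at_frequency = f[k], plateau = plateau)
}

#' Body-weight-normalized torque
#'
#' @param torque Torque, Nmm.
#' @param body_weight Body weight, kg (> 0).
#' @return Torque per body weight, Nmm/kg.
#' @export
normalize_torque <- function(torque, body_weight) {
  if (any(!is.finite(body_weight)) || any(body_weight <= 0))
    rg_stop("body weight must be positive", "ratgait_error_contract")
  torque / body_weight
}

#' Torque as percent of an animal's own baseline
#'
#' @param post_norm Post-surgical normalized torque, Nmm/kg.
#' @param baseline_norm Baseline normalized torque of the same animal,
#'   Nmm/kg (> 0).
#' @return `100 * post_norm / baseline_norm`, percent.
#' @export
percent_baseline <- function(post_norm, baseline_norm) {
  if (any(!is.finite(baseline_norm)) || any(baseline_norm <= 0))
    rg_stop("baseline torque must be positive", "ratgait_error_contract")
  100 * post_norm / baseline_norm
}

#' Reduce a long-format torque study table
#'
#' Takes per-animal stimulation sweeps at several timepoints (long format:
#' one row per animal x timepoint x frequency) and produces per-animal
#' maxima, body-weight-normalized torques, and percent-of-baseline values,
#' plus group summaries per timepoint. Percentages are computed per animal
#' against that animal's own baseline and then averaged within the group
#' (the primary summary); the ratio of group mean torques is also reported
#' since the two generally differ.
#'
#' @param torque_table Data frame with columns `animal`, `timepoint`,
#'   `body_weight_kg`, `frequency_hz`, `torque_nmm`.
#' @param baseline_timepoint Value of `timepoint` that is the baseline
#'   (default the smallest, conventionally -1 weeks).
#' @return List with `per_animal` (animal, timepoint, max_torque_nmm,
#'   norm_torque_nmm_per_kg, pct_baseline, plateau) and `group_summary`
#'   (timepoint, mean/sd of normalized torque, mean/sd of per-animal percent
#'   of baseline, ratio-of-means percent, n).
#' @export
torque_summary <- function(torque_table, baseline_timepoint = NULL) {
  need <- c("animal", "timepoint", "body_weight_kg", "frequency_hz", "torque_nmm")
  if (!all(need %in% names(torque_table)))
    rg_stop(paste0("torque table must have columns: ",
                   paste(need, collapse = ", ")), "ratgait_error_contract")
  if (nrow(torque_table) == 0)
    rg_stop("empty torque table", "ratgait_error_empty")
  if (is.null(baseline_timepoint))
    baseline_timepoint <- min(torque_table$timepoint)
  keys <- unique(torque_table[, c("animal", "timepoint")])
  per <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- torque_table[torque_table$animal == keys$animal[i] &
                          torque_table$timepoint == keys$timepoint[i], ]
    mx <- max_tetanic_torque(sub[, c("frequency_hz", "torque_nmm")])
    bw <- sub$body_weight_kg[1]
    data.frame(animal = keys$animal[i], timepoint = keys$timepoint[i],
               max_torque_nmm = mx$max_torque,
               norm_torque_nmm_per_kg = normalize_torque(mx$max_torque, bw),
               plateau = mx$plateau)
  }))
  base <- per[per$timepoint == baseline_timepoint,
              c("animal", "norm_torque_nmm_per_kg")]
  names(base)[2] <- "baseline_norm"
  per <- merge(per, base, by = "animal", all.x = TRUE, sort = FALSE)
  per$pct_baseline <- percent_baseline(per$norm_torque_nmm_per_kg,
                                       per$baseline_norm)
  per <- per[order(per$timepoint, per$animal), ]
  tps <- sort(unique(per$timepoint))
  grp <- do.call(rbind, lapply(tps, function(tp) {
    sub <- per[per$timepoint == tp, ]
    data.frame(timepoint = tp, n = nrow(sub),
               mean_norm = mean(sub$norm_torque_nmm_per_kg),
               sd_norm = stats::sd(sub$norm_torque_nmm_per_kg),
               mean_pct_baseline = mean(sub$pct_baseline),
               sd_pct_baseline = stats::sd(sub$pct_baseline),
               pct_of_mean_baseline = 100 * mean(sub$norm_torque_nmm_per_kg) /
                 mean(per$norm_torque_nmm_per_kg[per$timepoint == baseline_timepoint]))
  }))
  list(per_animal = per[, c("animal", "timepoint", "max_torque_nmm",
                            "norm_torque_nmm_per_kg", "pct_baseline",
                            "plateau")],
       group_summary = grp, baseline_timepoint = baseline_timepoint)
}

#' Simulate a synthetic isometric torque study
#'
#' Generates per-animal torque-frequency sweeps (sigmoid recruitment curve
#' plateauing over 10-150 Hz) for a longitudinal design with a baseline and
#' post-injury timepoints. This is a synthetic stand-in for servomotor
#' recordings, calibrated so that the group summaries land near a baseline
#' of ~114 Nmm/kg and post-injury deficits of ~72/76/79% of baseline with
#' the printed between-animal spreads of a typical 20%-mass tibialis
#' anterior VML study.
#'
#' @param n_animals Number of animals (default 4).
#' @param timepoints Timepoints in weeks (default `c(-1, 2, 4, 8)`; the
#'   first is baseline).
#' @param baseline_mean,baseline_sd Baseline normalized torque mean and
#'   between-animal sd, Nmm/kg (defaults 113.90 and 5.34).
#' @param deficit_mean Mean post-injury torque as a fraction of baseline,
#'   one per non-baseline timepoint (default `c(0.7151, 0.7648, 0.7874)`).
#' @param deficit_sd Between-animal sd of those fractions (default
#'   `c(0.0559, 0.0590, 0.0485)`).
#' @param body_weight_mean,body_weight_sd Body weight, kg (defaults 0.1802
#'   and 0.00675).
#' @param frequencies Stimulation frequencies, Hz.
#' @param seed Random seed.
#' @return Long-format data frame suitable for [torque_summary()].
#' @export
simulate_torque_study <- function(n_animals = 4,
                                  timepoints = c(-1, 2, 4, 8),
                                  baseline_mean = 113.90, baseline_sd = 5.34,
                                  deficit_mean = c(0.7151, 0.7648, 0.7874),
                                  deficit_sd = c(0.0559, 0.0590, 0.0485),
                                  body_weight_mean = 0.1802,
                                  body_weight_sd = 0.00675,
                                  frequencies = c(10, 20, 40, 60, 80, 100, 125, 150),
                                  seed = 1L) {
  if (length(deficit_mean) != length(timepoints) - 1 ||
      length(deficit_sd) != length(timepoints) - 1)
    rg_stop("one deficit mean/sd per non-baseline timepoint required",
            "ratgait_error_contract")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rows <- list()
  for (a in seq_len(n_animals)) {
    id <- sprintf("rat%02d", a)
    base_norm <- stats::rnorm(1, baseline_mean, baseline_sd)
    for (k in seq_along(timepoints)) {
      tp <- timepoints[k]
      frac <- if (k == 1) 1 else
        max(0.05, stats::rnorm(1, deficit_mean[k - 1], deficit_sd[k - 1]))
      bw <- max(0.05, stats::rnorm(1, body_weight_mean, body_weight_sd))
      tmax <- base_norm * frac * bw
      # sigmoid recruitment: half-maximal near 45 Hz, fused by ~100 Hz
      tq <- tmax / (1 + exp(-(frequencies - 45) / 12))
      rows[[length(rows) + 1L]] <- data.frame(
        animal = id, timepoint = tp, body_weight_kg = bw,
        frequency_hz = frequencies, torque_nmm = tq)
    }
  }
  do.call(rbind, rows)
}
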