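#' Spatiotemporal gait parameters
#'
#' Stride time, cadence and swing percentage from an event list. Stride time
#' is the mean heel-strike-to-heel-strike interval over complete cycles;
#' cadence is expressed per stride, `60 / stride_time` (the treadmill study
#' values this package targets, e.g. 172 "spm" at 0.352 s stride time, are
#' consistent with strides per minute); swing percentage is the mean of
#' `100 * (hs_next - to) / (hs_next - hs)` over cycles.
#'
#' @param events A [gait_events()] object with at least one complete cycle.
#' @return Object of class `spatiotemporal_params`: `stride_time` (s),
#'   `cadence` (strides/min), `swing_pct` (%), `n_cycles`.
#' @export
spatiotemporal <- function(events) {
  cyc <- segment_cycles(events)
  if (length(cyc) < 1)
    rg_stop("no complete gait cycle in events", "ratgait_error_insufficient_data")
  stride <- vapply(cyc, function(c) c[[3]] - c[[1]], 0)
  swing <- vapply(cyc, function(c) 100 * (c[[3]] - c[[2]]) / (c[[3]] - c[[1]]), 0)
  st <- mean(stride)
  structure(list(stride_time = st, cadence = 60 / st,
                 swing_pct = mean(swing), n_cycles = length(cyc)),
            class = "spatiotemporal_params")
}

#' @export
print.spatiotemporal_params <- function(x, ...) {
  cat(sprintf("Spatiotemporal (n=%d cycles): stride %.3f s, cadence %.2f spm, swing %.2f%%\n",
              x$n_cycles, x$stride_time, x$cadence, x$swing_pct))
  invisible(x)
}

#' Range of motion of a gait-cycle curve
#'
#' @param curve Numeric vector of finite joint-angle samples (deg),
#'   conventionally the 101-node cycle curve.
#' @return `max - min`, degrees.
#' @export
range_of_motion <- function(curve) {
  if (any(!is.finite(curve)))
    rg_stop("curve contains non-finite samples", "ratgait_error_contract")
  max(curve) - min(curve)
}

#' Aggregate gait cycles into a per-animal kinematic summary
#'
#' Pointwise mean of the normalized angle curves over cycles. The primary
#' range of motion is the mean of per-cycle ROMs (an "average range of
#' motion"); the ROM of the mean curve is also reported for comparison
#' (it is systematically smaller whenever cycles are imperfectly aligned).
#' Fewer than 3 cycles sets `below_minimum` (three steps per animal being
#' the usual minimum for stable averages).
#'
#' @param cycles List of `gait_cycle` objects from [cut_cycles()].
#' @param rat_id Optional animal identifier carried into the summary.
#' @return Object of class `kinematic_summary`: `mean_curves` (101 x angles),
#'   `rom` (mean per-cycle ROM), `rom_mean_curve`, `stance_fraction` (mean),
#'   `n_cycles`, `below_minimum`, `rat_id`.
#' @export
aggregate_cycles <- function(cycles, rat_id = NA_character_) {
  if (length(cycles) < 1)
    rg_stop("no cycles to aggregate", "ratgait_error_insufficient_data")
  angles <- colnames(cycles[[1]]$curves)
  arr <- vapply(cycles, function(c) c$curves,
                matrix(0, 101, length(angles)))
  mean_curves <- apply(arr, c(1, 2), mean)
  colnames(mean_curves) <- angles
  per_cycle_rom <- vapply(cycles, function(c)
    apply(c$curves, 2, range_of_motion), numeric(length(angles)))
  if (!is.matrix(per_cycle_rom))
    per_cycle_rom <- matrix(per_cycle_rom, nrow = length(angles))
  rom <- rowMeans(per_cycle_rom)
  names(rom) <- angles
  structure(list(mean_curves = mean_curves, rom = rom,
                 rom_mean_curve = apply(mean_curves, 2, range_of_motion),
                 stance_fraction = mean(vapply(cycles, `[[`, 0, "stance_fraction")),
                 n_cycles = length(cycles),
                 below_minimum = length(cycles) < 3, rat_id = rat_id),
            class = "kinematic_summary")
}

#' @export
print.kinematic_summary <- function(x, ...) {
  cat(sprintf("Kinematic summary%s: %d cycle(s)%s\n",
              if (is.na(x$rat_id)) "" else paste0(" [", x$rat_id, "]"),
              x$n_cycles,
              if (x$below_minimum) " (below the 3-cycle minimum)" else ""))
  print(round(x$rom, 2))
  invisible(x)
}

#' Circular phase shift between two gait-cycle curves
#'
#' Treats each 101-node curve as periodic (dropping the duplicated 100%
#' node) and returns the integer lag, in percent of the gait cycle, that
#' maximizes the Pearson correlation between the reference and the test
#' curve shifted back by that lag. Positive values mean the test curve is
#' delayed relative to the reference. Ties are broken toward the smallest
#' absolute lag (and toward the positive lag between exact opposites).
#'
#' @param reference,test Numeric vectors of 101 samples.
#' @return Integer lag in `[-50, 50]`, percent of cycle.
#' @export
#' @examples
#' s <- sin(2 * pi * (0:100) / 100)
#' phase_shift(s, c(s[97:100], s[1:97]))  # test delayed by ~4%
phase_shift <- function(reference, test) {
  if (length(reference) != 101 || length(test) != 101)
    rg_stop("curves must have 101 samples", "ratgait_error_contract")
  r <- reference[1:100]
  t_ <- test[1:100]
  if (stats::sd(r) == 0 || stats::sd(t_) == 0)
    rg_stop("zero-variance curve: phase shift undefined",
            "ratgait_error_degenerate_variance")
  lags <- 0:99
  cors <- vapply(lags, function(k) {
    shifted <- t_[((lags + k) %% 100) + 1]
    stats::cor(r, shifted)
  }, 0)
  signed <- ifelse(lags > 50, lags - 100L, lags)
  ord <- order(-cors, abs(signed), -sign(signed))
  as.integer(signed[ord[1]])
}
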