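# Moving-average smoother with edge padding (window must be odd).
smooth_ma <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2))[
    (half + 1):(half + length(x))]
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' the standard pre-smoothing for marker-derived joint angles. Rat treadmill
#' strides run at roughly 3 Hz, so a 15 Hz cutoff at 120 Hz passes the first
#' 4-5 stride harmonics essentially untouched while suppressing
#' frame-to-frame marker noise; the 6 Hz cutoff customary in human gait would
#' sit on top of the rat's 2nd harmonic and visibly shrink joint excursions.
#'
#' @param x Numeric series (NA-free).
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (default 15).
#' @param order Filter order (default 4).
#' @return Filtered series, same length.
#' @export
lowpass_filter <- function(x, rate, cutoff = 15, order = 4) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect heel-strike and toe-off events on a treadmill
#'
#' Stance is identified from the TOE marker: the foot is in contact while the
#' belt carries it backward at the belt speed and the toe stays low. A coarse
#' stance mask marks frames where the smoothed anterior toe velocity is
#' within `velocity_tol * belt_speed` of `-belt_speed` AND the smoothed toe
#' height is below the 25th height percentile plus `height_offset` mm;
#' sub-threshold gaps shorter than `min_duration` are closed and runs shorter
#' than `min_duration` discarded. Because smoothing and central differencing
#' smear the sharp velocity corner at foot contact, each stance edge is then
#' refined: the belt line `x(t) = a - belt_speed * t` is fitted robustly to
#' the interior of the run, and the edge is moved to the outermost frame
#' whose raw trajectory still lies on that line (within a noise-scaled
#' deviation threshold) with the toe below the height threshold. Heel strike
#' (HS) is a stance onset, toe off (TO) a stance offset; transitions at the
#' data boundary are not emitted.
#'
#' The ANKLE marker can be used as a fallback (`marker = "ANKLE"`) since the
#' rodent marker set carries no heel marker.
#'
#' @param trajectories A [marker_trajectories()] object (rate >= 50 Hz).
#' @param belt_speed Treadmill belt speed, cm/s.
#' @param marker Marker used for detection, `"TOE"` (default) or `"ANKLE"`.
#' @param velocity_tol Velocity tolerance as a fraction of belt speed
#'   (default 0.3).
#' @param height_offset Height threshold above the 25th percentile of marker
#'   height, mm (default 2).
#' @param min_duration Minimum stance/swing duration, s (default 0.05).
#' @param smooth_window Moving-average window (frames) applied to the marker
#'   position before differentiation (default 5).
#' @return Object of class `gait_events`: data frame `events` with columns
#'   `time`, `type` (alternating `"HS"`/`"TO"`), plus the detector
#'   parameters. Emits an `empty-events` warning when no alternating events
#'   are found.
#' @export
detect_events <- function(trajectories, belt_speed, marker = "TOE",
                          velocity_tol = 0.3, height_offset = 2,
                          min_duration = 0.05, smooth_window = 5L) {
  x <- trajectories
  if (!marker %in% x$marker_names)
    rg_stop(paste0("marker not present: ", marker),
            "ratgait_error_missing_marker")
  if (x$rate < 50)
    rg_stop("event detection requires a sampling rate of at least 50 Hz",
            "ratgait_error_contract")
  px <- smooth_ma(x$positions[, marker, 1], smooth_window)
  py <- smooth_ma(x$positions[, marker, 2], smooth_window)
  n <- length(px)
  v <- c(NA, (px[3:n] - px[1:(n - 2)]) * x$rate / 2, NA)
  v[1] <- (px[2] - px[1]) * x$rate
  v[n] <- (px[n] - px[n - 1]) * x$rate
  belt_mm <- belt_speed * 10  # cm/s -> mm/s
  height_thr <- stats::quantile(py, 0.25, na.rm = TRUE, names = FALSE) +
    height_offset
  stance <- abs(v + belt_mm) <= velocity_tol * belt_mm & py <= height_thr
  stance[is.na(stance)] <- FALSE
  min_frames <- max(1L, round(min_duration * x$rate))
  stance <- close_runs(stance, min_frames)
  stance <- refine_stance_edges(stance, x$positions[, marker, 1],
                                x$positions[, marker, 2], x$time, belt_mm,
                                height_thr)
  runs <- rle(stance)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev_time <- numeric(0)
  ev_type <- character(0)
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    if (starts[k] > 1L) {
      ev_time <- c(ev_time, x$time[starts[k]]); ev_type <- c(ev_type, "HS")
    }
    if (ends[k] < n) {
      ev_time <- c(ev_time, x$time[ends[k]]); ev_type <- c(ev_type, "TO")
    }
  }
  if (length(ev_time) < 2)
    rg_warn("no alternating gait events found", "ratgait_warning_empty_events")
  gait_events(ev_time, ev_type, belt_speed = belt_speed,
              params = list(marker = marker, velocity_tol = velocity_tol,
                            height_offset = height_offset,
                            min_duration = min_duration,
                            smooth_window = smooth_window))
}

# Edge refinement: the coarse mask is biased inward by the smoothing /
# central-difference smear at the contact corner. For each run, fit the belt
# line x(t) = a - belt * t to the run interior (median intercept, MAD noise
# scale) and move each edge outward (or inward) to the outermost contiguous
# frame whose raw x deviates from the line by at most max(2 mm, 4 * MAD) and
# whose raw height stays below the threshold. The deviation of the swinging
# toe from the belt line grows quadratically away from true contact, so the
# refined edges localize heel strike and toe off to about a frame.
refine_stance_edges <- function(stance, x_raw, y_raw, time, belt_mm,
                                height_thr, search = 10L, trim = 3L) {
  if (!any(stance)) return(stance)
  n <- length(stance)
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- logical(n)
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    core <- if (i1 - i0 + 1L > 2L * trim + 2L) (i0 + trim):(i1 - trim)
            else i0:i1
    a <- stats::median(x_raw[core] + belt_mm * time[core])
    dev_all <- abs(x_raw - (a - belt_mm * time))
    sig <- stats::mad(dev_all[core])
    thr <- max(2, 4 * sig)
    on_line <- dev_all <= thr & y_raw <= height_thr
    # outermost contiguous on-line frame around the run, bounded search
    lo <- i0
    while (lo > 1L && lo > i0 - search && on_line[lo - 1L]) lo <- lo - 1L
    while (lo < i1 && !on_line[lo]) lo <- lo + 1L
    hi <- i1
    while (hi < n && hi < i1 + search && on_line[hi + 1L]) hi <- hi + 1L
    while (hi > lo && !on_line[hi]) hi <- hi - 1L
    out[lo:hi] <- TRUE
  }
  out
}

# Close sub-minimum FALSE gaps between stance runs, then drop sub-minimum
# stance runs (morphological closing then opening on the binary signal).
close_runs <- function(b, min_frames) {
  r <- rle(b)
  n <- length(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && r$lengths[k] < min_frames &&
        k > 1 && k < length(r$values))
      b[starts[k]:ends[k]] <- TRUE
  }
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] < min_frames)
      b[starts[k]:ends[k]] <- FALSE
  }
  b
}

#' Construct a gait event list
#'
#' @param time Event times, s (strictly increasing).
#' @param type Event types, `"HS"` or `"TO"`, strictly alternating.
#' @param belt_speed Belt speed used for detection, cm/s.
#' @param params Detector parameters (list), recorded for provenance.
#' @return Object of class `gait_events`.
#' @export
gait_events <- function(time, type, belt_speed = NA_real_, params = list()) {
  if (length(time) != length(type))
    rg_stop("time and type must have equal length", "ratgait_error_contract")
  if (length(time) > 1) {
    if (any(diff(time) <= 0))
      rg_stop("event times must be strictly increasing", "ratgait_error_contract")
    if (any(type[-1] == type[-length(type)]))
      rg_stop("event types must alternate HS, TO, HS, ...", "ratgait_error_contract")
  }
  structure(list(events = data.frame(time = as.numeric(time),
                                     type = as.character(type)),
                 belt_speed = belt_speed, params = params),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  nhs <- sum(x$events$type == "HS")
  cat(sprintf("Gait events: %d HS, %d TO (%d complete cycles)\n",
              nhs, sum(x$events$type == "TO"), length(segment_cycles(x))))
  invisible(x)
}

#' Cut an event list into right-leg gait cycles
#'
#' A complete cycle is a heel-strike-to-heel-strike stride containing its
#' toe-off: the triplet (HS_i, TO_i, HS_(i+1)). Incomplete leading/trailing
#' fragments are dropped.
#'
#' @param events A [gait_events()] object.
#' @return List of numeric triplets `c(hs, to, hs_next)` (times in s).
#' @export
segment_cycles <- function(events) {
  ev <- events$events
  out <- list()
  i <- 1L
  while (i + 2L <= nrow(ev) + 0L) {
    if (i + 2L > nrow(ev)) break
    if (ev$type[i] == "HS" && ev$type[i + 1] == "TO" && ev$type[i + 2] == "HS") {
      out[[length(out) + 1L]] <- c(hs = ev$time[i], to = ev$time[i + 1],
                                   hs_next = ev$time[i + 2])
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Normalize a time series onto the 0-100% gait cycle
#'
#' Cubic-spline interpolation of an angle (or any) series onto 101 equally
#' spaced points from heel strike to the next heel strike; the endpoints
#' reproduce the series values at the two heel strikes to interpolation
#' tolerance. 101 nodes (0, 1, ..., 100% inclusive) is the standard gait
#' continuum length.
#'
#' @param time Sample times of the series, s.
#' @param values Series values at `time`.
#' @param cycle Numeric triplet `c(hs, to, hs_next)` from [segment_cycles()].
#' @return List with `curve` (101 values) and `stance_fraction`
#'   `(to - hs) / (hs_next - hs)`.
#' @export
normalize_cycle <- function(time, values, cycle) {
  hs <- cycle[[1]]; to <- cycle[[2]]; hs2 <- cycle[[3]]
  eps <- 1e-9
  if (min(time) > hs + eps || max(time) < hs2 - eps)
    rg_stop("series does not cover the gait cycle", "ratgait_error_coverage")
  ok <- is.finite(values)
  fun <- stats::splinefun(time[ok], values[ok], method = "fmm")
  curve <- fun(seq(hs, hs2, length.out = 101))
  list(curve = curve, stance_fraction = (to - hs) / (hs2 - hs))
}

#' Cut joint-angle trajectories into normalized gait cycles
#'
#' Applies [normalize_cycle()] to the five reported joint angles (hip
#' flexion, hip adduction, hip rotation, knee flexion, ankle flexion) of an
#' IK result for every complete cycle in an event list, optionally low-pass
#' filtering the angle series first.
#'
#' @param ik An `ik_result` (or data frame with `time` and angle columns).
#' @param events A [gait_events()] object.
#' @param angles Angle columns to extract (default the five reported angles).
#' @param lowpass Apply [lowpass_filter()] to each angle series before
#'   resampling (default FALSE).
#' @param cutoff Low-pass cutoff, Hz.
#' @return List of `gait_cycle` objects, each with `curves` (101 x angles
#'   matrix), `start`, `end`, `stance_fraction`.
#' @export
cut_cycles <- function(ik, events, angles = RG_ANGLES, lowpass = FALSE,
                       cutoff = 15) {
  df <- if (inherits(ik, "ik_result")) as.data.frame(ik) else ik
  rate <- if (inherits(ik, "ik_result")) ik$rate else
    1 / stats::median(diff(df$time))
  series <- df[, angles, drop = FALSE]
  if (lowpass)
    series[] <- lapply(series, lowpass_filter, rate = rate, cutoff = cutoff)
  lapply(segment_cycles(events), function(cy) {
    res <- lapply(angles, function(a) normalize_cycle(df$time, series[[a]], cy))
    curves <- do.call(cbind, lapply(res, `[[`, "curve"))
    colnames(curves) <- angles
    structure(list(curves = curves, start = cy[[1]], end = cy[[3]],
                   stance_fraction = res[[1]]$stance_fraction),
              class = "gait_cycle")
  })
}

#' Write detected events to CSV
#'
#' @param events A [gait_events()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events$events, path, row.names = FALSE)
  invisible(path)
}
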