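#' Construct a marker trajectory set
#'
#' In-memory container for time-stamped 3-D marker positions at a fixed
#' sampling rate. Missing samples are stored as `NA` (all three coordinates).
#'
#' @param positions Numeric array, frames x markers x 3 (mm), with marker
#'   names as the second dimnames.
#' @param rate Sampling rate, Hz.
#' @param time Optional time vector, seconds; defaults to
#'   `(0:(n-1)) / rate`.
#' @return Object of class `marker_trajectories` with fields `rate`, `time`,
#'   `marker_names`, `positions`.
#' @export
marker_trajectories <- function(positions, rate, time = NULL) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3)
    rg_stop("positions must be a frames x markers x 3 array", "ratgait_error_contract")
  if (!is.finite(rate) || rate <= 0)
    rg_stop("rate must be > 0", "ratgait_error_contract")
  n <- dim(positions)[1]
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  if (length(time) != n)
    rg_stop("time length must equal the number of frames", "ratgait_error_contract")
  if (n > 1 && any(abs(diff(time) - 1 / rate) > 1e-6))
    rg_stop("time must increase in steps of 1/rate", "ratgait_error_contract")
  nm <- dimnames(positions)[[2]]
  if (is.null(nm))
    rg_stop("positions must carry marker names", "ratgait_error_contract")
  structure(list(rate = rate, time = time, marker_names = nm,
                 positions = positions),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("Marker trajectories: %d frames x %d markers at %g Hz (%.3f s)\n",
              length(x$time), length(x$marker_names), x$rate,
              diff(range(x$time))))
  cat("  markers:", paste(x$marker_names, collapse = ", "), "\n")
  miss <- apply(is.na(x$positions[, , 1, drop = FALSE]), 2, mean)
  if (any(miss > 0))
    cat(sprintf("  missing samples: %s\n",
                paste(sprintf("%s %.1f%%", x$marker_names[miss > 0],
                              100 * miss[miss > 0]), collapse = ", ")))
  invisible(x)
}

#' @export
`[.marker_trajectories` <- function(x, i) {
  marker_trajectories(x$positions[i, , , drop = FALSE], x$rate,
                      time = x$time[i])
}

#' Read a TRC marker trajectory file
#'
#' Parses the tab-delimited TRC dialect emitted by mainstream motion-capture
#' tools: a `PathFileType` line, a header key row
#' (`DataRate ... OrigNumFrames`) with its value row, a marker-name row, an
#' X/Y/Z label row, then one row per frame beginning with `Frame#` and
#' `Time`. Coordinates are converted to mm (`Units` may be mm, cm or m);
#' blank coordinate cells become missing samples.
#'
#' @param path File path.
#' @return A [marker_trajectories()] object.
#' @export
read_trc <- function(path) {
  if (!file.exists(path))
    rg_stop(paste0("file not found: ", path), "ratgait_error_io")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || !grepl("^PathFileType", lines[1]))
    rg_stop("not a TRC file: missing PathFileType header", "ratgait_error_format")
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- as.list(vals)
  names(hdr) <- keys[seq_along(vals)]
  rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- hdr[["Units"]]
  unit_factor <- switch(units, mm = 1, cm = 10, m = 1000,
                        rg_stop(paste0("unknown Units in TRC header: ", units),
                                "ratgait_error_units"))
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) != n_markers)
    rg_stop(sprintf("line 4: %d marker names but NumMarkers=%d",
                    length(marker_names), n_markers), "ratgait_error_format")
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  if (length(data_lines) != n_frames)
    rg_stop(sprintf("line %d onward: %d data rows but NumFrames=%d",
                    6L, length(data_lines), n_frames), "ratgait_error_format")
  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  ncol_expect <- 2 + 3 * n_markers
  pos <- array(NA_real_, c(n_frames, n_markers, 3),
               dimnames = list(NULL, marker_names, c("x", "y", "z")))
  time <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    row <- cells[[f]]
    if (length(row) < 2 || length(row) > ncol_expect)
      rg_stop(sprintf("line %d: expected up to %d columns, found %d",
                      f + 5L, ncol_expect, length(row)), "ratgait_error_format")
    length(row) <- ncol_expect  # right-pad short rows (trailing blanks)
    time[f] <- as.numeric(row[2])
    xyz <- suppressWarnings(as.numeric(row[-(1:2)]))
    pos[f, , ] <- matrix(xyz, n_markers, 3, byrow = TRUE)
  }
  # a sample is missing iff any of its three coordinates is absent
  incomplete <- apply(is.na(pos), c(1, 2), any)
  for (k in 1:3) pos[, , k][incomplete] <- NA_real_
  marker_trajectories(pos * unit_factor, rate = rate, time = time)
}

#' Write a TRC marker trajectory file
#'
#' Emits the tab-delimited TRC dialect of [read_trc()], in mm, with 6 decimal
#' places and missing samples as empty cells. The file round-trips through
#' `read_trc` at the written precision.
#'
#' @param trajectories A [marker_trajectories()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(trajectories, path) {
  x <- trajectories
  n <- length(x$time)
  nm <- length(x$marker_names)
  if (n < 1 || nm < 1)
    rg_stop("cannot write a TRC file with zero frames or zero markers",
            "ratgait_error_empty")
  name_row <- c("Frame#", "Time",
                as.vector(rbind(x$marker_names, "", "")))
  xyz_row <- c("", "", as.vector(vapply(seq_len(nm), function(i)
    paste0(c("X", "Y", "Z"), i), character(3))))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  flat <- matrix(aperm(x$positions, c(3, 2, 1)), nrow = 3 * nm)  # (3*nm) x frames
  body <- vapply(seq_len(n), function(f)
    paste(c(sprintf("%d", f), sprintf("%.8f", x$time[f]), fmt(flat[, f])),
          collapse = "\t"), "")
  lines <- c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
            "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
          collapse = "\t"),
    paste(c(sprintf("%.6f", x$rate), sprintf("%.6f", x$rate),
            sprintf("%d", n), sprintf("%d", nm), "mm",
            sprintf("%.6f", x$rate), "1", sprintf("%d", n)),
          collapse = "\t"),
    paste(name_row, collapse = "\t"),
    paste(xyz_row, collapse = "\t"),
    body
  )
  writeLines(lines, path)
  invisible(path)
}

#' Validate the rodent 8-marker set
#'
#' Checks a trajectory set against the canonical marker set (SPINE, TAIL,
#' LASI, RASI, HIP, KNEE, ANKLE, TOE). Extra markers are tolerated with a
#' warning entry; the check passes iff all 8 canonical markers are present.
#'
#' @param trajectories A [marker_trajectories()] object.
#' @return List with `pass`, `missing`, `extra` and per-marker
#'   `missing_fraction` of samples.
#' @export
validate_marker_set <- function(trajectories) {
  nm <- trajectories$marker_names
  missing <- setdiff(RG_MARKERS, nm)
  extra <- setdiff(nm, RG_MARKERS)
  mf <- apply(is.na(trajectories$positions[, , 1, drop = FALSE]), 2, mean)
  names(mf) <- nm
  list(pass = length(missing) == 0, missing = missing, extra = extra,
       missing_fraction = mf)
}
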