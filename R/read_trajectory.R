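#' Read a tracked-trajectory table into a group recording
#'
#' Parses the tabular exports of video-tracking software into a
#' [group_recording()]. Two dialects are understood:
#'
#' * `"generic-csv"`: comma-separated with header columns
#'   `frame, time_s, fish_id, x_px, y_px`.
#' * `"toxtrac"`: tab-separated real-space export with header columns
#'   `Frame, Time, Arena, Track, X, Y` (`Track` is the fish id; `X`, `Y` are
#'   pixel coordinates).
#'
#' Every fish is aligned to the common frame grid spanning the minimum to the
#' maximum frame index seen in the file. Frames where a fish has no detection
#' are gaps: runs of at most `max_gap_frames` missing frames with detections
#' on both sides are filled by linear interpolation; longer gaps (and gaps
#' touching the start or end of the recording) are left marked missing and
#' are excluded from all time-summed endpoints downstream. The fraction of
#' grid frames detected is recorded per fish *before* interpolation as
#' `detection_fraction`.
#'
#' @param path Path to the trajectory table.
#' @param dialect `"generic-csv"` or `"toxtrac"`.
#' @param calibration A [calibration_info()] object.
#' @param site,tank_id Metadata labels attached to the recording.
#' @param max_gap_frames Longest run of missing frames that is interpolated
#'   (default 5).
#' @param sample_duration_s Nominal sample duration; defaults to the grid span
#'   plus one frame period.
#'
#' @return A [group_recording()].
#' @export
read_trajectory_table <- function(path, dialect = c("generic-csv", "toxtrac"),
                                  calibration, site = "unknown",
                                  tank_id = "unknown", max_gap_frames = 5,
                                  sample_duration_s = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("read_trajectory_table: file not found: ", path, call. = FALSE)
  }
  stopifnot(inherits(calibration, "calibration_info"))

  sep <- if (dialect == "generic-csv") "," else "\t"
  raw <- read.table(path, header = TRUE, sep = sep, colClasses = "character",
                    strip.white = TRUE, comment.char = "")
  cols <- switch(dialect,
    "generic-csv" = c(frame = "frame", time = "time_s", id = "fish_id",
                      x = "x_px", y = "y_px"),
    "toxtrac" = c(frame = "Frame", time = "Time", id = "Track",
                  x = "X", y = "Y"))
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("read_trajectory_table: missing column(s) ",
         paste(missing_cols, collapse = ", "), " for dialect ", dialect,
         call. = FALSE)
  }

  num <- function(col_key) {
    v <- raw[[cols[[col_key]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !(v %in% c("NA", "", "NaN")))
    if (length(bad)) {
      # +1 for the header row: report the line number in the file
      stop(sprintf(
        "read_trajectory_table: non-numeric value '%s' in column '%s' on line %d",
        v[bad[1L]], cols[[col_key]], bad[1L] + 1L), call. = FALSE)
    }
    out
  }
  frame <- num("frame")
  time_s <- num("time")
  x_px <- num("x")
  y_px <- num("y")
  fish_id <- raw[[cols[["id"]]]]
  if (any(is.na(frame))) {
    stop("read_trajectory_table: missing frame index", call. = FALSE)
  }

  grid <- seq(min(frame), max(frame))
  n_grid <- length(grid)
  # frame -> time mapping must be consistent across fish
  t_of_frame <- rep(NA_real_, n_grid)
  idx <- match(frame, grid)
  t_of_frame[idx] <- time_s
  conflict <- tapply(time_s, idx, function(v) diff(range(v)) > 1e-6)
  if (any(unlist(conflict), na.rm = TRUE)) {
    stop("read_trajectory_table: inconsistent frame/time grids across fish",
         call. = FALSE)
  }
  # fill times for frames nobody was detected on from the median frame period
  if (anyNA(t_of_frame)) {
    dt <- median(diff(t_of_frame), na.rm = TRUE)
    if (!is.finite(dt)) dt <- 1 / calibration$frame_rate
    known <- which(!is.na(t_of_frame))
    t_of_frame <- t_of_frame[known[1L]] + (grid - grid[known[1L]]) *
      (if (length(known) > 1L)
         (t_of_frame[known[length(known)]] - t_of_frame[known[1L]]) /
           (grid[known[length(known)]] - grid[known[1L]]) else dt)
  }

  trajectories <- lapply(split(seq_along(frame), fish_id), function(rows) {
    if (length(unique(frame[rows])) < 2L) {
      stop("read_trajectory_table: fewer than 2 frames for fish ",
           fish_id[rows[1L]], call. = FALSE)
    }
    xg <- rep(NA_real_, n_grid)
    yg <- rep(NA_real_, n_grid)
    at <- match(frame[rows], grid)
    xg[at] <- x_px[rows]
    yg[at] <- y_px[rows]
    det <- sum(is.finite(xg) & is.finite(yg)) / n_grid
    filled <- fill_gaps(xg, yg, max_gap_frames)
    fish_trajectory(fish_id[rows[1L]], t_of_frame, filled$x, filled$y,
                    detection_fraction = det)
  })

  if (is.null(sample_duration_s)) {
    dt <- median(diff(t_of_frame))
    sample_duration_s <- diff(range(t_of_frame)) + dt
  }
  group_recording(site, tank_id, unname(trajectories), calibration,
                  sample_duration_s = sample_duration_s)
}

#' Linearly interpolate short detection gaps
#'
#' Interior runs of missing frames of length at most `max_gap_frames` are
#' filled by linear interpolation of both coordinates; longer runs and runs
#' touching either end stay `NA`.
#' @noRd
fill_gaps <- function(x, y, max_gap_frames) {
  miss <- !(is.finite(x) & is.finite(y))
  if (!any(miss) || max_gap_frames < 1L) {
    x[miss] <- NA_real_; y[miss] <- NA_real_
    return(list(x = x, y = y))
  }
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(x)
  for (k in which(r$values)) {
    s <- starts[k]; e <- ends[k]
    if (s == 1L || e == n || r$lengths[k] > max_gap_frames) {
      x[s:e] <- NA_real_; y[s:e] <- NA_real_
      next
    }
    w <- (seq_len(e - s + 1L)) / (e - s + 2L)
    x[s:e] <- x[s - 1L] + w * (x[e + 1L] - x[s - 1L])
    y[s:e] <- y[s - 1L] + w * (y[e + 1L] - y[s - 1L])
  }
  list(x = x, y = y)
}
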