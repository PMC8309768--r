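#' Single-fish trajectory
#'
#' One fish's time-ordered 2-D pixel positions on the recording's common frame
#' grid. Frames where the tracker lost the fish and the gap was too long to
#' interpolate are retained with `valid = FALSE` and `NA` coordinates; all
#' time-summed endpoints skip them. `detection_fraction` is the fraction of
#' grid frames with a raw detection, recorded before any interpolation, and is
#' the quantity the tracking-accuracy QC gate tests.
#'
#' @param fish_id Identifier for the fish.
#' @param times_s Strictly increasing numeric vector of frame times (seconds).
#' @param x_px,y_px Numeric vectors of pixel coordinates, same length as
#'   `times_s`; `NA` marks an excluded frame.
#' @param detection_fraction Fraction of frames detected before gap-filling,
#'   in `[0, 1]`.
#'
#' @return An object of class `fish_trajectory`.
#' @export
fish_trajectory <- function(fish_id, times_s, x_px, y_px,
                            detection_fraction = 1) {
  n <- length(times_s)
  if (n < 2L) stop("fish_trajectory: need at least 2 frames", call. = FALSE)
  if (length(x_px) != n || length(y_px) != n) {
    stop("fish_trajectory: coordinate vectors must match times_s in length",
         call. = FALSE)
  }
  if (any(diff(times_s) <= 0)) {
    stop("fish_trajectory: times_s must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(detection_fraction) || length(detection_fraction) != 1L ||
      is.na(detection_fraction) ||
      detection_fraction < 0 || detection_fraction > 1) {
    stop("fish_trajectory: detection_fraction must be in [0, 1]", call. = FALSE)
  }
  valid <- is.finite(x_px) & is.finite(y_px)
  structure(
    list(fish_id = fish_id, times_s = as.numeric(times_s),
         x_px = as.numeric(x_px), y_px = as.numeric(y_px),
         valid = valid, detection_fraction = detection_fraction),
    class = "fish_trajectory"
  )
}

#' @export
print.fish_trajectory <- function(x, ...) {
  cat(sprintf("<fish_trajectory> fish %s: %d frames, %.1f%% detected\n",
              as.character(x$fish_id), length(x$times_s),
              100 * x$detection_fraction))
  invisible(x)
}

#' Group recording: one tank's trajectories
#'
#' The unit of behavioral analysis: the trajectories of one tank's fish (six
#' in the reference design) sharing a common time grid, plus the calibration
#' and site/tank metadata.
#'
#' @param site Site label (e.g. `"site1"`).
#' @param tank_id Tank identifier.
#' @param trajectories List of [fish_trajectory()] objects on a common grid.
#' @param calibration A [calibration_info()] object.
#' @param sample_duration_s Nominal sample duration in seconds (default 180,
#'   the 3-minute sample period of the reference protocol).
#'
#' @return An object of class `group_recording`.
#' @export
group_recording <- function(site, tank_id, trajectories, calibration,
                            sample_duration_s = 180) {
  if (!length(trajectories)) {
    stop("group_recording: no trajectories supplied", call. = FALSE)
  }
  if (!all(vapply(trajectories, inherits, logical(1), "fish_trajectory"))) {
    stop("group_recording: trajectories must be fish_trajectory objects",
         call. = FALSE)
  }
  stopifnot(inherits(calibration, "calibration_info"))
  grid <- trajectories[[1L]]$times_s
  same <- vapply(trajectories, function(tr) {
    length(tr$times_s) == length(grid) &&
      isTRUE(all.equal(tr$times_s, grid, tolerance = 1e-9))
  }, logical(1))
  if (!all(same)) {
    stop("group_recording: trajectories do not share a common time grid",
         call. = FALSE)
  }
  if (!is.numeric(sample_duration_s) || sample_duration_s <= 0) {
    stop("group_recording: sample_duration_s must be positive", call. = FALSE)
  }
  ids <- vapply(trajectories, function(tr) as.character(tr$fish_id), character(1))
  if (anyDuplicated(ids)) {
    stop("group_recording: duplicated fish ids", call. = FALSE)
  }
  names(trajectories) <- ids
  structure(
    list(site = site, tank_id = tank_id, trajectories = trajectories,
         calibration = calibration, sample_duration_s = sample_duration_s),
    class = "group_recording"
  )
}

#' @export
print.group_recording <- function(x, ...) {
  cat(sprintf("<group_recording> site %s tank %s: %d fish, %d frames, %.0f s\n",
              as.character(x$site), as.character(x$tank_id),
              length(x$trajectories), length(x$trajectories[[1]]$times_s),
              x$sample_duration_s))
  invisible(x)
}

n_fish <- function(group) length(group$trajectories)

#' Positions of a group recording as arrays
#'
#' Internal convenience: frames x fish matrices of x, y (pixel) and validity.
#' @noRd
group_arrays <- function(group) {
  xs <- vapply(group$trajectories, `[[`, numeric(length(group$trajectories[[1]]$times_s)), "x_px")
  ys <- vapply(group$trajectories, `[[`, numeric(nrow(xs)), "y_px")
  vs <- vapply(group$trajectories, `[[`, logical(nrow(xs)), "valid")
  list(x = xs, y = ys, valid = vs, times = group$trajectories[[1]]$times_s)
}
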