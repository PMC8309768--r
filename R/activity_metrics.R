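#' Activity metric configuration
#'
#' Two thresholds the activity endpoints need but that are conventions rather
#' than measurements: the instantaneous speed above which a frame counts as
#' "in motion" (default 5 mm/s, about half a body length per second for the
#' smaller site's fish), and the square cell size of the exploration grid
#' (default 10 mm).
#'
#' @param motion_speed_threshold_mm_s Non-negative speed threshold, mm/s.
#' @param exploration_cell_mm Positive grid cell edge, mm.
#' @return An object of class `activity_config`.
#' @export
activity_config <- function(motion_speed_threshold_mm_s = 5,
                            exploration_cell_mm = 10) {
  if (!is.numeric(motion_speed_threshold_mm_s) ||
      motion_speed_threshold_mm_s < 0 ||
      !is.finite(motion_speed_threshold_mm_s)) {
    stop("activity_config: motion threshold must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.numeric(exploration_cell_mm) || exploration_cell_mm <= 0) {
    stop("activity_config: exploration_cell_mm must be positive", call. = FALSE)
  }
  structure(list(motion_speed_threshold_mm_s = motion_speed_threshold_mm_s,
                 exploration_cell_mm = exploration_cell_mm),
            class = "activity_config")
}

#' Step lengths of a trajectory in mm
#'
#' Backward differences on the frame grid; a step exists only when both of
#' its frames are valid. Returns the per-step length (mm) and the number of
#' valid steps.
#' @noRd
step_lengths_mm <- function(traj, cal) {
  n <- length(traj$x_px)
  ok <- traj$valid[-n] & traj$valid[-1L]
  dx <- traj$x_px[-1L] - traj$x_px[-n]
  dy <- traj$y_px[-1L] - traj$y_px[-n]
  len_px <- sqrt(dx^2 + dy^2)
  len_px[!ok] <- NA_real_
  list(mm = px_to_mm(len_px, cal), ok = ok)
}

#' Distance traveled
#'
#' Total path length in mm: the sum of Euclidean step lengths over
#' consecutive valid frame pairs. Steps spanning an excluded frame are
#' omitted.
#'
#' @param traj A [fish_trajectory()].
#' @param cal A [calibration_info()].
#' @return Distance in mm.
#' @export
distance_traveled <- function(traj, cal) {
  stopifnot(inherits(traj, "fish_trajectory"), inherits(cal, "calibration_info"))
  st <- step_lengths_mm(traj, cal)
  if (!any(st$ok)) {
    stop("distance_traveled: no valid consecutive frame pair", call. = FALSE)
  }
  sum(st$mm[st$ok])
}

#' Swim speed
#'
#' Distance traveled divided by the valid observed duration: the number of
#' valid steps times the frame period. With complete tracking this equals
#' total distance over the sample duration minus one frame period.
#'
#' @inheritParams distance_traveled
#' @return Mean speed in mm/s.
#' @export
swim_speed <- function(traj, cal) {
  stopifnot(inherits(traj, "fish_trajectory"), inherits(cal, "calibration_info"))
  st <- step_lengths_mm(traj, cal)
  valid_s <- sum(st$ok) / cal$frame_rate
  if (valid_s <= 0) {
    stop("swim_speed: zero valid duration", call. = FALSE)
  }
  sum(st$mm[st$ok]) / valid_s
}

#' Time in motion
#'
#' Seconds whose instantaneous speed (step length x frame rate) exceeds the
#' motion threshold (strict comparison, so a stationary fish is never "in
#' motion" even at threshold zero).
#'
#' @inheritParams distance_traveled
#' @param cfg An [activity_config()].
#' @return Seconds in motion.
#' @export
time_in_motion <- function(traj, cal, cfg = activity_config()) {
  stopifnot(inherits(traj, "fish_trajectory"), inherits(cal, "calibration_info"),
            inherits(cfg, "activity_config"))
  st <- step_lengths_mm(traj, cal)
  if (!any(st$ok)) {
    stop("time_in_motion: no valid consecutive frame pair", call. = FALSE)
  }
  speeds <- st$mm[st$ok] * cal$frame_rate
  sum(speeds > cfg$motion_speed_threshold_mm_s) / cal$frame_rate
}

#' Tank exploration
#'
#' The arena is partitioned into square cells of `exploration_cell_mm` on a
#' side (cells at the far edges are truncated by the wall); the visited area
#' is the number of cells containing at least one valid position times the
#' full cell area, capped at the arena area. Positions outside the arena
#' bounds raise a warning and are clamped into the boundary cell.
#'
#' @inheritParams time_in_motion
#' @return List with `area_mm2` (visited area) and `percent` (of arena area).
#' @export
exploration_area <- function(traj, cal, cfg = activity_config()) {
  stopifnot(inherits(traj, "fish_trajectory"), inherits(cal, "calibration_info"),
            inherits(cfg, "activity_config"))
  cell <- cfg$exploration_cell_mm
  if (cell >= cal$arena_width_mm || cell >= cal$arena_height_mm) {
    stop("exploration_area: cell size must be smaller than the arena",
         call. = FALSE)
  }
  x_mm <- px_to_mm(traj$x_px[traj$valid], cal)
  y_mm <- px_to_mm(traj$y_px[traj$valid], cal)
  if (!length(x_mm)) {
    stop("exploration_area: no valid positions", call. = FALSE)
  }
  out_of_bounds <- x_mm < 0 | x_mm > cal$arena_width_mm |
    y_mm < 0 | y_mm > cal$arena_height_mm
  if (any(out_of_bounds)) {
    warning(sprintf("exploration_area: %d position(s) outside the arena; clamped",
                    sum(out_of_bounds)))
  }
  nx <- ceiling(cal$arena_width_mm / cell)
  ny <- ceiling(cal$arena_height_mm / cell)
  ix <- pmin(pmax(floor(x_mm / cell), 0), nx - 1L)
  iy <- pmin(pmax(floor(y_mm / cell), 0), ny - 1L)
  n_cells <- length(unique(ix * ny + iy))
  area <- min(n_cells * cell^2, arena_area_mm2(cal))
  list(area_mm2 = area, percent = 100 * area / arena_area_mm2(cal))
}
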