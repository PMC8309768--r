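#' Arena and camera calibration
#'
#' Bundles the pixel-to-millimetre scale, the video frame rate, and the arena
#' dimensions of one recording setup. The default arena is the 30.8 cm x 34 cm
#' white test tank used in the field protocol this package implements.
#'
#' @param px_per_mm Pixels per millimetre of the video frame. Must be > 0.
#' @param frame_rate Frames per second of the common time grid. Must be > 0.
#' @param arena_width_mm,arena_height_mm Arena dimensions in mm. Must be > 0.
#'
#' @return An object of class `calibration_info`.
#' @examples
#' cal <- calibration_info(px_per_mm = 10, frame_rate = 30)
#' px_to_mm(250, cal)
#' @export
calibration_info <- function(px_per_mm, frame_rate = 30,
                             arena_width_mm = 308, arena_height_mm = 340) {
  for (nm in c("px_per_mm", "frame_rate", "arena_width_mm", "arena_height_mm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("calibration_info: `", nm, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  structure(
    list(px_per_mm = px_per_mm, frame_rate = frame_rate,
         arena_width_mm = arena_width_mm, arena_height_mm = arena_height_mm),
    class = "calibration_info"
  )
}

#' @rdname calibration_info
#' @param x Numeric vector of pixel (or mm) values.
#' @param cal A `calibration_info` object.
#' @export
px_to_mm <- function(x, cal) {
  stopifnot(inherits(cal, "calibration_info"))
  x / cal$px_per_mm
}

#' @rdname calibration_info
#' @export
mm_to_px <- function(x, cal) {
  stopifnot(inherits(cal, "calibration_info"))
  x * cal$px_per_mm
}

#' @export
print.calibration_info <- function(x, ...) {
  cat(sprintf(
    "<calibration_info> %.4g px/mm, %.4g fps, arena %.4g x %.4g mm\n",
    x$px_per_mm, x$frame_rate, x$arena_width_mm, x$arena_height_mm))
  invisible(x)
}

arena_area_mm2 <- function(cal) cal$arena_width_mm * cal$arena_height_mm
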