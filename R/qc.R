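#' Tracking-accuracy quality-control gate
#'
#' A recording is considered reliable when every fish was detected in at least
#' `threshold` of the grid frames (before gap interpolation). The default
#' threshold is 0.80, the minimum tracking accuracy required by the field
#' protocol; the comparison is inclusive, so a fish at exactly the threshold
#' passes.
#'
#' @param group A [group_recording()].
#' @param threshold Minimum detection fraction in `[0, 1]` (default 0.80).
#'
#' @return A list of class `qc_report` with elements `per_fish` (data frame of
#'   `fish_id`, `detection_fraction`, `pass`), `tank_pass` (logical), and
#'   `failing_fish` (character vector of ids below threshold).
#' @examples
#' cal <- calibration_info(px_per_mm = 10)
#' tr <- fish_trajectory("f1", c(0, 1), c(0, 1), c(0, 1), detection_fraction = 0.9)
#' g <- group_recording("site1", "t1", list(tr), cal, sample_duration_s = 2)
#' qc_tracking_accuracy(g)$tank_pass
#' @export
qc_tracking_accuracy <- function(group, threshold = 0.80) {
  stopifnot(inherits(group, "group_recording"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("qc_tracking_accuracy: threshold must be in [0, 1]", call. = FALSE)
  }
  det <- vapply(group$trajectories, `[[`, numeric(1), "detection_fraction")
  per_fish <- data.frame(
    fish_id = names(group$trajectories),
    detection_fraction = unname(det),
    pass = unname(det >= threshold),
    stringsAsFactors = FALSE
  )
  structure(
    list(site = group$site, tank_id = group$tank_id, threshold = threshold,
         per_fish = per_fish,
         tank_pass = all(per_fish$pass),
         failing_fish = per_fish$fish_id[!per_fish$pass]),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> tank %s: %s (threshold %.2f)\n",
              as.character(x$tank_id),
              if (x$tank_pass) "PASS" else
                paste0("FAIL: ", paste(x$failing_fish, collapse = ", ")),
              x$threshold))
  invisible(x)
}
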