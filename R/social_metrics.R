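#' Proximity threshold configuration
#'
#' The "time in proximity" endpoint counts seconds a fish spends within two
#' body-lengths of at least one group member. The field protocol standardized
#' that distance at 1000 pixels; studies with different optics can supply an
#' mm threshold instead (conventionally twice the mean standard length).
#'
#' @param threshold_px Proximity radius in pixels (default 1000).
#' @param threshold_mm Proximity radius in mm, used when `use_mm = TRUE`.
#' @param use_mm Use the mm threshold rather than the pixel one.
#' @return An object of class `proximity_config`.
#' @export
proximity_config <- function(threshold_px = 1000, threshold_mm = NULL,
                             use_mm = FALSE) {
  if (use_mm) {
    if (is.null(threshold_mm) || !is.numeric(threshold_mm) || threshold_mm <= 0) {
      stop("proximity_config: use_mm = TRUE requires a positive threshold_mm",
           call. = FALSE)
    }
  } else if (!is.numeric(threshold_px) || length(threshold_px) != 1L ||
             threshold_px <= 0) {
    stop("proximity_config: threshold_px must be a single positive number",
         call. = FALSE)
  }
  structure(list(threshold_px = threshold_px, threshold_mm = threshold_mm,
                 use_mm = use_mm),
            class = "proximity_config")
}

#' Per-frame pairwise distance structure of a group
#'
#' Returns, per fish, the per-frame mean distance to all valid others, the
#' per-frame minimum distance, and the per-frame count of valid others.
#' A frame contributes to fish i only if fish i itself is valid there.
#' @noRd
pair_distance_frames <- function(group) {
  arr <- group_arrays(group)
  nfr <- nrow(arr$x)
  nf <- ncol(arr$x)
  sum_d <- matrix(0, nfr, nf)
  min_d <- matrix(Inf, nfr, nf)
  cnt <- matrix(0L, nfr, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq((i + 1L), nf)) {
      ok <- arr$valid[, i] & arr$valid[, j]
      d <- sqrt((arr$x[, i] - arr$x[, j])^2 + (arr$y[, i] - arr$y[, j])^2)
      d[!ok] <- NA_real_
      w <- which(ok)
      sum_d[w, i] <- sum_d[w, i] + d[w]
      sum_d[w, j] <- sum_d[w, j] + d[w]
      cnt[w, i] <- cnt[w, i] + 1L
      cnt[w, j] <- cnt[w, j] + 1L
      min_d[w, i] <- pmin(min_d[w, i], d[w])
      min_d[w, j] <- pmin(min_d[w, j], d[w])
    }
  }
  list(sum_d = sum_d, min_d = min_d, cnt = cnt, n_fish = nf, n_frames = nfr,
       valid = arr$valid)
}

#' Inter-individual distance
#'
#' For each fish, the time-averaged mean Euclidean distance to all other group
#' members, in mm. A frame enters a fish's average only when that fish and
#' *all* other group members have valid positions there (so the "mean over
#' others" is always over the full group).
#'
#' @param group A [group_recording()] with at least 2 fish.
#' @return Named numeric vector, mm, one value per fish.
#' @export
interindividual_distance <- function(group) {
  stopifnot(inherits(group, "group_recording"))
  if (n_fish(group) < 2L) {
    stop("interindividual_distance: need at least 2 fish", call. = FALSE)
  }
  pf <- pair_distance_frames(group)
  full <- pf$cnt == (pf$n_fish - 1L)  # frames where every other fish is valid
  out <- vapply(seq_len(pf$n_fish), function(i) {
    use <- full[, i] & pf$valid[, i]
    if (!any(use)) return(NA_real_)
    mean(pf$sum_d[use, i] / (pf$n_fish - 1L))
  }, numeric(1))
  names(out) <- names(group$trajectories)
  px_to_mm(out, group$calibration)
}

#' Nearest-neighbour distance
#'
#' For each fish, the time-averaged distance to its closest valid group
#' member, in mm.
#'
#' @inheritParams interindividual_distance
#' @return Named numeric vector, mm, one value per fish.
#' @export
nearest_neighbor_distance <- function(group) {
  stopifnot(inherits(group, "group_recording"))
  if (n_fish(group) < 2L) {
    stop("nearest_neighbor_distance: need at least 2 fish", call. = FALSE)
  }
  pf <- pair_distance_frames(group)
  out <- vapply(seq_len(pf$n_fish), function(i) {
    use <- pf$valid[, i] & pf$cnt[, i] > 0L
    if (!any(use)) return(NA_real_)
    mean(pf$min_d[use, i])
  }, numeric(1))
  names(out) <- names(group$trajectories)
  px_to_mm(out, group$calibration)
}

#' Time in proximity
#'
#' Seconds each fish spends with at least one group member within the
#' proximity threshold (inclusive comparison). Frames excluded by gap
#' handling are excluded from both numerator and denominator; the result
#' carries both raw seconds and the fraction of that fish's valid time.
#'
#' @inheritParams interindividual_distance
#' @param cfg A [proximity_config()].
#' @return Named numeric vector of seconds per fish, with the fraction of
#'   valid time in attribute `"fraction"` and the valid seconds in
#'   attribute `"valid_s"`.
#' @export
time_in_proximity <- function(group, cfg = proximity_config()) {
  stopifnot(inherits(group, "group_recording"),
            inherits(cfg, "proximity_config"))
  if (n_fish(group) < 2L) {
    stop("time_in_proximity: need at least 2 fish", call. = FALSE)
  }
  thr_px <- if (cfg$use_mm) mm_to_px(cfg$threshold_mm, group$calibration)
            else cfg$threshold_px
  pf <- pair_distance_frames(group)
  fr <- group$calibration$frame_rate
  secs <- numeric(pf$n_fish)
  frac <- numeric(pf$n_fish)
  valid_s <- numeric(pf$n_fish)
  for (i in seq_len(pf$n_fish)) {
    use <- pf$valid[, i] & pf$cnt[, i] > 0L
    nin <- sum(pf$min_d[use, i] <= thr_px)
    secs[i] <- min(nin / fr, group$sample_duration_s)
    valid_s[i] <- sum(use) / fr
    frac[i] <- if (valid_s[i] > 0) (nin / fr) / valid_s[i] else NA_real_
  }
  names(secs) <- names(group$trajectories)
  attr(secs, "fraction") <- frac
  attr(secs, "valid_s") <- valid_s
  secs
}
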