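#' Trajectory simulation configuration for one site
#'
#' Parameters of the correlated random walk with centroid attraction that
#' emulates one site's group swimming: per-frame speeds are gamma distributed
#' (mean `mean_speed_mm_s`, shape `speed_shape`), headings persist with
#' weight `heading_persistence`, are attracted toward the group centroid with
#' weight `cohesion_weight`, and receive von Mises angular noise with
#' concentration `heading_noise_kappa`. Between-tank heterogeneity — real
#' tanks of wild fish differ — enters as symmetric multipliers (normal with
#' mean 1, truncated well above zero) on the mean speed (`tank_speed_cv`)
#' and on the cohesion weight (`tank_cohesion_cv`).
#'
#' @param mean_speed_mm_s Mean frame speed, mm/s.
#' @param speed_shape Gamma shape of the frame-speed distribution.
#' @param heading_persistence Heading persistence weight in `[0, 1)`.
#' @param cohesion_weight Centroid-attraction weight, >= 0. The attraction
#'   strength is `cohesion_weight * min(d / cohesion_range_mm, 1)` for a fish
#'   at distance `d` from the group centroid, so cohesion fades once a fish
#'   has rejoined the group.
#' @param cohesion_range_mm Distance scale of the attraction spring
#'   (default 1000 mm, larger than the tank, so the pull grows linearly
#'   with distance from the group everywhere in the arena).
#' @param heading_noise_kappa von Mises concentration of heading noise (> 0;
#'   small values approach uniform headings).
#' @param tank_speed_cv,tank_cohesion_cv Spread (sd, as a fraction of the
#'   mean) of the symmetric per-tank multipliers applied to the mean speed
#'   and the cohesion weight (0 disables heterogeneity).
#' @param n_fish Fish per tank (default 6).
#' @param n_tanks_per_site Tanks per site (default 12).
#' @param duration_s Sample duration, s (default 180).
#' @param frame_rate Frames per second (default 30).
#' @param arena A [calibration_info()] (default: the 308 x 340 mm tank at
#'   20 px/mm, 30 fps — a scale at which the 1000 px proximity standard is
#'   50 mm, about two body lengths of the larger site's fish).
#' @return An object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(mean_speed_mm_s, speed_shape = 2,
                                  heading_persistence = 0.9,
                                  cohesion_weight = 0.5,
                                  cohesion_range_mm = 1000,
                                  heading_noise_kappa = 4,
                                  tank_speed_cv = 0, tank_cohesion_cv = 0,
                                  n_fish = 6, n_tanks_per_site = 12,
                                  duration_s = 180, frame_rate = 30,
                                  arena = NULL) {
  if (is.null(arena)) arena <- calibration_info(20, frame_rate)
  stopifnot(inherits(arena, "calibration_info"))
  if (mean_speed_mm_s <= 0 || speed_shape <= 0 || heading_noise_kappa <= 0) {
    stop("trajectory_sim_config: speed and noise parameters must be positive",
         call. = FALSE)
  }
  if (heading_persistence < 0 || heading_persistence >= 1) {
    stop("trajectory_sim_config: heading_persistence must be in [0, 1)",
         call. = FALSE)
  }
  if (cohesion_weight < 0) {
    stop("trajectory_sim_config: cohesion_weight must be >= 0", call. = FALSE)
  }
  if (cohesion_range_mm <= 0) {
    stop("trajectory_sim_config: cohesion_range_mm must be positive",
         call. = FALSE)
  }
  structure(
    list(mean_speed_mm_s = mean_speed_mm_s, speed_shape = speed_shape,
         heading_persistence = heading_persistence,
         cohesion_weight = cohesion_weight,
         cohesion_range_mm = cohesion_range_mm,
         heading_noise_kappa = heading_noise_kappa,
         tank_speed_cv = tank_speed_cv, tank_cohesion_cv = tank_cohesion_cv,
         n_fish = n_fish, n_tanks_per_site = n_tanks_per_site,
         duration_s = duration_s, frame_rate = frame_rate, arena = arena),
    class = "trajectory_sim_config")
}

#' von Mises random angles (Best-Fisher rejection sampler)
#' @noRd
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    if (any(ok)) {
      ang <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + sum(ok))] <- ang
      got <- got + sum(ok)
    }
  }
  out
}

#' Symmetric tank multiplier: normal(1, cv) truncated below at 0.15
#' @noRd
rmult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1L, 1, cv)
      if (v >= 0.15) break
    }
    out[i] <- v
  }
  out
}

#' Simulate one tank's group swimming
#'
#' Runs the correlated random walk for one tank. Each fish consumes its own
#' random substream (derived from `seed`), so adding a fish to the
#' configuration never perturbs the others' draws; tank-level heterogeneity
#' multipliers are drawn from the tank's own stream. Output is bit-reproducible
#' for a given seed.
#'
#' @param cfg A [trajectory_sim_config()].
#' @param site Site label.
#' @param tank_id Tank identifier.
#' @param seed Integer seed for this tank.
#' @return A [group_recording()] (positions in pixels, per the calibration).
#' @export
simulate_group <- function(cfg, site, tank_id, seed) {
  stopifnot(inherits(cfg, "trajectory_sim_config"))
  arena <- cfg$arena
  n_steps <- round(cfg$duration_s * cfg$frame_rate) - 1L
  if (n_steps < 1L) stop("simulate_group: duration too short", call. = FALSE)

  set.seed(seed)
  speed_mult <- rmult(1L, cfg$tank_speed_cv)
  coh_mult <- rmult(1L, cfg$tank_cohesion_cv)
  fish_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_fish)

  init <- matrix(0, cfg$n_fish, 2L)
  head0 <- numeric(cfg$n_fish)
  steps <- matrix(0, n_steps, cfg$n_fish)
  noise <- matrix(0, n_steps, cfg$n_fish)
  scale_mm <- cfg$mean_speed_mm_s * speed_mult / cfg$speed_shape
  for (i in seq_len(cfg$n_fish)) {
    set.seed(fish_seeds[i])
    init[i, ] <- c(runif(1, 0, arena$arena_width_mm),
                   runif(1, 0, arena$arena_height_mm))
    head0[i] <- runif(1, -pi, pi)
    steps[, i] <- rgamma(n_steps, shape = cfg$speed_shape,
                         scale = scale_mm) / cfg$frame_rate
    noise[, i] <- rvonmises(n_steps, cfg$heading_noise_kappa)
  }

  pos_mm <- sim_tank_cpp(init, steps, noise, head0,
                         cfg$heading_persistence,
                         cfg$cohesion_weight * coh_mult,
                         cfg$cohesion_range_mm,
                         arena$arena_width_mm, arena$arena_height_mm)
  times <- (seq_len(n_steps + 1L) - 1L) / cfg$frame_rate
  trajectories <- lapply(seq_len(cfg$n_fish), function(i) {
    fish_trajectory(paste0("fish", i), times,
                    x_px = pos_mm[, i, 1L] * arena$px_per_mm,
                    y_px = pos_mm[, i, 2L] * arena$px_per_mm,
                    detection_fraction = 1)
  })
  group_recording(site, tank_id, trajectories, arena,
                  sample_duration_s = cfg$duration_s)
}

#' Write a group recording in the generic-csv trajectory dialect
#'
#' Emits exactly the format [read_trajectory_table()] reads with
#' `dialect = "generic-csv"`, so simulated data exercise the real parser.
#'
#' @param group A [group_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_group_csv <- function(group, path) {
  stopifnot(inherits(group, "group_recording"))
  arr <- group_arrays(group)
  n_frames <- nrow(arr$x)
  rows <- do.call(rbind, lapply(seq_along(group$trajectories), function(i) {
    keep <- arr$valid[, i]
    data.frame(frame = (seq_len(n_frames) - 1L)[keep],
               time_s = sprintf("%.10g", arr$times[keep]),
               fish_id = names(group$trajectories)[i],
               x_px = sprintf("%.10g", arr$x[keep, i]),
               y_px = sprintf("%.10g", arr$y[keep, i]),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$frame), ]
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
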