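#' Study presets
#'
#' `reference_study_preset()` encodes the reference two-site field design: 2 sites
#' x 12 tanks x 6 fish x 180 s at 30 fps in the 308 x 340 mm tank, with the
#' site contrasts the field study reported — Site 1 faster (mean frame speed
#' 14 vs 9 mm/s) and less cohesive (centroid-attraction weight 0.2 vs 0.8),
#' Site 1 fish larger (median standard length 22/13 vs 10/9 mm by sex), and
#' a sex shape dimorphism only in Site 2 (Site 2 males' posterior region
#' shrunk toward a posterior/anterior ratio of ~1.3, against ~1.5-1.6
#' elsewhere). Site speed-distribution shapes are fixed so both sites have
#' the same expected fraction of frames below the 5 mm/s motion threshold,
#' and heading persistence is fixed so both sites have the same expected
#' arena coverage: the study found no site difference in time-in-motion or
#' exploration, so none is planted. Between-tank lognormal heterogeneity
#' (CV 0.35 on speed, 0.45 on cohesion) gives tank means a spread of the
#' order of the published standard errors.
#'
#' `identical_sites_preset()` is the matching null study: both sites share
#' one parameter set (the average behavior), all four landmark groups share
#' the template, size distribution, and noise, so every between-group test's
#' null hypothesis is true. Its `duration_s`, `frame_rate`, and
#' `n_per_group` arguments let calibration experiments that only exercise
#' test levels run at a smaller problem size.
#'
#' @return A list of class `study_preset` with elements `site1`, `site2`
#'   ([trajectory_sim_config()]s), and `landmarks`
#'   ([landmark_sim_config()]).
#' @export
reference_study_preset <- function() {
  d <- function(...) {
    m <- matrix(0, 7L, 2L)
    for (e in list(...)) m[e[1L], e[2L]] <- e[3L]
    m
  }
  defo <- list(
    "site1:female" = d(c(4, 1, 0.20), c(3, 2, 0.05), c(5, 1, -0.10)),
    "site1:male"   = d(c(4, 1, 0.20), c(3, 2, 0.05), c(5, 1, -0.10)),
    "site2:female" = d(c(4, 1, -0.60), c(6, 2, -0.10)),
    "site2:male"   = d(c(4, 1, -1.30), c(3, 2, -0.20), c(6, 2, -0.25))
  )
  structure(list(
    site1 = trajectory_sim_config(
      mean_speed_mm_s = 14, speed_shape = 2,
      heading_persistence = 0.82, cohesion_weight = 0.2,
      heading_noise_kappa = 3,
      tank_speed_cv = 0.35, tank_cohesion_cv = 0.45),
    site2 = trajectory_sim_config(
      # speed_shape and tank_speed_cv jointly solve for the same mean AND
      # between-tank sd of time-in-motion as site 1 (the study found no
      # site difference there, so none is planted; site 2 tanks are also
      # the less variable ones in the study), and the straighter heading
      # dynamics (persistence, kappa) equate expected arena coverage so no
      # exploration contrast is planted either
      mean_speed_mm_s = 9, speed_shape = 4.593646,
      heading_persistence = 0.97, cohesion_weight = 0.8,
      heading_noise_kappa = 10,
      tank_speed_cv = 0.2304974, tank_cohesion_cv = 0.45),
    landmarks = landmark_sim_config(
      deformations = defo,
      median_sl_mm = c("site1:female" = 13, "site1:male" = 22,
                       "site2:female" = 9, "site2:male" = 10),
      n_per_group = c("site1:female" = 9, "site1:male" = 61,
                      "site2:female" = 23, "site2:male" = 49))
  ), class = "study_preset")
}

#' @rdname reference_study_preset
#' @param duration_s,frame_rate Recording length and rate of the null
#'   preset's tanks.
#' @param n_per_group Specimens per site x sex group in the null preset.
#' @export
identical_sites_preset <- function(duration_s = 180, frame_rate = 30,
                                   n_per_group = 18) {
  shared <- function() trajectory_sim_config(
    mean_speed_mm_s = 11.5, speed_shape = 3,
    heading_persistence = 0.88, cohesion_weight = 0.5,
    heading_noise_kappa = 5,
    tank_speed_cv = 0.35, tank_cohesion_cv = 0.45,
    duration_s = duration_s, frame_rate = frame_rate)
  structure(list(
    site1 = shared(),
    site2 = shared(),
    landmarks = landmark_sim_config(
      deformations = list(),
      median_sl_mm = c("site1:female" = 14, "site1:male" = 14,
                       "site2:female" = 14, "site2:male" = 14),
      n_per_group = c("site1:female" = n_per_group,
                      "site1:male" = n_per_group,
                      "site2:female" = n_per_group,
                      "site2:male" = n_per_group))
  ), class = "study_preset")
}

#' Simulate a full two-site study
#'
#' Draws every tank's trajectories and every specimen's landmarks for a
#' preset, with one master seed: tank and group seeds are spawned from it,
#' each tank then uses per-fish substreams, so the whole study is
#' bit-reproducible.
#'
#' @param preset A `study_preset` (or a list with `site1`, `site2`,
#'   `landmarks` entries of the right classes).
#' @param seed Integer master seed.
#' @return A list of class `study_data`: `groups` (list of
#'   [group_recording()]), `landmarks` (list of [landmark_set()]), and
#'   `truth` (the preset plus the spawned seeds — the generator's ground
#'   truth for recovery tests).
#' @export
simulate_study <- function(preset, seed) {
  stopifnot(is.list(preset),
            inherits(preset$site1, "trajectory_sim_config"),
            inherits(preset$site2, "trajectory_sim_config"),
            inherits(preset$landmarks, "landmark_sim_config"))
  if (!identical(preset$site1$n_tanks_per_site, preset$site2$n_tanks_per_site)) {
    stop("simulate_study: sites must have the same number of tanks",
         call. = FALSE)
  }
  set.seed(seed)
  n_tanks <- preset$site1$n_tanks_per_site
  tank_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n_tanks),
                       nrow = 2L)
  lm_groups <- names(preset$landmarks$n_per_group)
  lm_seeds <- sample.int(.Machine$integer.max - 1L, length(lm_groups))
  names(lm_seeds) <- lm_groups

  groups <- list()
  for (s in 1:2) {
    cfg <- preset[[paste0("site", s)]]
    for (tk in seq_len(n_tanks)) {
      id <- sprintf("site%d_tank%02d", s, tk)
      groups[[id]] <- simulate_group(cfg, paste0("site", s), id,
                                     seed = tank_seeds[s, tk])
    }
  }
  landmarks <- list()
  for (g in lm_groups) {
    parts <- strsplit(g, ":", fixed = TRUE)[[1L]]
    landmarks <- c(landmarks, simulate_landmarks(
      preset$landmarks, parts[1L], parts[2L],
      n = preset$landmarks$n_per_group[[g]], seed = lm_seeds[[g]]))
  }
  structure(list(groups = groups, landmarks = landmarks,
                 truth = list(preset = preset, seed = seed,
                              tank_seeds = tank_seeds, lm_seeds = lm_seeds)),
            class = "study_data")
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d tanks, %d landmark specimens, seed %d\n",
              length(x$groups), length(x$landmarks), x$truth$seed))
  invisible(x)
}
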