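test_that("simulated tanks have the right shape and are bit-reproducible", {
  cfg <- trajectory_sim_config(mean_speed_mm_s = 12, duration_s = 180,
                               frame_rate = 30)
  g <- simulate_group(cfg, "site1", "t1", seed = 7)
  expect_length(g$trajectories, 6)
  expect_length(g$trajectories[[1]]$times_s, 5400)

  g2 <- simulate_group(cfg, "site1", "t1", seed = 7)
  expect_identical(g, g2)

  g3 <- simulate_group(cfg, "site1", "t1", seed = 8)
  expect_false(identical(g$trajectories[[1]]$x_px, g3$trajectories[[1]]$x_px))
})

test_that("per-fish substreams: adding a fish never perturbs the others", {
  cfg5 <- trajectory_sim_config(mean_speed_mm_s = 10, n_fish = 5,
                                duration_s = 6, frame_rate = 20,
                                cohesion_weight = 0)
  cfg6 <- trajectory_sim_config(mean_speed_mm_s = 10, n_fish = 6,
                                duration_s = 6, frame_rate = 20,
                                cohesion_weight = 0)
  g5 <- simulate_group(cfg5, "s", "t", seed = 42)
  g6 <- simulate_group(cfg6, "s", "t", seed = 42)
  # with no coupling (cohesion 0) the first five trajectories are identical
  for (i in 1:5) {
    expect_identical(g5$trajectories[[i]]$x_px, g6$trajectories[[i]]$x_px)
    expect_identical(g5$trajectories[[i]]$y_px, g6$trajectories[[i]]$y_px)
  }
})

test_that("no simulated position ever leaves the arena", {
  cfg <- trajectory_sim_config(mean_speed_mm_s = 40, speed_shape = 1,
                               duration_s = 20, frame_rate = 30,
                               heading_persistence = 0.5,
                               cohesion_weight = 2)
  for (seed in 1:5) {
    g <- simulate_group(cfg, "s", "t", seed = seed)
    arr_w <- g$calibration$arena_width_mm * g$calibration$px_per_mm
    arr_h <- g$calibration$arena_height_mm * g$calibration$px_per_mm
    for (tr in g$trajectories) {
      expect_true(all(tr$x_px >= 0 & tr$x_px <= arr_w))
      expect_true(all(tr$y_px >= 0 & tr$y_px <= arr_h))
    }
  }
})

test_that("realized mean speed matches the configured mean within 3 MC SEs", {
  cfg <- trajectory_sim_config(mean_speed_mm_s = 11, speed_shape = 3,
                               duration_s = 60, frame_rate = 30)
  speeds <- unlist(lapply(1:6, function(s) {
    g <- simulate_group(cfg, "s", "t", seed = 100 + s)
    vapply(g$trajectories, swim_speed, numeric(1), cal = g$calibration)
  }))
  # per-frame speeds are gamma(mean 11, shape 3): a fish's mean over m frames
  # has variance 11^2/(3 m); fish means are independent
  m <- 60 * 30 - 1
  se <- sqrt(11^2 / (3 * m) / length(speeds))
  expect_lt(abs(mean(speeds) - 11), 3 * se)
})

test_that("uncorrelated walkers reach the uniform-pair expected distance", {
  # persistence 0, cohesion 0, near-uniform headings: the reflected random
  # walk's stationary marginal is uniform on the arena, so the expected
  # inter-fish distance is the closed-form uniform-rectangle value
  cfg <- trajectory_sim_config(mean_speed_mm_s = 2000, speed_shape = 2,
                               heading_persistence = 0,
                               cohesion_weight = 0,
                               heading_noise_kappa = 1e-9,
                               n_fish = 4, duration_s = 60, frame_rate = 30)
  tank_iids <- vapply(1:8, function(s) {
    mean(interindividual_distance(simulate_group(cfg, "s", "t", seed = 300 + s)))
  }, numeric(1))
  expected <- uniform_rect_expected_distance(308, 340)
  mc_se <- sd(tank_iids) / sqrt(length(tank_iids))
  expect_lt(abs(mean(tank_iids) - expected), 3 * mc_se)
})

test_that("expected cohesion decreases tank-mean IID over 0, 0.4, 0.8", {
  mk <- function(w) trajectory_sim_config(mean_speed_mm_s = 12,
                                          cohesion_weight = w,
                                          duration_s = 60, frame_rate = 15)
  iid_mean <- function(w, seeds) {
    vapply(seeds, function(s)
      mean(interindividual_distance(simulate_group(mk(w), "s", "t", s))),
      numeric(1))
  }
  n_rep <- 16
  m0 <- iid_mean(0, 1:n_rep + 1000)
  m4 <- iid_mean(0.4, 1:n_rep + 2000)
  m8 <- iid_mean(0.8, 1:n_rep + 3000)
  ci <- function(v) mean(v) + c(-1, 1) * qt(0.975, n_rep - 1) * sd(v) / sqrt(n_rep)
  # strictly decreasing with non-overlapping 95% CIs
  expect_gt(ci(m0)[1], ci(m4)[2])
  expect_gt(ci(m4)[1], ci(m8)[2])
})

test_that("landmark generator: nuisance-only case collapses to the template", {
  cfg <- landmark_sim_config(
    deformations = list(), landmark_noise_sd = 0,
    median_sl_mm = c("a:unknown" = 20), sl_log_sd = 0.3,
    n_per_group = c("a:unknown" = 6))
  sets <- simulate_landmarks(cfg, "a", "unknown", 6, seed = 9)
  # sizes vary, shapes do not
  expect_gt(sd(vapply(sets, function(s) centroid_size(s$landmarks_mm),
                      numeric(1))), 0)
  ga <- gpa_align(c(sets, list(fix_landmarks(template_shape(), id = "tpl"))))
  n <- dim(ga$aligned)[1]
  for (i in seq_len(n - 1)) {
    expect_lt(sqrt(sum((ga$aligned[i, , ] - ga$aligned[n, , ])^2)), 1e-8)
  }
})

test_that("group centroid size is recovered within 5% at n = 100", {
  cfg <- landmark_sim_config(
    deformations = list(),
    median_sl_mm = c("a:unknown" = 18), sl_log_sd = 0.12,
    n_per_group = c("a:unknown" = 100))
  sets <- simulate_landmarks(cfg, "a", "unknown", 100, seed = 22)
  sl <- vapply(sets, standard_length, numeric(1))
  # lognormal: mean standard length = median * exp(sd^2 / 2)
  expect_lt(abs(mean(sl) - 18 * exp(0.12^2 / 2)) / 18, 0.05)
})

test_that("study simulation is reproducible and carries its ground truth", {
  preset <- identical_sites_preset(duration_s = 2, frame_rate = 10,
                                   n_per_group = 4)
  s1 <- simulate_study(preset, seed = 77)
  s2 <- simulate_study(preset, seed = 77)
  expect_identical(s1$groups, s2$groups)
  expect_identical(s1$landmarks, s2$landmarks)
  expect_equal(length(s1$groups), 24)
  expect_equal(length(s1$landmarks), 16)
  expect_equal(s1$truth$seed, 77)
  expect_s3_class(s1$truth$preset$site1, "trajectory_sim_config")
})

test_that("simulated outputs round-trip through the real parsers", {
  cfg <- trajectory_sim_config(mean_speed_mm_s = 9, duration_s = 4,
                               frame_rate = 15)
  g <- simulate_group(cfg, "site2", "t3", seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_group_csv(g, tmp)
  back <- read_trajectory_table(tmp, "generic-csv", cfg$arena,
                                site = "site2", tank_id = "t3")
  expect_equal(length(back$trajectories), 6)
  for (i in 1:6) {
    expect_equal(back$trajectories[[i]]$x_px, g$trajectories[[i]]$x_px,
                 tolerance = 1e-9)
  }

  lm_cfg <- landmark_sim_config(
    deformations = list(), median_sl_mm = c("site2:male" = 10),
    n_per_group = c("site2:male" = 5))
  sets <- simulate_landmarks(lm_cfg, "site2", "male", 5, seed = 8)
  tps <- withr::local_tempfile(fileext = ".tps")
  write_tps(sets, tps)
  back_lm <- read_tps(tps, metadata = data.frame(
    id = vapply(sets, function(s) as.character(s$fish_id), character(1)),
    site = "site2", sex = "male"))
  expect_equal(back_lm[[3]]$landmarks_mm, sets[[3]]$landmarks_mm,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back_lm[[1]]$sex, "male")
})

test_that("the reference preset plants the documented site contrasts", {
  # Monte Carlo over a few studies at a fixed master seed: Site 1 faster in
  # nearly all rank-paired tank comparisons, and the cohesion contrast holds
  # in every study
  counts <- vapply(1:5, function(k) {
    study <- simulate_study(reference_study_preset(), seed = 400 + k)
    tanks <- collapse_to_tank_means(behavior_endpoints(study$groups))
    s1 <- tanks[tanks$site == "site1", ]
    s2 <- tanks[tanks$site == "site2", ]
    expect_gt(mean(s1$swim_speed_mm_s), mean(s2$swim_speed_mm_s))
    expect_gt(mean(s1$interindividual_distance_mm),
              mean(s2$interindividual_distance_mm))
    expect_lt(mean(s1$time_in_proximity_s), mean(s2$time_in_proximity_s))
    sum(sort(s1$swim_speed_mm_s) > sort(s2$swim_speed_mm_s))
  }, numeric(1))
  expect_gte(mean(counts), 10.5)
})
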