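# Fixture builders used across test files.

fix_cal <- function(px_per_mm = 10, frame_rate = 30,
                    w = 308, h = 340) {
  calibration_info(px_per_mm, frame_rate, w, h)
}

# group recording from a list of frames x 2 position matrices (pixels)
fix_group <- function(pos_list, cal = fix_cal(), dt = NULL, site = "site1",
                      tank_id = "t1", duration = NULL) {
  if (is.null(dt)) dt <- 1 / cal$frame_rate
  nfr <- nrow(pos_list[[1]])
  times <- (seq_len(nfr) - 1) * dt
  trs <- lapply(seq_along(pos_list), function(i) {
    p <- pos_list[[i]]
    det <- mean(is.finite(p[, 1]) & is.finite(p[, 2]))
    fish_trajectory(paste0("fish", i), times, p[, 1], p[, 2],
                    detection_fraction = det)
  })
  if (is.null(duration)) duration <- nfr * dt
  group_recording(site, tank_id, trs, cal, sample_duration_s = duration)
}

# random walk positions within the arena (pixels), optionally with NA gaps
fix_random_positions <- function(n_frames, cal = fix_cal(), na_frac = 0) {
  w_px <- cal$arena_width_mm * cal$px_per_mm
  h_px <- cal$arena_height_mm * cal$px_per_mm
  p <- cbind(runif(n_frames, 0, w_px), runif(n_frames, 0, h_px))
  if (na_frac > 0) {
    drop <- sample.int(n_frames, round(na_frac * n_frames))
    p[drop, ] <- NA_real_
  }
  p
}

fix_random_group <- function(n_fish = 3, n_frames = 40, cal = fix_cal(),
                             na_frac = 0) {
  fix_group(replicate(n_fish, fix_random_positions(n_frames, cal, na_frac),
                      simplify = FALSE), cal)
}

# landmark set from a 7 x 2 matrix with optional rigid motion + scaling
fix_landmarks <- function(base = template_shape(), rot = 0, scale = 1,
                          shift = c(0, 0), id = "f1", site = "site1",
                          sex = "unknown") {
  rotm <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2,
                 byrow = TRUE)
  landmark_set(id, sweep(scale * base %*% t(rotm), 2, shift, `+`),
               site = site, sex = sex)
}

fix_noisy_landmarks <- function(n, sd = 0.1, seed = 1, base = template_shape(),
                                site = "site1", sex = "unknown") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    fix_landmarks(base + matrix(rnorm(14, sd = sd), 7, 2),
                  rot = runif(1, -pi, pi), scale = exp(rnorm(1, 0, 0.2)),
                  shift = runif(2, -30, 30),
                  id = paste0("spec", i), site = site, sex = sex)
  })
}

# a generic-csv trajectory file for a group recording-like layout
fix_write_csv <- function(path, frames, times, ids, xs, ys) {
  df <- data.frame(frame = frames, time_s = times, fish_id = ids,
                   x_px = xs, y_px = ys)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}
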