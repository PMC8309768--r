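# Independent brute-force oracles. Everything here is written as plain
# per-frame / per-pair loops (or closed forms) so the vectorized package
# implementations are checked against a second, independent derivation.

bf_dist <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# mean over frames (where fish i and all others are valid) of the mean
# distance to the other fish, in mm
bf_iid <- function(group) {
  trs <- group$trajectories
  n <- length(trs)
  nfr <- length(trs[[1]]$times_s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (f in seq_len(nfr)) {
      if (!all(vapply(trs, function(tr) tr$valid[f], logical(1)))) next
      ds <- c()
      for (j in seq_len(n)) {
        if (j == i) next
        ds <- c(ds, bf_dist(trs[[i]]$x_px[f], trs[[i]]$y_px[f],
                            trs[[j]]$x_px[f], trs[[j]]$y_px[f]))
      }
      vals <- c(vals, mean(ds))
    }
    out[i] <- if (length(vals)) mean(vals) / group$calibration$px_per_mm
              else NA_real_
  }
  out
}

bf_nnd <- function(group) {
  trs <- group$trajectories
  n <- length(trs)
  nfr <- length(trs[[1]]$times_s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (f in seq_len(nfr)) {
      if (!trs[[i]]$valid[f]) next
      ds <- c()
      for (j in seq_len(n)) {
        if (j == i || !trs[[j]]$valid[f]) next
        ds <- c(ds, bf_dist(trs[[i]]$x_px[f], trs[[i]]$y_px[f],
                            trs[[j]]$x_px[f], trs[[j]]$y_px[f]))
      }
      if (length(ds)) vals <- c(vals, min(ds))
    }
    out[i] <- if (length(vals)) mean(vals) / group$calibration$px_per_mm
              else NA_real_
  }
  out
}

bf_tip <- function(group, threshold_px) {
  trs <- group$trajectories
  n <- length(trs)
  nfr <- length(trs[[1]]$times_s)
  out <- numeric(n)
  for (i in seq_len(n)) {
    count <- 0L
    for (f in seq_len(nfr)) {
      if (!trs[[i]]$valid[f]) next
      ds <- c()
      for (j in seq_len(n)) {
        if (j == i || !trs[[j]]$valid[f]) next
        ds <- c(ds, bf_dist(trs[[i]]$x_px[f], trs[[i]]$y_px[f],
                            trs[[j]]$x_px[f], trs[[j]]$y_px[f]))
      }
      if (length(ds) && min(ds) <= threshold_px) count <- count + 1L
    }
    out[i] <- count / group$calibration$frame_rate
  }
  out
}

bf_distance_mm <- function(traj, cal) {
  total <- 0
  for (f in 2:length(traj$x_px)) {
    if (traj$valid[f - 1] && traj$valid[f]) {
      total <- total + bf_dist(traj$x_px[f - 1], traj$y_px[f - 1],
                               traj$x_px[f], traj$y_px[f])
    }
  }
  total / cal$px_per_mm
}

bf_motion_s <- function(traj, cal, threshold) {
  count <- 0L
  for (f in 2:length(traj$x_px)) {
    if (traj$valid[f - 1] && traj$valid[f]) {
      sp <- bf_dist(traj$x_px[f - 1], traj$y_px[f - 1],
                    traj$x_px[f], traj$y_px[f]) /
        cal$px_per_mm * cal$frame_rate
      if (sp > threshold) count <- count + 1L
    }
  }
  count / cal$frame_rate
}

bf_exploration <- function(traj, cal, cell) {
  nx <- ceiling(cal$arena_width_mm / cell)
  ny <- ceiling(cal$arena_height_mm / cell)
  seen <- character(0)
  for (f in seq_along(traj$x_px)) {
    if (!traj$valid[f]) next
    x <- traj$x_px[f] / cal$px_per_mm
    y <- traj$y_px[f] / cal$px_per_mm
    ix <- min(max(floor(x / cell), 0), nx - 1)
    iy <- min(max(floor(y / cell), 0), ny - 1)
    seen <- union(seen, paste(ix, iy))
  }
  area <- min(length(seen) * cell^2, cal$arena_width_mm * cal$arena_height_mm)
  list(area_mm2 = area,
       percent = 100 * area / (cal$arena_width_mm * cal$arena_height_mm))
}

# ordinary-Procrustes fixed point: center and unit-scale every configuration,
# then iterate closed-form 2-D rotations onto the running mean. The rotation
# angle comes from the analytic optimum (atan2 of cross/dot sums), not from
# the package's SVD path.
oracle_rotate2d <- function(x, target) {
  num <- sum(x[, 1] * target[, 2] - x[, 2] * target[, 1])
  den <- sum(x[, 1] * target[, 1] + x[, 2] * target[, 2])
  th <- atan2(num, den)
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  x %*% t(rot)
}

oracle_gpa_consensus <- function(lm_list, iters = 400) {
  norm1 <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  confs <- lapply(lm_list, norm1)
  cons <- confs[[1]]
  for (k in seq_len(iters)) {
    confs <- lapply(confs, oracle_rotate2d, target = cons)
    cons <- norm1(Reduce(`+`, confs) / length(confs))
  }
  list(consensus = cons, aligned = lapply(confs, oracle_rotate2d, target = cons))
}

# permutation distribution of the Welch t statistic, two-sided
perm_welch_p <- function(a, b, n_perm, seed = 1) {
  set.seed(seed)
  obs <- abs(welch_t(a, b)$statistic)
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    t_k <- tryCatch(abs(welch_t(pool[idx], pool[-idx])$statistic),
                    error = function(e) Inf)
    if (t_k >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# full 2^n sign enumeration of the signed-rank statistic (average ranks)
enum_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v_obs + 1e-12)
  p_ge <- mean(vs >= v_obs - 1e-12)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# tie-corrected Kruskal-Wallis H from the textbook formula
kw_hand <- function(values, group) {
  n <- length(values)
  r <- rank(values)
  group <- factor(group)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, group, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# expected distance between two independent uniform points in a W x H
# rectangle (closed form)
uniform_rect_expected_distance <- function(w, h) {
  d <- sqrt(w^2 + h^2)
  (w^3 / h^2 + h^3 / w^2 +
     d * (3 - w^2 / h^2 - h^2 / w^2) +
     5 / 2 * (h^2 / w * log((w + d) / h) + w^2 / h * log((h + d) / w))) / 15
}

# vectorized permutation distribution of the Welch t statistic (two-sided),
# for large permutation counts
perm_welch_p_fast <- function(a, b, n_perm, seed = 1) {
  set.seed(seed)
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  welch_stat <- function(idx_mat) {
    xa <- matrix(pool[idx_mat], nrow = na)
    sum_a <- colSums(xa)
    ss_a <- colSums(xa^2)
    sum_b <- sum(pool) - sum_a
    ss_b <- sum(pool^2) - ss_a
    nb <- n - na
    ma <- sum_a / na; mb <- sum_b / nb
    va <- (ss_a - na * ma^2) / (na - 1)
    vb <- (ss_b - nb * mb^2) / (nb - 1)
    (ma - mb) / sqrt(va / na + vb / nb)
  }
  obs <- abs(welch_stat(matrix(seq_len(na), ncol = 1)))
  chunk <- 20000L
  hits <- 0L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    idx <- replicate(m, sample.int(n, na))
    hits <- hits + sum(abs(welch_stat(idx)) >= obs - 1e-12)
    done <- done + m
  }
  (hits + 1) / (n_perm + 1)
}
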