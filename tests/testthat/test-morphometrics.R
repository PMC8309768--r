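test_that("standard length is the mouth-to-caudal distance, rigid invariant", {
  base <- template_shape()
  base[1, ] <- c(0, 0); base[4, ] <- c(22, 0)
  lm <- fix_landmarks(base)
  expect_equal(standard_length(lm), 22)

  rotated <- fix_landmarks(base, rot = 1.1, shift = c(15, -8))
  expect_equal(standard_length(rotated), 22, tolerance = 1e-12)

  degenerate <- base; degenerate[4, ] <- degenerate[1, ]
  expect_warning(sl <- standard_length(fix_landmarks(degenerate)), "coincide")
  expect_equal(sl, 0)
})

test_that("region areas use the shoelace formula on the stated polygons", {
  # shared vertex LM5 at (0,2): anterior quad 1,5,6,7 is a 1 x 2 rectangle
  # (area 2), posterior quad 2,3,4,5 is a 4 x 2 rectangle (area 8)
  lm_mat <- matrix(0, 7, 2)
  lm_mat[1, ] <- c(0, 0)
  lm_mat[2, ] <- c(0, 0); lm_mat[3, ] <- c(4, 0); lm_mat[4, ] <- c(4, 2)
  lm_mat[5, ] <- c(0, 2)
  lm_mat[6, ] <- c(-1, 2); lm_mat[7, ] <- c(-1, 0)
  ra <- region_areas(landmark_set("sq", lm_mat))
  expect_equal(ra$posterior_mm2, 8)
  expect_equal(ra$anterior_mm2, 2)
  expect_equal(ra$ratio, 4)

  # invariant under rigid motion, equivariant under scaling s (areas x s^2)
  tpl <- fix_landmarks(template_shape())
  ra0 <- region_areas(tpl)
  ra_rot <- region_areas(fix_landmarks(template_shape(), rot = 2.2,
                                       shift = c(-4, 9)))
  expect_equal(ra_rot$anterior_mm2, ra0$anterior_mm2, tolerance = 1e-10)
  expect_equal(ra_rot$ratio, ra0$ratio, tolerance = 1e-10)
  ra_s <- region_areas(fix_landmarks(template_shape(), scale = 3))
  expect_equal(ra_s$posterior_mm2, 9 * ra0$posterior_mm2, tolerance = 1e-10)
  expect_equal(ra_s$ratio, ra0$ratio, tolerance = 1e-10)

  # a bow-tie posterior region warns with signed-area diagnostics
  bow <- matrix(0, 7, 2)
  bow[1, ] <- c(0, 0)
  bow[2, ] <- c(0, 0); bow[3, ] <- c(1, 1); bow[4, ] <- c(1, 0)
  bow[5, ] <- c(0, 1)   # 2->3 crosses 4->5: bow tie
  bow[6, ] <- c(-1, 1); bow[7, ] <- c(-1, 0)
  expect_warning(region_areas(landmark_set("bow", bow)), "self-intersecting")
})

test_that("GPA removes rigid motion and scale", {
  base <- template_shape()
  sets <- list(fix_landmarks(base, id = "a"),
               fix_landmarks(base, rot = pi / 2, shift = c(40, -12), id = "b"),
               fix_landmarks(base, scale = 3, id = "c"))
  ga <- gpa_align(sets)
  d_ab <- sqrt(sum((ga$aligned[1, , ] - ga$aligned[2, , ])^2))
  d_ac <- sqrt(sum((ga$aligned[1, , ] - ga$aligned[3, , ])^2))
  expect_lt(d_ab, 1e-10)
  expect_lt(d_ac, 1e-10)
  expect_equal(ga$centroid_sizes,
               c(centroid_size(base), centroid_size(base),
                 3 * centroid_size(base)), tolerance = 1e-10)
  # consensus is centered with unit centroid size
  expect_equal(colMeans(ga$consensus), c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(sum(ga$consensus^2), 1, tolerance = 1e-12)
})

test_that("GPA matches the closed-form pairwise-OPA fixed point", {
  sets <- fix_noisy_landmarks(10, sd = 0.5, seed = 23)
  ga <- gpa_align(sets, project_tangent = FALSE)
  oracle <- oracle_gpa_consensus(lapply(sets, `[[`, "landmarks_mm"))
  # consensus agrees up to a global rotation: align oracle onto ours first
  cons_o <- oracle_rotate2d(oracle$consensus, ga$consensus)
  expect_lt(sqrt(sum((cons_o - ga$consensus)^2)), 1e-8)
})

test_that("GPA residuals decrease monotonically and alignment is idempotent", {
  sets <- fix_noisy_landmarks(8, sd = 0.8, seed = 31)
  ga <- gpa_align(sets, project_tangent = FALSE)
  expect_true(all(diff(ga$rss_trace) <= 1e-12))

  realigned <- gpa_align(lapply(seq_along(sets), function(i) {
    landmark_set(sets[[i]]$fish_id, ga$aligned[i, , ],
                 site = sets[[i]]$site, sex = sets[[i]]$sex)
  }), project_tangent = FALSE)
  # aligning aligned shapes changes nothing beyond tolerance, up to the
  # global rotational indeterminacy of the superimposition
  for (i in seq_along(sets)) {
    ri <- oracle_rotate2d(realigned$aligned[i, , ], ga$aligned[i, , ])
    expect_equal(ri, ga$aligned[i, , ], tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("per-specimen nuisance transforms do not change aligned shapes", {
  sets <- fix_noisy_landmarks(6, sd = 0.4, seed = 41)
  set.seed(42)
  nuisance <- lapply(sets, function(s) {
    fix_landmarks(s$landmarks_mm, rot = runif(1, -pi, pi),
                  scale = exp(runif(1, -1, 1)), shift = runif(2, -100, 100),
                  id = s$fish_id)
  })
  a <- gpa_align(sets)
  b <- gpa_align(nuisance)
  # remove the global rotational ambiguity per specimen set
  for (i in seq_along(sets)) {
    bi <- oracle_rotate2d(b$aligned[i, , ], a$aligned[i, , ])
    expect_equal(bi, a$aligned[i, , ], tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("tangent projection is a sub-1e-4 refinement at realistic variation", {
  # sub-0.1 mm digitizing error on a ~20 mm fish, the scale of tpsDIG use
  sets <- fix_noisy_landmarks(12, sd = 0.05, seed = 51)
  with_proj <- gpa_align(sets, project_tangent = TRUE)
  without <- gpa_align(sets, project_tangent = FALSE)
  expect_lt(max(abs(with_proj$aligned - without$aligned)), 1e-4)
})

test_that("degenerate configurations raise a domain error naming the fish", {
  sets <- fix_noisy_landmarks(3, seed = 61)
  sets[[2]] <- landmark_set("flatfish", matrix(5, 7, 2))
  expect_error(gpa_align(sets), "flatfish")
})

test_that("shape PCA: variance fractions, sign convention, degenerate case", {
  sets <- fix_noisy_landmarks(20, sd = 0.4, seed = 71)
  an <- shape_pca(gpa_align(sets))
  expect_equal(sum(an$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(an$variance_explained) <= 1e-12))
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(an$pc_loadings))) {
    expect_gt(an$pc_loadings[which.max(abs(an$pc_loadings[, k])), k], 0)
  }
  # scores reproduce the centered aligned coordinates
  n <- dim(an$aligned)[1]
  flat <- matrix(an$aligned, nrow = n)
  recon <- an$pc_scores %*% t(an$pc_loadings)
  expect_equal(recon, sweep(flat, 2, colMeans(flat)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # identical specimens: flagged zero-variance
  same <- lapply(1:5, function(i) fix_landmarks(template_shape(),
                                                id = paste0("s", i)))
  an0 <- shape_pca(gpa_align(same))
  expect_true(an0$zero_variance)

  expect_error(shape_pca(gpa_align(fix_noisy_landmarks(2, seed = 1))),
               "at least 3")
})

test_that("PC1 separates two planted shape clusters by sign", {
  set.seed(20210712)
  # a body-depth contrast: dorsal-fin landmark up, ventral landmark down,
  # each by 3 sigma (nearly orthogonal to the size and rotation modes the
  # superimposition removes)
  delta <- matrix(0, 7, 2)
  delta[3, 2] <- 3 * 0.3
  delta[6, 2] <- -3 * 0.3
  g1 <- fix_noisy_landmarks(50, sd = 0.3, seed = 814, site = "a")
  g2 <- fix_noisy_landmarks(50, sd = 0.3, seed = 815,
                            base = template_shape() + delta, site = "b")
  an <- shape_pca(gpa_align(c(g1, g2)))
  pc1 <- an$pc_scores[, 1]
  lab <- rep(c("a", "b"), each = 50)
  acc <- max(mean((pc1 > median(pc1)) == (lab == "a")),
             mean((pc1 > median(pc1)) == (lab == "b")))
  expect_gt(acc, 0.95)
})

test_that("per-group consensus shapes: identity, symmetry, recovery", {
  sets <- fix_noisy_landmarks(9, sd = 0.3, seed = 91)
  an <- gpa_align(sets)
  labels <- c("solo", rep(c("g1", "g2"), 4))
  cons <- consensus_by_group(an, labels)
  expect_equal(cons[["solo"]], an$aligned[1, , ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # two mirror-image deviations around the global consensus average to it
  an2 <- an
  dev <- matrix(0.01 * seq_len(14), 7, 2)
  an2$aligned <- an2$aligned[1:2, , , drop = FALSE]
  an2$aligned[1, , ] <- an$consensus + dev
  an2$aligned[2, , ] <- an$consensus - dev
  an2$info <- an$info[1:2, ]
  cons2 <- consensus_by_group(an2, c("g", "g"))
  expect_equal(cons2[["g"]], an$consensus, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_warning(consensus_by_group(an, factor(labels,
                                               levels = c(unique(labels), "empty"))),
                 "empty")
})

test_that("group mean shapes recover the generator's planted deformation", {
  cfg <- landmark_sim_config(
    deformations = list("a:unknown" = matrix(0, 7, 2),
                        "b:unknown" = {
                          m <- matrix(0, 7, 2); m[4, 1] <- -1.3; m
                        }),
    median_sl_mm = c("a:unknown" = 20, "b:unknown" = 20),
    landmark_noise_sd = 0.12,
    n_per_group = c("a:unknown" = 100, "b:unknown" = 100))
  sa <- simulate_landmarks(cfg, "a", "unknown", 100, seed = 100)
  sb <- simulate_landmarks(cfg, "b", "unknown", 100, seed = 101)
  an <- gpa_align(c(sa, sb))
  cons <- consensus_by_group(an, rep(c("a", "b"), each = 100))
  diffs <- cons[["a"]] - cons[["b"]]
  per_lm <- rowSums(diffs^2)
  # superimposition spreads part of a single-landmark displacement onto the
  # others (it removes the translation/size/rotation components of the
  # planted vector), so the oracle is the analytic projection of the
  # displacement off the similarity modes of the template
  tpl <- template_shape()
  tplc <- sweep(tpl, 2, colMeans(tpl))
  t_hat <- as.vector(tplc) / sqrt(sum(tplc^2))
  r_mat <- cbind(-tplc[, 2], tplc[, 1])
  r_hat <- as.vector(r_mat) / sqrt(sum(r_mat^2))
  e <- matrix(0, 7, 2); e[4, 1] <- -1.3
  ec <- as.vector(sweep(e, 2, colMeans(e)))
  e_shape <- ec - sum(ec * t_hat) * t_hat - sum(ec * r_hat) * r_hat
  e_mat <- matrix(e_shape, 7, 2)
  share_expected <- sum(e_mat[4, ]^2) / sum(e_mat^2)
  expect_equal(unname(which.max(per_lm)), 4L)
  expect_equal(unname(per_lm[4] / sum(per_lm)), share_expected, tolerance = 0.08)
})
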