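#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the size measure removed during Procrustes superimposition.
#'
#' @param lm A k x 2 numeric matrix of landmark coordinates.
#' @return Centroid size, in the units of `lm`.
#' @export
centroid_size <- function(lm) {
  lm <- as.matrix(lm)
  ctr <- colMeans(lm)
  sqrt(sum(sweep(lm, 2L, ctr)^2))
}

#' Standard length
#'
#' Euclidean distance between the mouth landmark (1) and the caudal-fin
#' landmark (4): the anterior-to-posterior body length.
#'
#' @param lm A [landmark_set()].
#' @return Length in mm.
#' @export
standard_length <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  d <- sqrt(sum((lm$landmarks_mm[1L, ] - lm$landmarks_mm[4L, ])^2))
  if (d == 0) warning("standard_length: landmarks 1 and 4 coincide")
  d
}

#' Shoelace (signed polygon) area
#' @noRd
shoelace_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(seq_len(nrow(xy))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

is_simple_quad <- function(xy) {
  # a quadrilateral is simple iff neither diagonal pair of opposite edges cross
  seg_cross <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  !(seg_cross(xy[1, ], xy[2, ], xy[3, ], xy[4, ]) ||
    seg_cross(xy[2, ], xy[3, ], xy[4, ], xy[1, ]))
}

#' Body-region areas and their ratio
#'
#' Absolute shoelace areas of the anterior quadrilateral (landmarks
#' 1, 5, 6, 7: mouth, anterior anal fin, ventral surface, ventral anterior
#' skull) and the posterior quadrilateral (landmarks 2, 3, 4, 5: posterior
#' dorsal skull, anterior dorsal fin, caudal fin, anterior anal fin), on the
#' original mm-scale landmarks, plus their posterior/anterior ratio.
#'
#' @param lm A [landmark_set()].
#' @return A list of class `region_areas` with `anterior_mm2`,
#'   `posterior_mm2`, and `ratio`.
#' @export
region_areas <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  ant_xy <- lm$landmarks_mm[c(1L, 5L, 6L, 7L), , drop = FALSE]
  post_xy <- lm$landmarks_mm[c(2L, 3L, 4L, 5L), , drop = FALSE]
  ant_signed <- shoelace_area(ant_xy)
  post_signed <- shoelace_area(post_xy)
  if (!is_simple_quad(ant_xy) || !is_simple_quad(post_xy)) {
    warning(sprintf(
      "region_areas: self-intersecting region polygon (signed areas: anterior %.4g, posterior %.4g)",
      ant_signed, post_signed))
  }
  ant <- abs(ant_signed)
  post <- abs(post_signed)
  if (ant == 0) {
    stop("region_areas: degenerate anterior region (zero area)", call. = FALSE)
  }
  structure(list(anterior_mm2 = ant, posterior_mm2 = post, ratio = post / ant),
            class = "region_areas")
}

#' Optimal rotation of one configuration onto another
#'
#' Orthogonal-fit solution via SVD of the cross-product matrix; reflections
#' are disallowed (determinant forced positive), since all specimens are
#' photographed in a consistent orientation.
#' @noRd
opa_rotate <- function(x, target) {
  m <- crossprod(x, target)
  sv <- svd(m)
  s <- diag(2L)
  if (det(sv$u %*% t(sv$v)) < 0) s[2L, 2L] <- -1
  x %*% (sv$u %*% s %*% t(sv$v))
}

center_scale <- function(lm) {
  ctr <- sweep(as.matrix(lm), 2L, colMeans(lm))
  cs <- sqrt(sum(ctr^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincident",
                    call. = FALSE)
  ctr / cs
}

#' Generalized Procrustes alignment
#'
#' Superimposes landmark configurations by removing translation (centering),
#' size (scaling to unit centroid size), and rotation (iterative orthogonal
#' fits to the running consensus, reflections disallowed). The consensus is
#' re-centered and re-scaled to unit centroid size each iteration; iteration
#' stops when the consensus root-mean-square change drops below `tol`.
#' Optionally the aligned shapes are orthogonally projected into the tangent
#' space at the consensus; at the shape variation typical of these data the
#' projection changes coordinates by less than 1e-6.
#'
#' @param sets A list of [landmark_set()] objects (at least 2).
#' @param tol Convergence tolerance on the consensus (default 1e-10).
#' @param max_iter Maximum number of rotation sweeps (default 100).
#' @param project_tangent Project aligned shapes into the tangent space at
#'   the consensus (default TRUE).
#' @return An object of class `shape_analysis`: `aligned` (n x 7 x 2 array),
#'   `consensus` (7 x 2), `centroid_sizes` (mm), `info` (data frame of
#'   `fish_id`, `site`, `sex`), `iterations`, `rss_trace` (summed squared
#'   Procrustes residuals per iteration).
#' @export
gpa_align <- function(sets, tol = 1e-10, max_iter = 100,
                      project_tangent = TRUE) {
  if (length(sets) < 2L) stop("gpa_align: need at least 2 landmark sets",
                              call. = FALSE)
  stopifnot(all(vapply(sets, inherits, logical(1), "landmark_set")))
  n <- length(sets)
  sizes <- numeric(n)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    lm <- sets[[i]]$landmarks_mm
    sizes[i] <- centroid_size(lm)
    confs[[i]] <- tryCatch(center_scale(lm), error = function(e) {
      stop("gpa_align: degenerate configuration for fish ",
           as.character(sets[[i]]$fish_id), call. = FALSE)
    })
  }
  consensus <- confs[[1L]]
  rss_trace <- numeric(0)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    confs <- lapply(confs, opa_rotate, target = consensus)
    new_cons <- Reduce(`+`, confs) / n
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    rss_trace[iterations] <- sum(vapply(
      confs, function(cc) sum((cc - new_cons)^2), numeric(1)))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol || iterations >= max_iter) break
  }
  # final rotation pass onto the converged consensus
  confs <- lapply(confs, opa_rotate, target = consensus)
  aligned <- aperm(simplify2array(confs), c(3L, 1L, 2L))
  if (project_tangent) {
    v <- as.vector(consensus)
    v <- v / sqrt(sum(v^2))
    flat <- matrix(aligned, nrow = n)
    proj <- flat - (flat %*% v - 1) %*% t(v)  # remove component along consensus
    aligned <- array(proj, dim = dim(aligned))
  }
  dimnames(aligned) <- list(NULL, landmark_names(), c("x", "y"))
  dimnames(consensus) <- list(landmark_names(), c("x", "y"))
  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = sizes,
         info = landmark_metadata(sets), iterations = iterations,
         rss_trace = rss_trace, tol = tol,
         pc_scores = NULL, variance_explained = NULL, pc_loadings = NULL),
    class = "shape_analysis"
  )
}

#' @export
print.shape_analysis <- function(x, ...) {
  cat(sprintf("<shape_analysis> %d specimens, %d landmarks, %d GPA iterations%s\n",
              dim(x$aligned)[1L], dim(x$aligned)[2L], x$iterations,
              if (!is.null(x$pc_scores)) sprintf(
                ", PC1+PC2 %.2f%% of shape variance",
                100 * sum(x$variance_explained[1:2])) else ""))
  invisible(x)
}

#' Shape principal components
#'
#' Principal-component decomposition of the Procrustes-aligned coordinates
#' flattened to 14-vectors and centered on the mean shape — a relative-warps
#' analysis with uniform weighting. Component signs are fixed by making each
#' loading vector's largest-magnitude entry positive.
#'
#' @param analysis A `shape_analysis` from [gpa_align()].
#' @return The `shape_analysis` with `pc_scores` (n x axes), `pc_loadings`,
#'   and `variance_explained` (descending, summing to 1) filled in. If all
#'   specimens are identical the analysis is flagged with
#'   `zero_variance = TRUE` and the variance fractions are all `NA`.
#' @export
shape_pca <- function(analysis) {
  stopifnot(inherits(analysis, "shape_analysis"))
  n <- dim(analysis$aligned)[1L]
  if (n < 3L) stop("shape_pca: need at least 3 specimens", call. = FALSE)
  flat <- matrix(analysis$aligned, nrow = n)
  ctr <- sweep(flat, 2L, colMeans(flat))
  total_var <- sum(ctr^2)
  if (total_var < 1e-24) {
    analysis$pc_scores <- matrix(0, n, 0L)
    analysis$variance_explained <- NA_real_
    analysis$zero_variance <- TRUE
    return(analysis)
  }
  sv <- svd(ctr)
  keep <- sv$d^2 / sum(sv$d^2) > 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each axis positive
  for (k in seq_len(ncol(v))) {
    big <- which.max(abs(v[, k]))
    if (v[big, k] < 0) {
      v[, k] <- -v[, k]
      u[, k] <- -u[, k]
    }
  }
  analysis$pc_scores <- u %*% diag(d, nrow = length(d))
  analysis$pc_loadings <- v
  analysis$variance_explained <- d^2 / sum(d^2)
  analysis$zero_variance <- FALSE
  analysis
}

#' Per-group consensus shapes
#'
#' Arithmetic mean of the aligned coordinates within each group (site x sex
#' by default), for composite overlay plots.
#'
#' @param analysis A `shape_analysis`.
#' @param labels Factor-like vector of group labels, one per specimen;
#'   defaults to `site:sex` from the analysis metadata.
#' @return Named list of 7 x 2 mean shapes; empty groups are skipped with a
#'   warning.
#' @export
consensus_by_group <- function(analysis, labels = NULL) {
  stopifnot(inherits(analysis, "shape_analysis"))
  if (is.null(labels)) {
    labels <- paste(analysis$info$site, analysis$info$sex, sep = ":")
  }
  n <- dim(analysis$aligned)[1L]
  if (length(labels) != n) {
    stop("consensus_by_group: one label per specimen required", call. = FALSE)
  }
  if (!is.factor(labels)) labels <- factor(labels)
  out <- list()
  for (g in levels(labels)) {
    idx <- which(labels == g)
    if (!length(idx)) {
      warning("consensus_by_group: empty group ", g, " skipped")
      next
    }
    m <- apply(analysis$aligned[idx, , , drop = FALSE], c(2L, 3L), mean)
    dimnames(m) <- dimnames(analysis$consensus)
    out[[g]] <- m
  }
  out
}
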