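#' The stylized 7-landmark template shape
#'
#' A stylized zebrafish landmark configuration (20 mm standard length, y up)
#' used as the base shape of the landmark generator. It is a drawing
#' convenience with the right qualitative geometry — posterior region larger
#' than anterior, ratio about 1.57 — not a measured biological consensus.
#'
#' @return A 7 x 2 matrix of template coordinates in mm.
#' @export
template_shape <- function() {
  path <- system.file("extdata", "template_shape_7lm.tsv",
                      package = "shoalmorph", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("x_mm", "y_mm")])
  dimnames(m) <- list(df$landmark, c("x", "y"))
  m
}

#' Landmark simulation configuration
#'
#' Generates specimens as `template + group deformation + isotropic noise`,
#' then applies the nuisance transforms a Procrustes analysis must undo: a
#' uniform scaling to a lognormal standard-length draw, a random rotation,
#' and a random translation. Deformation fields and the noise sd are in the
#' mm units of the 20 mm template.
#'
#' @param template 7 x 2 base shape (default [template_shape()]).
#' @param deformations Named list of 7 x 2 displacement matrices, keyed by
#'   `"site:sex"`; groups without an entry get zero deformation.
#' @param median_sl_mm Named numeric vector of median standard lengths (mm)
#'   per `"site:sex"` group.
#' @param sl_log_sd Lognormal sd of the standard-length draws (default 0.12).
#' @param landmark_noise_sd Isotropic landmark noise sd, template mm
#'   (default 0.12; well below a fifth of the smallest landmark spacing).
#' @param n_per_group Named integer vector of specimens per `"site:sex"`
#'   group.
#' @return An object of class `landmark_sim_config`.
#' @export
landmark_sim_config <- function(template = template_shape(),
                                deformations = list(),
                                median_sl_mm, sl_log_sd = 0.12,
                                landmark_noise_sd = 0.12,
                                n_per_group) {
  template <- as.matrix(template)
  if (nrow(template) != 7L || ncol(template) != 2L ||
      centroid_size(template) < 1e-9) {
    stop("landmark_sim_config: template must be a non-degenerate 7 x 2 matrix",
         call. = FALSE)
  }
  min_spacing <- min(dist(template))
  if (landmark_noise_sd >= 0.2 * min_spacing) {
    stop("landmark_sim_config: noise sd too large relative to landmark spacing",
         call. = FALSE)
  }
  if (landmark_noise_sd < 0) {
    stop("landmark_sim_config: noise sd must be >= 0", call. = FALSE)
  }
  structure(
    list(template = template, deformations = deformations,
         median_sl_mm = median_sl_mm, sl_log_sd = sl_log_sd,
         landmark_noise_sd = landmark_noise_sd, n_per_group = n_per_group),
    class = "landmark_sim_config")
}

group_key <- function(site, sex) paste(site, sex, sep = ":")

#' Simulate landmark sets for one site x sex group
#'
#' @param cfg A [landmark_sim_config()].
#' @param site,sex Group labels (`cfg$median_sl_mm` must carry the
#'   `"site:sex"` key).
#' @param n Number of specimens.
#' @param seed Integer seed.
#' @param id_prefix Prefix for specimen ids.
#' @return List of [landmark_set()] objects.
#' @export
simulate_landmarks <- function(cfg, site, sex, n, seed,
                               id_prefix = NULL) {
  stopifnot(inherits(cfg, "landmark_sim_config"))
  key <- group_key(site, sex)
  if (!key %in% names(cfg$median_sl_mm)) {
    stop("simulate_landmarks: no size entry for group ", key, call. = FALSE)
  }
  defo <- cfg$deformations[[key]]
  if (is.null(defo)) defo <- matrix(0, 7L, 2L)
  base <- cfg$template + defo
  template_sl <- sqrt(sum((cfg$template[1L, ] - cfg$template[4L, ])^2))
  if (is.null(id_prefix)) id_prefix <- gsub("[^a-z0-9]", "", tolower(key))

  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    shape <- base + matrix(rnorm(14L, sd = cfg$landmark_noise_sd), 7L, 2L)
    sl <- cfg$median_sl_mm[[key]] * exp(rnorm(1L, 0, cfg$sl_log_sd))
    s <- sl / template_sl
    th <- runif(1L, -pi, pi)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    shift <- runif(2L, -50, 50)
    xy <- sweep(s * shape %*% rot, 2L, shift, `+`)
    out[[i]] <- landmark_set(sprintf("%s_%03d", id_prefix, i), xy,
                             site = site, sex = sex)
  }
  out
}
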