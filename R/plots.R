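#' Composite consensus-shape overlay
#'
#' Overlays the per-group mean shapes (Procrustes units) with the landmark
#' polygon drawn through the digitizing order, one color per group.
#'
#' @param cons Named list of 7 x 2 mean shapes from [consensus_by_group()].
#' @param path PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_consensus_overlay <- function(cons, path) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(max(length(cons), 2L), "Dark 3")
  rng <- range(unlist(cons))
  plot(NA, xlim = rng, ylim = rng, asp = 1, xlab = "x (Procrustes units)",
       ylab = "y (Procrustes units)", main = "Group consensus shapes")
  outline <- c(1, 2, 3, 4, 5, 6, 7, 1)
  for (i in seq_along(cons)) {
    m <- cons[[i]]
    graphics::lines(m[outline, 1], m[outline, 2], col = cols[i], lwd = 2)
    graphics::points(m[, 1], m[, 2], col = cols[i], pch = 19)
  }
  graphics::legend("topright", legend = names(cons), col = cols[seq_along(cons)],
                   lwd = 2, bty = "n")
  invisible(path)
}

#' Boxplot of the posterior/anterior area ratio by group
#'
#' @param endpoints Specimen table from [morphometric_endpoints()].
#' @param path PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_ratio_boxplot <- function(endpoints, path) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  grp <- paste(endpoints$site, endpoints$sex, sep = ":")
  graphics::boxplot(endpoints$area_ratio ~ grp,
                    xlab = "", ylab = "posterior / anterior area ratio",
                    main = "Body-region size ratio by population and sex")
  graphics::stripchart(endpoints$area_ratio ~ grp, vertical = TRUE,
                       method = "jitter", add = TRUE, pch = 1,
                       col = grDevices::adjustcolor("black", 0.4))
  invisible(path)
}

#' Boxplots of tank-mean behavioral endpoints by site
#'
#' @param tank_table Tank-level [endpoint_table()].
#' @param path PNG output path.
#' @return Invisibly, `path`.
#' @export
plot_behavior <- function(tank_table, path) {
  eps <- behavioral_endpoint_names()
  grDevices::png(path, width = 1400, height = 800, res = 120)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(2, 4), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (ep in eps) {
    graphics::boxplot(tank_table[[ep]] ~ tank_table$site, xlab = "",
                      ylab = ep, main = ep, cex.main = 0.8)
  }
  invisible(path)
}
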