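# Scalp topography of band-power differences between workload conditions.
#
# Per channel and band, normalized coefficients are averaged within each
# condition over every trial of every participant; the map shows the
# decibel ratio 10*log10(HCL/LCL) (low-load condition as baseline), with
# channels below a display threshold (0.2 dB by default) rendered neutral.

#' Per-channel condition means and dB differences
#'
#' @param features Labeled per-epoch band-power tibble from
#'   [band_power_features()] (both conditions must be present).
#' @param bands Band names, default the four canonical bands.
#' @return A `cond_band_means` tibble: one row per channel x band with
#'   `lcl_mean`, `hcl_mean` and `db_difference = 10*log10(hcl/lcl)`.
#' @export
condition_band_means <- function(features, bands = band_edges()$band) {
  stopifnot(is.data.frame(features))
  if (!all(condition_levels %in% unique(features$condition))) {
    abort("both LCL and HCL epochs are required.")
  }
  id_cols <- c("subject", "session", "trial", "epoch_index", "condition",
               "label", "t_start")
  fcols <- setdiff(names(features), id_cols)
  long <- tidyr::pivot_longer(
    features[, c("condition", fcols)], dplyr::all_of(fcols),
    names_to = "feature", values_to = "value"
  )
  parts <- regmatches(long$feature,
                      regexpr("_(?=[^_]+$)", long$feature, perl = TRUE),
                      invert = TRUE)
  long$channel <- vapply(parts, `[`, character(1), 1)
  long$band <- vapply(parts, `[`, character(1), 2)
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$channel, .data$band, .data$condition),
    mean = mean(.data$value), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "condition",
                             values_from = "mean")
  out <- tibble(
    channel = wide$channel, band = wide$band,
    lcl_mean = wide$LCL, hcl_mean = wide$HCL,
    db_difference = 10 * log10(wide$HCL / wide$LCL)
  )
  out$band <- factor(out$band, levels = bands)
  out <- dplyr::arrange(out, .data$band, .data$channel)
  class(out) <- c("cond_band_means", class(out))
  out
}

# thin-plate spline interpolation from scattered electrode values to a grid
tps_interpolate <- function(x, y, v, gx, gy) {
  n <- length(x)
  rbf <- function(r2) {
    out <- numeric(length(r2))
    pos <- r2 > 0
    out[pos] <- 0.5 * r2[pos] * log(r2[pos])
    out
  }
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- matrix(rbf(d2), n, n)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, c(v, 0, 0, 0))
  g2 <- outer(gx, x, "-")^2 + outer(gy, y, "-")^2
  G <- matrix(rbf(g2), length(gx), n)
  drop(G %*% coef[1:n] + coef[n + 1] + coef[n + 2] * gx + coef[n + 3] * gy)
}

#' Grid data for scalp difference maps
#'
#' Applies the display mask (channels with `|dB| <= threshold_db` are set
#' to zero, the neutral colour) and interpolates the masked per-channel
#' values over the head disk with a thin-plate spline.
#'
#' @param means A `cond_band_means` tibble.
#' @param threshold_db Display threshold in dB (default 0.2). Raising it
#'   can only mask more channels, never fewer.
#' @param grid_n Interpolation grid resolution per axis.
#' @return A list with `grid` (tibble `x`, `y`, `band`, `db` clipped to the
#'   head disk) and `electrodes` (projected positions with masked dB
#'   values and a `shown` flag).
#' @export
scalp_map_data <- function(means, threshold_db = 0.2, grid_n = 67) {
  proj <- project_montage()
  elec <- dplyr::inner_join(means, proj[, c("channel", "x", "y")],
                            by = "channel")
  elec$shown <- abs(elec$db_difference) > threshold_db
  elec$db_masked <- ifelse(elec$shown, elec$db_difference, 0)
  gx <- seq(-1, 1, length.out = grid_n)
  grid_xy <- tidyr::expand_grid(x = gx, y = gx)
  grid_xy <- grid_xy[grid_xy$x^2 + grid_xy$y^2 <= 1, ]
  grids <- purrr::map(split(elec, elec$band, drop = TRUE), function(e) {
    g <- grid_xy
    g$db <- tps_interpolate(e$x, e$y, e$db_masked, grid_xy$x, grid_xy$y)
    g$band <- e$band[1]
    g
  })
  list(grid = dplyr::bind_rows(grids), electrodes = elec)
}

#' Plot scalp topographic difference maps
#'
#' One map per band on a diverging scale: red marks increased oscillation
#' activity under high load, blue suppression, neutral green channels
#' below the dB threshold.
#'
#' @inheritParams scalp_map_data
#' @return A ggplot faceted by band.
#' @export
plot_scalp_maps <- function(means, threshold_db = 0.2, grid_n = 67) {
  dat <- scalp_map_data(means, threshold_db, grid_n)
  lim <- max(abs(dat$grid$db), 0.3)
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 181))
  circ$x <- cos(circ$theta)
  circ$y <- sin(circ$theta)
  nose <- tibble(x = c(-0.08, 0, 0.08), y = c(0.995, 1.08, 0.995))
  ggplot2::ggplot(dat$grid, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$db)) +
    ggplot2::geom_path(data = circ, linewidth = 0.4) +
    ggplot2::geom_path(data = nose, linewidth = 0.4) +
    ggplot2::geom_point(data = dat$electrodes, size = 0.6) +
    ggplot2::facet_wrap(~band, nrow = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#d9f0d3",
                                  high = "#b2182b", limits = c(-lim, lim),
                                  name = "dB (HCL vs LCL)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' @export
autoplot.cond_band_means <- function(object, threshold_db = 0.2, ...) {
  plot_scalp_maps(object, threshold_db = threshold_db)
}

#' Render scalp maps to image files
#'
#' Writes one PNG per band plus a CSV of per-channel dB differences.
#'
#' @inheritParams scalp_map_data
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
render_scalp_maps <- function(means, dir, threshold_db = 0.2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (b in levels(droplevels(means$band))) {
    p <- plot_scalp_maps(means[means$band == b, ], threshold_db)
    path <- file.path(dir, sprintf("topo_%s.png", b))
    ggplot2::ggsave(path, p, width = 4, height = 4.6, dpi = 120)
    paths <- c(paths, path)
  }
  csv <- file.path(dir, "channel_db.csv")
  readr::write_csv(as_tibble(means), csv, progress = FALSE)
  invisible(c(paths, csv))
}
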