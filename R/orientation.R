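#' Accumulate (theta, depth) samples into a population heat map
#'
#' Bins are half-open `[lo, hi)` with the last bin closed, uniform in both
#' dimensions. Internal state keeps raw counts (not probabilities) so count
#' conservation is exact; normalization happens only at plotting/export time.
#'
#' @param samples data.frame with `theta` (degrees) and `depth` (nm) columns,
#'   e.g. from [orientation_samples()]. May be empty.
#' @param theta_bin Bin width in degrees (default 5).
#' @param depth_bin Bin width in nm (default 0.05).
#' @param depth_max Upper edge of the depth axis; defaults to the smallest
#'   multiple of `depth_bin` covering the samples.
#' @return Object of class `heatmap2d`: `theta_edges`, `depth_edges`,
#'   `counts` (theta bins x depth bins), `n_samples`.
#' @export
accumulate_heatmap <- function(samples, theta_bin = 5, depth_bin = 0.05,
                               depth_max = NULL) {
  stopifnot(theta_bin > 0, depth_bin > 0)
  theta <- samples$theta
  depth <- samples$depth
  if (length(theta) && (any(theta < 0 | theta > 180) || any(depth < 0))) {
    stop("samples outside theta in [0,180] / depth >= 0", call. = FALSE)
  }
  nt <- ceiling(180 / theta_bin)
  if (is.null(depth_max)) {
    depth_max <- if (length(depth)) max(depth_bin,
                                        ceiling(max(depth) / depth_bin) *
                                          depth_bin) else depth_bin
  }
  nd <- ceiling(depth_max / depth_bin)
  theta_edges <- (0:nt) * theta_bin
  depth_edges <- (0:nd) * depth_bin
  counts <- matrix(0L, nrow = nt, ncol = nd)
  if (length(theta)) {
    if (any(depth > depth_edges[nd + 1L])) {
      stop("depth samples exceed depth_max", call. = FALSE)
    }
    ti <- pmin(floor(theta / theta_bin) + 1L, nt)
    di <- pmin(floor(depth / depth_bin) + 1L, nd)
    tab <- tabulate((di - 1L) * nt + ti, nbins = nt * nd)
    counts <- matrix(as.integer(tab), nrow = nt, ncol = nd)
  }
  structure(list(theta_edges = theta_edges, depth_edges = depth_edges,
                 counts = counts, n_samples = length(theta)),
            class = "heatmap2d")
}

#' @export
print.heatmap2d <- function(x, ...) {
  cat("heatmap2d: ", nrow(x$counts), " theta bins x ", ncol(x$counts),
      " depth bins, ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Mode (main population) of a heat map
#'
#' Center of the maximal-count cell. Ties are broken deterministically toward
#' the smallest theta, then the smallest depth.
#'
#' @param map A `heatmap2d`.
#' @return Named numeric vector `c(theta = , depth = )` (bin centers).
#' @export
find_mode <- function(map) {
  stopifnot(inherits(map, "heatmap2d"))
  if (map$n_samples == 0L) stop("empty heat map has no mode", call. = FALSE)
  hits <- which(map$counts == max(map$counts), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  ti <- hits[1L, 1L]
  di <- hits[1L, 2L]
  c(theta = (map$theta_edges[ti] + map$theta_edges[ti + 1L]) / 2,
    depth = (map$depth_edges[di] + map$depth_edges[di + 1L]) / 2)
}

#' Classify a candidate's membrane orientation from its heat map
#'
#' The verdict is driven by the mode (main population) cell, mirroring how
#' the reference populations are read: a candidate is `correct` when the mode
#' sits at small tilt and shallow hydroxy position (HMI-like: mode theta <=
#' `theta_ok` and mode depth >= `depth_ok`), `incorrect` when the mode is
#' flipped and buried (PYR-like: mode theta >= `theta_bad` and mode depth <=
#' `depth_bad`), and `ambiguous` otherwise. The minority population on the
#' opposite side of theta = 90 degrees from the mode is reported as a
#' fraction, not penalized.
#'
#' @param map A `heatmap2d`.
#' @param theta_ok,depth_ok,theta_bad,depth_bad Classification thresholds
#'   (degrees / nm). Defaults 60, 1.4, 120, 1.2; must satisfy
#'   `theta_ok < theta_bad`.
#' @return Object of class `orientation_verdict`: `mode_theta`, `mode_depth`,
#'   `label`, `secondary_population_fraction`, `thresholds`.
#' @export
classify_orientation <- function(map, theta_ok = 60, depth_ok = 1.4,
                                 theta_bad = 120, depth_bad = 1.2) {
  if (theta_ok >= theta_bad) {
    stop("non-monotone thresholds: theta_ok must be < theta_bad",
         call. = FALSE)
  }
  mode <- find_mode(map)
  label <- if (mode[["theta"]] <= theta_ok && mode[["depth"]] >= depth_ok) {
    "correct"
  } else if (mode[["theta"]] >= theta_bad && mode[["depth"]] <= depth_bad) {
    "incorrect"
  } else {
    "ambiguous"
  }
  centers <- (map$theta_edges[-1L] + map$theta_edges[-length(map$theta_edges)]) / 2
  opposite <- if (mode[["theta"]] <= 90) centers > 90 else centers < 90
  frac <- sum(map$counts[opposite, , drop = FALSE]) / map$n_samples
  structure(list(mode_theta = mode[["theta"]], mode_depth = mode[["depth"]],
                 label = label, secondary_population_fraction = frac,
                 thresholds = c(theta_ok = theta_ok, depth_ok = depth_ok,
                                theta_bad = theta_bad, depth_bad = depth_bad)),
            class = "orientation_verdict")
}

#' @export
print.orientation_verdict <- function(x, ...) {
  cat("orientation verdict: ", x$label, " (mode theta = ",
      round(x$mode_theta, 1), " deg, mode depth = ", round(x$mode_depth, 2),
      " nm, secondary population ",
      round(100 * x$secondary_population_fraction, 1), "%)\n", sep = "")
  invisible(x)
}

#' Export a heat map as a long-format data.frame / CSV
#'
#' @param map A `heatmap2d`.
#' @param path Optional CSV path; if given, the table is written there.
#' @param normalize If `TRUE`, add a `probability` column
#'   (counts / n_samples).
#' @return data.frame with `theta_center`, `depth_center`, `count` (and
#'   `probability`), invisibly if written.
#' @export
heatmap_table <- function(map, path = NULL, normalize = TRUE) {
  tc <- (map$theta_edges[-1L] + map$theta_edges[-length(map$theta_edges)]) / 2
  dc <- (map$depth_edges[-1L] + map$depth_edges[-length(map$depth_edges)]) / 2
  df <- data.frame(theta_center = rep(tc, times = length(dc)),
                   depth_center = rep(dc, each = length(tc)),
                   count = as.integer(map$counts))
  if (normalize && map$n_samples > 0L) {
    df$probability <- df$count / map$n_samples
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Plot a tilt-angle/depth population heat map
#'
#' @param map A `heatmap2d`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(map, title = "Orientation-distance population") {
  df <- heatmap_table(map, normalize = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta_center,
                                   y = .data$depth_center,
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(theta ~ "(degrees)"),
                  y = "OH distance from bilayer center (nm)",
                  fill = "count", title = title) +
    ggplot2::theme_minimal()
}
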