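AMU_PER_NM3_TO_KG_PER_M3 <- 1.66053906660

#' Partial mass-density profile along the membrane normal
#'
#' Every frame is recentered so the lipid (reference) center of mass sits at
#' z = 0, removing bilayer drift; atom masses of the selection are then
#' accumulated into signed-z bins by minimum image and converted to
#' kg m^-3 using the lateral box area times the bin width, averaged over
#' frames. The bin grid spans at least `[-box_z/2, +box_z/2]` so every atom
#' lands in a bin and mass is conserved exactly.
#'
#' @param traj A [trajectory()] with a constant box.
#' @param group Integer atom indices of the profiled selection (may be
#'   empty, giving an all-zero profile).
#' @param bin_width Bin width in nm (default 0.1); must not exceed the box
#'   height.
#' @param reference Integer atom indices of the lipid group used for
#'   per-frame recentering.
#' @param label Group label stored in the profile.
#' @return Object of class `density_profile`: `bin_centers` (signed nm,
#'   relative to bilayer COM), `density` (kg m^-3), `label`, `n_frames`,
#'   `bin_width`, `area` (nm^2).
#' @export
partial_density <- function(traj, group, bin_width = 0.1, reference,
                            label = "group") {
  stopifnot(bin_width > 0, length(reference) >= 1L)
  box <- traj$frames[[1L]]$box
  if (bin_width > box[3L]) {
    stop("bin width exceeds the box height", call. = FALSE)
  }
  n_half <- ceiling(box[3L] / 2 / bin_width)
  nb <- 2L * n_half
  edges <- (seq_len(nb + 1L) - 1L - n_half) * bin_width
  acc <- numeric(nb)
  masses <- traj$atoms$mass
  nf <- length(traj$frames)
  for (fr in traj$frames) {
    if (max(abs(fr$box - box)) > 1e-9) {
      stop("partial_density requires a constant box across frames",
           call. = FALSE)
    }
    if (length(group) == 0L) next
    mem <- membrane_frame(fr, reference, masses)
    dz <- minimum_image(fr$coords[group, 3L] - mem$z_center, box[3L])
    bin <- pmin(pmax(floor(dz / bin_width) + n_half + 1L, 1L), nb)
    acc <- acc + vapply(split(masses[group], factor(bin, levels = seq_len(nb))),
                        sum, numeric(1))
  }
  area <- box[1L] * box[2L]
  density <- acc * AMU_PER_NM3_TO_KG_PER_M3 / (area * bin_width * nf)
  structure(list(bin_centers = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                 density = unname(density), label = label, n_frames = nf,
                 bin_width = bin_width, area = area),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("density profile '", x$label, "': ", length(x$density), " bins of ",
      x$bin_width, " nm, ", x$n_frames, " frames, peak ",
      round(max(x$density), 1), " kg m^-3\n", sep = "")
  invisible(x)
}

#' Total group mass implied by a density profile
#'
#' Integral of the profile times the lateral area, converted back to amu.
#' For an exact binning this reproduces the summed atomic mass of the group.
#'
#' @param profile A `density_profile`.
#' @return Mass in amu.
#' @export
profile_mass <- function(profile) {
  sum(profile$density) * profile$area * profile$bin_width /
    AMU_PER_NM3_TO_KG_PER_M3
}

#' Locate the lipid-water interface from density profiles
#'
#' Per leaflet, the interface is the z where the water and lipid densities
#' cross: the outermost sign change of (water - lipid), refined by linear
#' interpolation between bin centers.
#'
#' @param water,lipid `density_profile` objects on the same binning.
#' @return Named numeric vector `c(lower = , upper = )`, signed nm.
#' @export
locate_interface <- function(water, lipid) {
  if (length(water$bin_centers) != length(lipid$bin_centers) ||
      max(abs(water$bin_centers - lipid$bin_centers)) > 1e-9) {
    stop("profiles must share one binning", call. = FALSE)
  }
  z <- water$bin_centers
  d <- water$density - lipid$density
  crossing_z <- function(i) {
    if (d[i] == 0) return(z[i])
    z[i] + (z[i + 1L] - z[i]) * d[i] / (d[i] - d[i + 1L])
  }
  find_side <- function(side) {
    idx <- if (side == "upper") which(z > 0) else which(z < 0)
    idx <- idx[idx < length(z)]
    # a genuine sign change; an exact zero counts only when flanked by
    # opposite signs (flat zero stretches are not interfaces)
    is_cross <- d[idx] * d[idx + 1L] < 0 |
      (d[idx] == 0 & idx > 1L & d[pmax(idx - 1L, 1L)] * d[idx + 1L] < 0)
    cross <- idx[is_cross]
    if (!length(cross)) {
      stop("no lipid-water interface found in the ", side, " half-space",
           call. = FALSE)
    }
    pick <- if (side == "upper") max(cross) else min(cross)
    crossing_z(pick)
  }
  c(lower = find_side("lower"), upper = find_side("upper"))
}

#' Export density profiles as a long-format data.frame / CSV
#'
#' @param profiles A `density_profile` or list of them.
#' @param path Optional CSV path.
#' @return data.frame with `bin_center`, `density`, `group`.
#' @export
density_table <- function(profiles, path = NULL) {
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(bin_center = p$bin_centers, density = p$density,
               group = p$label, stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Plot partial density profiles with the lipid-water interface
#'
#' @param profiles List of `density_profile` objects.
#' @param interface Optional result of [locate_interface()]; drawn as
#'   vertical lines.
#' @return A ggplot object.
#' @export
plot_density_profiles <- function(profiles, interface = NULL) {
  df <- density_table(profiles)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center,
                                        y = .data$density,
                                        colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z relative to bilayer COM (nm)",
                  y = expression(density ~ (kg ~ m^-3))) +
    ggplot2::theme_minimal()
  if (!is.null(interface)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(interface),
                                 colour = "blue", linetype = 2)
  }
  p
}
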