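#' Settings for dot-surface (Shrake-Rupley) SASA
#'
#' @param probe_radius Solvent probe radius in nm (default 0.14, water).
#' @param n_dots Dots per atomic sphere (default 960, >= 24). Dots are placed
#'   on a deterministic Fibonacci spiral lattice, so areas are seed-free and
#'   exactly reproducible; the area resolution of a single dot is
#'   `4*pi*(r+probe)^2 / n_dots`.
#' @param radii_source Label of the vdW radii table in use (metadata only).
#' @return Object of class `sasa_settings`.
#' @export
sasa_settings <- function(probe_radius = 0.14, n_dots = 960L,
                          radii_source = "bondi") {
  stopifnot(probe_radius >= 0, n_dots >= 24L)
  structure(list(probe_radius = probe_radius, n_dots = as.integer(n_dots),
                 radii_source = radii_source), class = "sasa_settings")
}

#' Quasi-uniform unit-sphere dots (Fibonacci spiral lattice)
#'
#' @param n Number of dots.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area of selected atoms
#'
#' Each atom's accessible sphere (vdW radius + probe) is sampled with a
#' deterministic dot lattice; the accessible area is the sphere area times
#' the fraction of dots not inside any occluder's expanded sphere, with
#' minimum-image distances in the periodic box. An atom never occludes
#' itself.
#'
#' @param frame A trajectory frame with whole (unwrapped) molecule
#'   coordinates for the atoms of interest.
#' @param atoms_idx Integer indices of the atoms whose area is computed.
#' @param occluders_idx Integer indices of occluding atoms (typically every
#'   atom in the system; the atom itself is skipped automatically).
#' @param radii Numeric vdW radii (nm) for the full atom table.
#' @param settings A [sasa_settings()].
#' @return Named numeric vector of per-atom areas in nm^2 (names = indices).
#' @export
shrake_rupley <- function(frame, atoms_idx, occluders_idx, radii,
                          settings = sasa_settings()) {
  if (anyNA(radii[c(atoms_idx, occluders_idx)])) {
    bad <- c(atoms_idx, occluders_idx)[is.na(radii[c(atoms_idx,
                                                     occluders_idx)])][1L]
    stop("missing vdW radius for atom ", bad, call. = FALSE)
  }
  dots <- fibonacci_sphere(settings$n_dots)
  box <- frame$box
  probe <- settings$probe_radius
  occ_pos <- frame$coords[occluders_idx, , drop = FALSE]
  occ_rad <- radii[occluders_idx] + probe
  areas <- numeric(length(atoms_idx))
  for (a in seq_along(atoms_idx)) {
    i <- atoms_idx[a]
    ri <- radii[i] + probe
    ci <- frame$coords[i, ]
    if (nrow(occ_pos) == 0L) {
      areas[a] <- 4 * pi * ri^2
      next
    }
    disp <- minimum_image(occ_pos - matrix(ci, nrow(occ_pos), 3L,
                                           byrow = TRUE), box)
    d2 <- rowSums(disp^2)
    cand <- which(d2 < (ri + occ_rad)^2 & occluders_idx != i & d2 > 1e-12)
    if (!length(cand)) {
      areas[a] <- 4 * pi * ri^2
      next
    }
    pts <- dots * ri
    exposed <- rep(TRUE, settings$n_dots)
    for (j in cand) {
      dd <- pts - matrix(disp[j, ], settings$n_dots, 3L, byrow = TRUE)
      exposed <- exposed & rowSums(dd^2) >= occ_rad[j]^2
      if (!any(exposed)) break
    }
    areas[a] <- 4 * pi * ri^2 * mean(exposed)
  }
  names(areas) <- atoms_idx
  areas
}

#' Per-molecule group SASA with block statistics
#'
#' For every frame and ligand copy, the summed Shrake-Rupley area of the
#' chosen group's atoms is computed with (by default) every other atom of
#' the system as an occluder — lipids, water, ions, the other ligand copies
#' and the rest of the copy's own molecule — so the value measures how
#' available the group is in the membrane context. The per-frame mean over
#' copies is block-averaged.
#'
#' @param traj A [trajectory()].
#' @param spec A [ligand_spec()].
#' @param group "oh" or "oono".
#' @param settings A [sasa_settings()].
#' @param n_blocks Number of time blocks (default 5).
#' @param occluders "all" (default) for every system atom, or an integer
#'   vector of occluder indices (e.g. excluding other ligand copies).
#' @param stride Analyze every `stride`-th frame (default 1). Block
#'   statistics are computed on the strided series.
#' @return A [block_average()]; attribute `per_frame` holds the per-frame
#'   per-molecule areas (nm^2).
#' @export
group_sasa_block_stats <- function(traj, spec, group = c("oh", "oono"),
                                   settings = sasa_settings(),
                                   n_blocks = 5L, occluders = "all",
                                   stride = 1L) {
  group <- match.arg(group)
  atoms <- traj$atoms
  radii <- atoms$vdw_radius
  gidx <- lapply(seq_len(spec$n_copies), function(k) {
    resolve_ligand_atoms(atoms, spec, k, group)
  })
  frames <- traj$frames[seq(1L, length(traj$frames), by = stride)]
  per_frame <- numeric(length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    vals <- vapply(seq_len(spec$n_copies), function(k) {
      occ <- if (identical(occluders, "all")) {
        seq_len(nrow(atoms))
      } else {
        occluders
      }
      sum(shrake_rupley(fr, gidx[[k]], occ, radii, settings))
    }, numeric(1))
    per_frame[i] <- mean(vals)
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  dt <- if (length(times) > 1L) stats::median(diff(times)) else NA_real_
  ba <- block_average(per_frame, n_blocks, frame_dt = dt)
  attr(ba, "per_frame") <- per_frame
  ba
}
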