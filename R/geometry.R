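#' Minimum-image displacement
#'
#' Folds displacements into `[-box/2, box/2)` per component for an
#' orthorhombic periodic box.
#'
#' @param d Numeric vector, or n x 3 matrix of displacements (nm).
#' @param box Scalar box edge (for vector `d`) or length-3 edge vector (nm).
#' @return Folded displacement(s), same shape as `d`.
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    stopifnot(ncol(d) == length(box))
    for (k in seq_along(box)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}

#' Unwrap a molecule across periodic boundaries
#'
#' Breadth-first traversal of the covalent bond graph from a root atom,
#' placing each atom at its minimum-image position relative to its already
#' placed bonded neighbour. The root atom is left unchanged, so the result is
#' translationally consistent with the input.
#'
#' @param frame A trajectory frame (list with `box`, `coords`).
#' @param molecule Integer vector of global atom indices of one molecule.
#' @param bonds Two-column integer matrix of bonded global index pairs; the
#'   graph restricted to `molecule` must be connected.
#' @return Matrix (length(molecule) x 3) of unwrapped coordinates, rows in
#'   the order of `molecule`, row names the indices.
#' @export
make_whole <- function(frame, molecule, bonds) {
  n <- length(molecule)
  stopifnot(n >= 1L, is.matrix(bonds) || n == 1L)
  coords <- frame$coords[molecule, , drop = FALSE]
  if (n == 1L) {
    rownames(coords) <- molecule
    return(coords)
  }
  b1 <- match(bonds[, 1L], molecule)
  b2 <- match(bonds[, 2L], molecule)
  keep <- !is.na(b1) & !is.na(b2)
  adj <- vector("list", n)
  for (e in which(keep)) {
    adj[[b1[e]]] <- c(adj[[b1[e]]], b2[e])
    adj[[b2[e]]] <- c(adj[[b2[e]]], b1[e])
  }
  out <- coords
  visited <- logical(n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (!visited[nb]) {
        disp <- minimum_image(coords[nb, ] - out[cur, ], frame$box)
        out[nb, ] <- out[cur, ] + disp
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  if (!all(visited)) {
    comp <- rep(NA_integer_, n)
    comp[visited] <- 1L
    cid <- 1L
    while (anyNA(comp)) {
      cid <- cid + 1L
      seed <- which(is.na(comp))[1L]
      stack <- seed
      comp[seed] <- cid
      while (length(stack)) {
        cur <- stack[1L]; stack <- stack[-1L]
        for (nb in adj[[cur]]) if (is.na(comp[nb])) {
          comp[nb] <- cid; stack <- c(stack, nb)
        }
      }
    }
    stop("bond graph is disconnected: ", max(comp), " components (sizes ",
         paste(tabulate(comp), collapse = ", "), ")", call. = FALSE)
  }
  rownames(out) <- molecule
  out
}

#' Mass-weighted center of mass
#'
#' @param coords n x 3 matrix of (unwrapped) coordinates, nm.
#' @param masses Numeric vector of atomic masses, amu.
#' @return Length-3 position vector.
#' @export
center_of_mass <- function(coords, masses) {
  coords <- rbind(coords)
  stopifnot(nrow(coords) == length(masses))
  total <- sum(masses)
  if (total <= 0) stop("zero total mass", call. = FALSE)
  colSums(coords * masses) / total
}

#' Locate the bilayer along the membrane normal
#'
#' The membrane normal is fixed to the box z axis (flat bilayer patch). The
#' bilayer center is the z coordinate of the lipid center of mass, computed
#' with minimum-image displacements relative to the first lipid atom so a
#' bilayer drifting across the periodic boundary is handled, then wrapped
#' into the box. The outward normal points from the bilayer center toward
#' water: +z for the upper leaflet, -z for the lower.
#'
#' @param frame A trajectory frame.
#' @param lipid_group Integer indices of all lipid atoms (both leaflets).
#' @param masses Atomic masses of all atoms in the frame's atom table.
#' @return List with `z_center` (nm, in `[0, box_z)`) and `box_z`; class
#'   `membrane_frame`. Use [outward_normal()] for the per-leaflet normal.
#' @export
membrane_frame <- function(frame, lipid_group, masses) {
  if (length(lipid_group) == 0L) stop("empty lipid group", call. = FALSE)
  z <- frame$coords[lipid_group, 3L]
  m <- masses[lipid_group]
  zref <- z[1L]
  dz <- minimum_image(z - zref, frame$box[3L])
  zc <- (zref + sum(dz * m) / sum(m)) %% frame$box[3L]
  structure(list(z_center = zc, box_z = frame$box[3L]),
            class = "membrane_frame")
}

#' Per-leaflet outward membrane normal
#'
#' @param leaflet "upper" or "lower".
#' @return Unit 3-vector: `(0,0,1)` for the upper leaflet, `(0,0,-1)` for
#'   the lower (pointing from bilayer center toward water).
#' @export
outward_normal <- function(leaflet) {
  switch(leaflet,
         upper = c(0, 0, 1),
         lower = c(0, 0, -1),
         stop("leaflet must be 'upper' or 'lower'", call. = FALSE))
}

#' Tilt angle and hydroxy depth of one ligand copy
#'
#' The ligand central axis vector runs from the center of mass of the core
#' ring (`axis_tail`) to that of the hydroxy oxygen (`axis_head`). The copy
#' is assigned to a leaflet by the sign of the minimum-image z displacement
#' of its hydroxy-group center of mass from the bilayer center; the tilt
#' angle theta is measured against that leaflet's *outward* normal, so a
#' correctly oriented ligand reads small theta in either leaflet and a
#' flipped one reads theta near 180 degrees. Depth is the absolute
#' minimum-image z distance of the hydroxy-group center of mass from the
#' bilayer center (leaflet-folded, nonnegative).
#'
#' @param frame A trajectory frame.
#' @param spec A [ligand_spec()] with an `oh_group`.
#' @param copy Copy number.
#' @param membrane A [membrane_frame()] for the same frame.
#' @param atoms Atom table of the trajectory.
#' @return One-row data.frame: `frame_time`, `copy`, `theta` (degrees,
#'   [0, 180]), `depth` (nm, >= 0), `leaflet`.
#' @export
ligand_orientation <- function(frame, spec, copy, membrane, atoms) {
  all_idx <- resolve_ligand_atoms(atoms, spec, copy, "all")
  bonds <- resolve_ligand_bonds(atoms, spec, copy)
  whole <- make_whole(frame, all_idx, bonds)
  loc <- function(group) {
    idx <- resolve_ligand_atoms(atoms, spec, copy, group)
    whole[match(idx, all_idx), , drop = FALSE]
  }
  m_of <- function(group) {
    atoms$mass[resolve_ligand_atoms(atoms, spec, copy, group)]
  }
  oh_com <- center_of_mass(loc("oh"), m_of("oh"))
  axis <- center_of_mass(loc("axis_head"), m_of("axis_head")) -
    center_of_mass(loc("axis_tail"), m_of("axis_tail"))
  alen <- sqrt(sum(axis^2))
  if (alen < 1e-9) {
    stop("degenerate geometry: zero-length ligand axis vector (copy ", copy,
         ")", call. = FALSE)
  }
  dz <- minimum_image(oh_com[3L] - membrane$z_center, membrane$box_z)
  leaflet <- if (dz >= 0) "upper" else "lower"
  cosang <- sum(axis * outward_normal(leaflet)) / alen
  theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  data.frame(frame_time = frame$time, copy = copy, theta = theta,
             depth = abs(dz), leaflet = leaflet, stringsAsFactors = FALSE)
}

#' Orientation samples for every ligand copy over a trajectory
#'
#' Applies [membrane_frame()] and [ligand_orientation()] frame by frame,
#' producing the raw (theta, depth) stream the population heat map is built
#' from.
#'
#' @param traj A [trajectory()].
#' @param spec A [ligand_spec()].
#' @param lipid_group Integer indices of all lipid atoms.
#' @return data.frame with one row per copy per frame: `frame_time`, `copy`,
#'   `theta`, `depth`, `leaflet`.
#' @export
orientation_samples <- function(traj, spec, lipid_group) {
  atoms <- traj$atoms
  masses <- atoms$mass
  # resolve indices once; per-frame work is pure geometry
  pre <- lapply(seq_len(spec$n_copies), function(k) {
    all_idx <- resolve_ligand_atoms(atoms, spec, k, "all")
    grp <- function(g) match(resolve_ligand_atoms(atoms, spec, k, g), all_idx)
    list(all_idx = all_idx, bonds = resolve_ligand_bonds(atoms, spec, k),
         oh = grp("oh"), head = grp("axis_head"), tail = grp("axis_tail"),
         m_all = masses[all_idx])
  })
  nf <- length(traj$frames)
  nc <- spec$n_copies
  theta <- depth <- matrix(NA_real_, nf, nc)
  leaf <- matrix(NA_character_, nf, nc)
  times <- frame_times(traj)
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    mem <- membrane_frame(fr, lipid_group, masses)
    for (k in seq_len(nc)) {
      p <- pre[[k]]
      whole <- make_whole(fr, p$all_idx, p$bonds)
      oh_com <- center_of_mass(whole[p$oh, , drop = FALSE], p$m_all[p$oh])
      axis <- center_of_mass(whole[p$head, , drop = FALSE],
                             p$m_all[p$head]) -
        center_of_mass(whole[p$tail, , drop = FALSE], p$m_all[p$tail])
      alen <- sqrt(sum(axis^2))
      if (alen < 1e-9) {
        stop("degenerate geometry: zero-length ligand axis vector (copy ",
             k, ")", call. = FALSE)
      }
      dz <- minimum_image(oh_com[3L] - mem$z_center, mem$box_z)
      lf <- if (dz >= 0) "upper" else "lower"
      cosang <- sum(axis * outward_normal(lf)) / alen
      theta[i, k] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      depth[i, k] <- abs(dz)
      leaf[i, k] <- lf
    }
  }
  data.frame(frame_time = rep(times, each = nc), copy = rep(seq_len(nc), nf),
             theta = as.vector(t(theta)), depth = as.vector(t(depth)),
             leaflet = as.vector(t(leaf)), stringsAsFactors = FALSE)
}
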