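# Shared fixtures and independent oracles, all built in code at test time.

# A bare frame from explicit coordinates.
make_frame <- function(coords, box = c(10, 10, 10), time = 0) {
  list(time = time, box = box, coords = rbind(coords))
}

# Minimal membrane + single-ligand-copy system placed by hand: two heavy
# reference beads straddling z = z_center give a known bilayer center, and
# one template copy is placed with an explicit rotation/translation.
# Returns list(atoms, spec, frame, lipid_idx).
manual_ligand_system <- function(axis_dir = c(0, 0, 1),
                                 oh_target = c(5, 5, 6.6),
                                 box = c(10, 10, 10), with_oh = TRUE) {
  tmpl <- default_ligand_template(with_oh = with_oh, n_copies = 1L)
  atoms <- data.frame(
    name = c("C1", "C1", rownames(tmpl$coords)),
    resname = c("LIP", "LIP", rep("LIG", nrow(tmpl$coords))),
    resid = c(1L, 2L, rep(3L, nrow(tmpl$coords))),
    stringsAsFactors = FALSE
  )
  atoms$index <- seq_len(nrow(atoms))
  atoms <- membscreen:::assign_atom_properties(atoms)
  lig_rows <- 3:nrow(atoms)
  lig_mass <- atoms$mass[lig_rows]
  com_of <- function(names_) {
    i <- match(names_, rownames(tmpl$coords))
    colSums(tmpl$coords[i, , drop = FALSE] * lig_mass[i]) / sum(lig_mass[i])
  }
  axis_t <- com_of(tmpl$spec$axis_head) - com_of(tmpl$spec$axis_tail)
  axis_t <- axis_t / sqrt(sum(axis_t^2))
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  rot <- membscreen:::rotation_between(axis_t, axis_dir)
  oh_names <- if (with_oh) tmpl$spec$oh_group else tmpl$spec$axis_tail
  oi <- match(oh_names, rownames(tmpl$coords))
  m <- lig_mass[oi]
  xyz <- tmpl$coords %*% t(rot)
  oh_com <- colSums(xyz[oi, , drop = FALSE] * m) / sum(m)
  xyz <- xyz + matrix(oh_target - oh_com, nrow(xyz), 3, byrow = TRUE)
  coords <- rbind(c(5, 5, box[3] / 2 - 2), c(5, 5, box[3] / 2 + 2), xyz)
  list(atoms = atoms, spec = tmpl$spec,
       frame = make_frame(coords, box = box), lipid_idx = 1:2)
}

# Independent sort/cut-based 2D histogram oracle (never touches
# accumulate_heatmap internals). Right-open bins, last bin closed.
histogram_oracle <- function(theta, depth, tbin, dbin, nt, nd) {
  counts <- matrix(0L, nt, nd)
  for (i in seq_along(theta)) {
    ti <- min(floor(theta[i] / tbin) + 1, nt)
    di <- min(floor(depth[i] / dbin) + 1, nd)
    counts[ti, di] <- counts[ti, di] + 1L
  }
  counts
}

# Closed-form exposed area of one of two identical spheres of radius R
# (vdW + probe) whose centers are d apart: 4*pi*R^2 minus the spherical cap
# cut off by the midplane, i.e. 2*pi*R^2 + pi*R*d for d < 2R.
two_sphere_exposed_area <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  2 * pi * R^2 + pi * R * d
}

# Brute-force connected components from an adjacency matrix.
components_oracle <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ]))))
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comp
}

# Cache generated scenarios across tests within one run.
.scenario_cache <- new.env(parent = emptyenv())
cached_scenario <- function(key, cfg) {
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- generate_scenario(cfg)
  }
  .scenario_cache[[key]]
}
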