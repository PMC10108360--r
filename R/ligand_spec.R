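#' Define a ligand candidate for membrane-orientation analysis
#'
#' A ligand spec names, per candidate, the atom groups every downstream
#' observable needs: the full atom list, the two ends of the central axis
#' vector (heteroaromatic core ring as tail, hydroxy oxygen as head by
#' default), the hydroxy group (O + H), the ester/amide carbonyl-O / amide-N
#' group, hydrogen-bond donor pairs and acceptor atoms, and the covalent bond
#' list used to make copies whole across the periodic boundary. Groups are
#' given as atom *names* within one copy; copies are resolved in a trajectory
#' by residue name and residue id.
#'
#' @param resname Residue name of the ligand copies in the trajectory.
#' @param n_copies Number of copies (>= 1).
#' @param all_atoms Character vector of all atom names in one copy.
#' @param axis_tail Atom names whose center of mass is the axis tail
#'   (core ring).
#' @param axis_head Atom names whose center of mass is the axis head
#'   (hydroxy oxygen by default).
#' @param oh_group Atom names of the hydroxy group (O and H), or `NULL` for
#'   control compounds lacking the hydroxymethyl group.
#' @param oono_group Atom names of the ester/amide carbonyl oxygens and amide
#'   nitrogens.
#' @param donors List of length-2 character vectors `c(D, H)`; each H must be
#'   bonded to its D in `bonds`.
#' @param acceptors Atom names acting as H-bond acceptors.
#' @param bonds Two-column character matrix (or list of pairs) of bonded atom
#'   names; the bond graph must connect `all_atoms`.
#' @return An object of class `ligand_spec`.
#' @export
ligand_spec <- function(resname, n_copies, all_atoms, axis_tail, axis_head,
                        oh_group = NULL, oono_group = character(0),
                        donors = list(), acceptors = character(0), bonds) {
  stopifnot(is.character(resname), length(resname) == 1L,
            n_copies >= 1L, length(all_atoms) >= 2L)
  if (is.list(bonds)) bonds <- do.call(rbind, bonds)
  bonds <- as.matrix(bonds)
  stopifnot(ncol(bonds) == 2L)
  named <- unique(c(axis_tail, axis_head, oh_group, oono_group,
                    unlist(donors), acceptors, as.vector(bonds)))
  unknown <- setdiff(named, all_atoms)
  if (length(unknown)) {
    stop("atom name(s) not in all_atoms: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(axis_tail) == 0L || length(axis_head) == 0L) {
    stop("axis_tail and axis_head must be nonempty", call. = FALSE)
  }
  if (length(intersect(axis_tail, axis_head))) {
    stop("axis_tail and axis_head must be disjoint", call. = FALSE)
  }
  bondkey <- c(paste(bonds[, 1L], bonds[, 2L]), paste(bonds[, 2L], bonds[, 1L]))
  for (d in donors) {
    stopifnot(length(d) == 2L)
    if (!(paste(d[1L], d[2L]) %in% bondkey)) {
      stop("donor hydrogen ", d[2L], " is not bonded to donor ", d[1L],
           " in the bond list", call. = FALSE)
    }
  }
  structure(list(resname = resname, n_copies = as.integer(n_copies),
                 all_atoms = all_atoms, axis_tail = axis_tail,
                 axis_head = axis_head, oh_group = oh_group,
                 oono_group = oono_group, donors = donors,
                 acceptors = acceptors, bonds = bonds),
            class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat("ligand spec '", x$resname, "': ", x$n_copies, " copies, ",
      length(x$all_atoms), " atoms/copy",
      if (is.null(x$oh_group)) " (no hydroxy group)" else "", "\n", sep = "")
  invisible(x)
}

#' Resolve the global atom indices of one ligand copy
#'
#' Copies are identified by residue name; the k-th distinct resid carrying
#' that residue name is copy k. Within a copy, atoms are matched by name.
#'
#' @param atoms Atom table of the trajectory.
#' @param spec A [ligand_spec()].
#' @param copy Copy number in 1..n_copies.
#' @param group One of "all", "axis_tail", "axis_head", "oh", "oono".
#' @return Integer vector of global atom indices (1-based).
#' @export
resolve_ligand_atoms <- function(atoms, spec, copy, group = "all") {
  stopifnot(inherits(spec, "ligand_spec"), copy >= 1L, copy <= spec$n_copies)
  resids <- unique(atoms$resid[atoms$resname == spec$resname])
  if (length(resids) < spec$n_copies) {
    stop("trajectory holds ", length(resids), " '", spec$resname,
         "' residues but spec declares ", spec$n_copies, " copies",
         call. = FALSE)
  }
  sel <- atoms$resname == spec$resname & atoms$resid == resids[copy]
  names_wanted <- switch(group,
    all = spec$all_atoms,
    axis_tail = spec$axis_tail,
    axis_head = spec$axis_head,
    oh = spec$oh_group,
    oono = spec$oono_group,
    stop("unknown group: ", group, call. = FALSE))
  if (is.null(names_wanted) || length(names_wanted) == 0L) {
    stop("ligand spec '", spec$resname, "' has no '", group, "' group",
         call. = FALSE)
  }
  idx <- atoms$index[sel][match(names_wanted, atoms$name[sel])]
  if (anyNA(idx)) {
    missing <- names_wanted[is.na(idx)]
    stop("copy ", copy, " is missing atom(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx
}

# Bond list of one copy as a 2-column matrix of global indices.
resolve_ligand_bonds <- function(atoms, spec, copy) {
  all_idx <- resolve_ligand_atoms(atoms, spec, copy, "all")
  loc <- function(nm) all_idx[match(nm, spec$all_atoms)]
  cbind(loc(spec$bonds[, 1L]), loc(spec$bonds[, 2L]))
}

#' Built-in rigid ligand template used by the synthetic generator
#'
#' A minimal DAG-mimetic candidate: a six-membered heteroaromatic core
#' (five carbons + one ring nitrogen) in the xy plane, a hydroxymethyl arm
#' along +z ending in the hydroxy O-H, an ester carbonyl oxygen and an amide
#' N with its carbonyl oxygen flanking the ring. The template's central axis
#' (ring centroid to hydroxy oxygen) points along +z, so placing a copy is a
#' rotation plus translation. Coordinates in nm.
#'
#' @param with_oh If `FALSE`, the hydroxymethyl arm (CM, O1, HO1) is removed,
#'   emulating the control compounds lacking the hydroxymethyl group.
#' @param resname Residue name given to generated copies.
#' @param n_copies Copies declared in the returned spec.
#' @return A list with `coords` (named matrix, nm) and `spec`
#'   (a [ligand_spec()]).
#' @export
default_ligand_template <- function(with_oh = TRUE, resname = "LIG",
                                    n_copies = 4L) {
  ang <- (0:5) * pi / 3
  ring <- cbind(0.14 * cos(ang), 0.14 * sin(ang), rep(0, 6))
  coords <- rbind(
    ring,
    CM  = c(0, 0, 0.105),
    O1  = c(0, 0, 0.245),
    HO1 = c(0, 0, 0.345),
    C7  = c(0.26, 0.05, -0.06),
    O2  = c(0.33, 0.05, -0.17),
    N2  = c(-0.26, -0.05, -0.06),
    O3  = c(-0.33, -0.05, -0.17)
  )
  rownames(coords)[1:6] <- c("C1", "C2", "C3", "N1", "C4", "C5")
  ring_names <- rownames(coords)[1:6]
  bonds <- rbind(
    cbind(ring_names, ring_names[c(2:6, 1)]),
    c("C1", "CM"), c("CM", "O1"), c("O1", "HO1"),
    c("C2", "C7"), c("C7", "O2"),
    c("C5", "N2"), c("N2", "O3")
  )
  oh <- c("O1", "HO1")
  donors <- list(c("O1", "HO1"))
  acceptors <- c("O1", "O2", "O3", "N2")
  if (!with_oh) {
    keep <- !rownames(coords) %in% c("CM", "O1", "HO1")
    coords <- coords[keep, , drop = FALSE]
    bonds <- bonds[!(bonds[, 1L] %in% c("CM", "O1", "HO1") |
                       bonds[, 2L] %in% c("CM", "O1", "HO1")), , drop = FALSE]
    oh <- NULL
    donors <- list()
    acceptors <- c("O2", "O3", "N2")
  }
  spec <- ligand_spec(
    resname = resname, n_copies = n_copies,
    all_atoms = rownames(coords),
    axis_tail = ring_names,
    axis_head = if (with_oh) "O1" else "C7",
    oh_group = oh, oono_group = c("O2", "N2", "O3"),
    donors = donors, acceptors = acceptors, bonds = bonds
  )
  list(coords = coords, spec = spec)
}
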