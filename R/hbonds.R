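#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen/acceptor triple counts as a hydrogen bond when the
#' minimum-image donor-acceptor distance is at most `r_da_max` and the
#' hydrogen-donor-acceptor angle (vertex at the donor) is at most
#' `angle_max`. These are the conventional geometric defaults of the MD
#' analysis ecosystem; both are configuration keys and are echoed into every
#' report.
#'
#' @param r_da_max Donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_max H-D-A angle cutoff, degrees, in (0, 90) (default 30).
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(r_da_max = 0.35, angle_max = 30) {
  stopifnot(r_da_max > 0, angle_max > 0, angle_max < 90)
  structure(list(r_da_max = r_da_max, angle_max = angle_max),
            class = "hbond_criterion")
}

# Candidate acceptor indices per donor via a periodic cell list; falls back
# to all acceptors when the box is too small for 3 cells per dimension.
cell_list_candidates <- function(dcoords, acoords, box, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  if (any(ncell < 3L)) {
    return(NULL)
  }
  size <- box / ncell
  cell_of <- function(xyz) {
    ix <- pmin(floor((xyz[, 1L] %% box[1L]) / size[1L]), ncell[1L] - 1L)
    iy <- pmin(floor((xyz[, 2L] %% box[2L]) / size[2L]), ncell[2L] - 1L)
    iz <- pmin(floor((xyz[, 3L] %% box[3L]) / size[3L]), ncell[3L] - 1L)
    cbind(ix, iy, iz)
  }
  acell <- cell_of(acoords)
  akey <- acell[, 1L] + ncell[1L] * (acell[, 2L] + ncell[2L] * acell[, 3L])
  amap <- split(seq_len(nrow(acoords)), akey)
  dcell <- cell_of(dcoords)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  lapply(seq_len(nrow(dcoords)), function(i) {
    keys <- unique(vapply(seq_len(nrow(offs)), function(o) {
      cx <- (dcell[i, 1L] + offs[o, 1L]) %% ncell[1L]
      cy <- (dcell[i, 2L] + offs[o, 2L]) %% ncell[2L]
      cz <- (dcell[i, 3L] + offs[o, 3L]) %% ncell[3L]
      cx + ncell[1L] * (cy + ncell[2L] * cz)
    }, numeric(1)))
    unlist(amap[as.character(keys)], use.names = FALSE)
  })
}

#' Detect hydrogen bonds in one frame
#'
#' Evaluates every donor (D,H) pair against the acceptor list under the
#' geometric criterion, with minimum-image distances in the orthorhombic
#' box. An acceptor identical to the donor or its hydrogen is never
#' counted. `method = "grid"` uses a periodic cell list to restrict the
#' acceptor search; `method = "brute"` is the exhaustive O(ND x NA)
#' reference. Both return identical sets.
#'
#' @param frame A trajectory frame.
#' @param donors Two-column integer matrix of (donor, hydrogen) global atom
#'   indices.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param crit An [hbond_criterion()].
#' @param method "grid" (default) or "brute".
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`, one row
#'   per detected bond, ordered by donor then acceptor.
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          crit = hbond_criterion(),
                          method = c("grid", "brute")) {
  method <- match.arg(method)
  donors <- rbind(donors)
  if (nrow(donors) == 0L || length(acceptors) == 0L) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  }
  box <- frame$box
  dpos <- frame$coords[donors[, 1L], , drop = FALSE]
  hpos <- frame$coords[donors[, 2L], , drop = FALSE]
  apos <- frame$coords[acceptors, , drop = FALSE]
  cosmax <- cos(crit$angle_max * pi / 180)
  dh <- minimum_image(hpos - dpos, box)
  dhn <- sqrt(rowSums(dh^2))
  if (method == "brute") {
    # fully vectorized over the donor x acceptor grid
    nd <- nrow(donors); na <- length(acceptors)
    ii <- rep(seq_len(nd), times = na)
    jj <- rep(seq_len(na), each = nd)
    da <- minimum_image(apos[jj, , drop = FALSE] - dpos[ii, , drop = FALSE],
                        box)
    r2 <- rowSums(da^2)
    keep <- r2 <= crit$r_da_max^2 & r2 > 0 &
      acceptors[jj] != donors[ii, 1L] & acceptors[jj] != donors[ii, 2L]
    ii <- ii[keep]; jj <- jj[keep]
    cosang <- rowSums(da[keep, , drop = FALSE] * dh[ii, , drop = FALSE]) /
      (sqrt(r2[keep]) * dhn[ii])
    hit <- cosang >= cosmax - 1e-12
    res <- data.frame(donor = donors[ii[hit], 1L],
                      hydrogen = donors[ii[hit], 2L],
                      acceptor = acceptors[jj[hit]])
  } else {
    cand <- cell_list_candidates(dpos, apos, box, crit$r_da_max)
    out_d <- integer(0); out_h <- integer(0); out_a <- integer(0)
    for (i in seq_len(nrow(donors))) {
      js <- if (is.null(cand)) seq_along(acceptors) else cand[[i]]
      if (!length(js)) next
      js <- js[acceptors[js] != donors[i, 1L] & acceptors[js] != donors[i, 2L]]
      if (!length(js)) next
      da <- minimum_image(apos[js, , drop = FALSE] -
                            matrix(dpos[i, ], length(js), 3L, byrow = TRUE),
                          box)
      r2 <- rowSums(da^2)
      keep <- r2 <= crit$r_da_max^2 & r2 > 0
      if (!any(keep)) next
      cosang <- (da[keep, , drop = FALSE] %*% dh[i, ]) /
        (sqrt(r2[keep]) * dhn[i])
      hit <- js[keep][cosang >= cosmax - 1e-12]
      if (length(hit)) {
        out_d <- c(out_d, rep(donors[i, 1L], length(hit)))
        out_h <- c(out_h, rep(donors[i, 2L], length(hit)))
        out_a <- c(out_a, acceptors[hit])
      }
    }
    res <- data.frame(donor = out_d, hydrogen = out_h, acceptor = out_a)
  }
  res <- res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Donor pairs and acceptor indices for the two sides of a ligand-partner
# H-bond count. Returns list(donors = 2-col matrix, acceptors = int vector)
# for "ligand side" and "partner side" given the group choice.
hbond_participants <- function(traj, spec, copy, group, partner_groups) {
  atoms <- traj$atoms
  lig_all <- resolve_ligand_atoms(atoms, spec, copy, "all")
  name_of <- atoms$name[lig_all]
  gidx <- resolve_ligand_atoms(atoms, spec, copy, group)
  # ligand donors restricted to the group (hydroxy only; OO/NO are
  # acceptor-only)
  ldon <- do.call(rbind, lapply(spec$donors, function(d) {
    di <- lig_all[match(d[1L], name_of)]
    hi <- lig_all[match(d[2L], name_of)]
    if (di %in% gidx) c(di, hi) else NULL
  }))
  if (is.null(ldon)) ldon <- matrix(integer(0), 0L, 2L)
  lacc <- intersect(lig_all[match(spec$acceptors, name_of)], gidx)
  list(lig_donors = ldon, lig_acceptors = lacc)
}

# Water donor pairs (OW,HW1),(OW,HW2) and acceptor OW indices from the atom
# table; lipid head-group acceptors (phosphorus-bead) with no donors.
partner_participants <- function(atoms, partner, water_group, lipid_group) {
  if (partner == "water") {
    w <- water_group
    ow <- w[atoms$name[w] == "OW"]
    don <- NULL
    for (h in c("HW1", "HW2")) {
      hw <- w[atoms$name[w] == h]
      if (length(hw) == length(ow)) don <- rbind(don, cbind(ow, hw))
    }
    if (is.null(don)) don <- matrix(integer(0), 0L, 2L)
    list(donors = don, acceptors = ow)
  } else if (partner == "lipid") {
    acc <- lipid_group[atoms$element[lipid_group] %in% c("P", "O", "N")]
    list(donors = matrix(integer(0), 0L, 2L), acceptors = acc)
  } else {
    stop("partner must be 'water' or 'lipid'", call. = FALSE)
  }
}

#' Per-molecule hydrogen-bond block statistics
#'
#' For every frame, hydrogen bonds between the chosen ligand group (hydroxy
#' `"oh"`, acting as donor and acceptor; ester/amide `"oono"`, acceptor
#' only) and the partner group (water, donor and acceptor; lipid,
#' acceptor only) are counted, summed over the ligand copies and divided by
#' the number of copies ("per molecule"). The per-frame series is then
#' block-averaged.
#'
#' @param traj A [trajectory()].
#' @param spec A [ligand_spec()].
#' @param group "oh" or "oono".
#' @param partner "water" or "lipid".
#' @param water_group,lipid_group Integer atom indices of the partner
#'   selections.
#' @param crit An [hbond_criterion()].
#' @param n_blocks Number of time blocks (default 5).
#' @return A [block_average()]; also carries attribute `per_frame` with the
#'   per-molecule count series.
#' @export
hbond_block_stats <- function(traj, spec, group = c("oh", "oono"),
                              partner = c("water", "lipid"),
                              water_group = NULL, lipid_group = NULL,
                              crit = hbond_criterion(), n_blocks = 5L) {
  group <- match.arg(group)
  partner <- match.arg(partner)
  atoms <- traj$atoms
  pp <- partner_participants(atoms, partner, water_group, lipid_group)
  parts <- lapply(seq_len(spec$n_copies), function(k) {
    hbond_participants(traj, spec, k, group, partner)
  })
  nf <- length(traj$frames)
  per_frame <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    total <- 0L
    for (k in seq_len(spec$n_copies)) {
      p <- parts[[k]]
      total <- total +
        nrow(detect_hbonds(fr, p$lig_donors, pp$acceptors, crit,
                           method = "brute")) +
        nrow(detect_hbonds(fr, pp$donors, p$lig_acceptors, crit,
                           method = "brute"))
    }
    per_frame[i] <- total / spec$n_copies
  }
  dt <- if (nf > 1L) stats::median(diff(frame_times(traj))) else NA_real_
  ba <- block_average(per_frame, n_blocks, frame_dt = dt)
  attr(ba, "per_frame") <- per_frame
  ba
}
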