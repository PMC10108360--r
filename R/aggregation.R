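#' Ligand cluster partition in one frame
#'
#' Two ligand copies are adjacent when their minimum-image minimum
#' inter-atomic distance is at most `cutoff`; clusters are the connected
#' components of that adjacency (single linkage).
#'
#' @param frame A trajectory frame.
#' @param spec A [ligand_spec()] with `n_copies >= 1`.
#' @param atoms Atom table of the trajectory.
#' @param cutoff Contact distance cutoff in nm (default 0.4).
#' @return Object of class `cluster_state`: `frame_time`, `clusters` (list
#'   of integer copy-id vectors partitioning 1..n_copies),
#'   `largest_cluster_size`, `n_clusters`.
#' @export
ligand_clusters <- function(frame, spec, atoms, cutoff = 0.4, idx = NULL) {
  stopifnot(cutoff > 0)
  nc <- spec$n_copies
  if (nc == 0L) stop("ligand spec declares zero copies", call. = FALSE)
  if (is.null(idx)) {
    idx <- lapply(seq_len(nc), function(k) {
      resolve_ligand_atoms(atoms, spec, k, "all")
    })
  }
  adj <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc - 1L)) {
    ci <- frame$coords[idx[[i]], , drop = FALSE]
    for (j in (i + 1L):nc) {
      cj <- frame$coords[idx[[j]], , drop = FALSE]
      mind2 <- Inf
      for (r in seq_len(nrow(ci))) {
        d <- minimum_image(cj - matrix(ci[r, ], nrow(cj), 3L, byrow = TRUE),
                           frame$box)
        mind2 <- min(mind2, min(rowSums(d^2)))
      }
      adj[i, j] <- adj[j, i] <- mind2 <= cutoff^2
    }
  }
  comp <- rep(NA_integer_, nc)
  cid <- 0L
  for (s in seq_len(nc)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    stack <- s
    comp[s] <- cid
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      nb <- which(adj[cur, ] & is.na(comp))
      comp[nb] <- cid
      stack <- c(stack, nb)
    }
  }
  clusters <- unname(split(seq_len(nc), comp))
  structure(list(frame_time = frame$time, clusters = clusters,
                 largest_cluster_size = max(lengths(clusters)),
                 n_clusters = length(clusters)),
            class = "cluster_state")
}

#' Ligand cluster time series and summary
#'
#' @param traj A [trajectory()].
#' @param spec A [ligand_spec()].
#' @param cutoff Contact cutoff in nm (default 0.4).
#' @return List with `timeseries` (data.frame: `time`, `n_clusters`,
#'   `largest_cluster_size`), `clustered_frame_fraction` (fraction of frames
#'   holding any cluster of size >= 2) and `mean_largest_cluster_size`.
#' @export
cluster_timeseries <- function(traj, spec, cutoff = 0.4) {
  idx <- lapply(seq_len(spec$n_copies), function(k) {
    resolve_ligand_atoms(traj$atoms, spec, k, "all")
  })
  states <- lapply(traj$frames, function(fr) {
    ligand_clusters(fr, spec, traj$atoms, cutoff, idx = idx)
  })
  ts <- data.frame(
    time = vapply(states, function(s) s$frame_time, numeric(1)),
    n_clusters = vapply(states, function(s) s$n_clusters, integer(1)),
    largest_cluster_size = vapply(states, function(s) s$largest_cluster_size,
                                  integer(1))
  )
  list(timeseries = ts,
       clustered_frame_fraction = mean(ts$largest_cluster_size >= 2L),
       mean_largest_cluster_size = mean(ts$largest_cluster_size))
}
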