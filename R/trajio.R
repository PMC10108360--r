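#' Construct a trajectory object
#'
#' A trajectory bundles a single atom table with an ordered list of frames.
#' Every frame shares the atom table; frame times must be strictly
#' increasing.
#'
#' @param atoms Atom table: data.frame with columns `index` (1..n,
#'   contiguous), `name`, `resname`, `resid`, `mass` (amu), `vdw_radius`
#'   (nm), `element`.
#' @param frames List of frames, each a list with `time` (ps), `box`
#'   (three edge lengths, nm, orthorhombic) and `coords` (n x 3 matrix, nm).
#' @return An object of class `membscreen_traj`.
#' @export
trajectory <- function(atoms, frames) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1L)
  n <- nrow(atoms)
  if (!identical(atoms$index, seq_len(n))) {
    stop("atom indices must be contiguous 1..n", call. = FALSE)
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f$coords) || nrow(f$coords) != n || ncol(f$coords) != 3L) {
      stop("frame ", i, ": coordinate count does not match atom table",
           call. = FALSE)
    }
    if (any(!is.finite(f$coords)) || any(!is.finite(f$box)) || any(f$box <= 0)) {
      stop("frame ", i, ": coordinates and box must be finite, box > 0",
           call. = FALSE)
    }
  }
  structure(list(atoms = atoms, frames = frames), class = "membscreen_traj")
}

#' @export
print.membscreen_traj <- function(x, ...) {
  times <- vapply(x$frames, function(f) f$time, numeric(1))
  cat("membscreen trajectory: ", nrow(x$atoms), " atoms, ",
      length(x$frames), " frames, t = ", min(times), "..", max(times),
      " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `membscreen_traj`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

frame_times <- function(traj) vapply(traj$frames, function(f) f$time, numeric(1))

#' Read a (multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GRO dialect: title line (a `t= <ps>` tag, if
#' present, sets the frame time), atom count, atom records
#' (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`), and a box line. Concatenated frames are
#' read in order. Velocities, if present, are parsed and discarded. Only
#' orthorhombic boxes are supported: a box line with nonzero off-diagonal
#' components is rejected.
#'
#' @param path Path to a GRO file.
#' @param overrides Optional data.frame(name, mass, vdw_radius) overriding the
#'   built-in element lookup for specific atom names.
#' @return A [trajectory()] object; masses and radii assigned from the
#'   built-in element table.
#' @export
read_gro <- function(path, overrides = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  frames <- list()
  atoms <- NULL
  frame_no <- 0L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i]) && i == length(lines)) break
    frame_no <- frame_no + 1L
    title <- lines[i]
    if (i + 1L > length(lines)) {
      stop("frame ", frame_no, ": truncated file (missing atom count line)",
           call. = FALSE)
    }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop("frame ", frame_no, ": invalid atom count at line ", i + 1L,
           call. = FALSE)
    }
    body_end <- i + 1L + natoms
    if (body_end + 1L > length(lines)) {
      stop("frame ", frame_no, ": declares ", natoms,
           " atoms but file ends early (line ", length(lines), ")",
           call. = FALSE)
    }
    body <- lines[(i + 2L):body_end]
    if (any(nchar(body) < 44L)) {
      bad <- which(nchar(body) < 44L)[1L]
      stop("frame ", frame_no, ": atom record at line ", i + 1L + bad,
           " shorter than the fixed-column width", call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(substr(body, 21L, 28L)))
    y <- suppressWarnings(as.numeric(substr(body, 29L, 36L)))
    z <- suppressWarnings(as.numeric(substr(body, 37L, 44L)))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(x) | is.na(y) | is.na(z))[1L]
      stop("frame ", frame_no, ": unparseable coordinates at line ",
           i + 1L + bad, call. = FALSE)
    }
    boxvals <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[body_end + 1L]), "\\s+")[[1L]]))
    if (length(boxvals) < 3L || anyNA(boxvals)) {
      stop("frame ", frame_no, ": invalid box line (is the declared atom ",
           "count consistent with the body?)", call. = FALSE)
    }
    if (length(boxvals) > 3L && any(abs(boxvals[4:length(boxvals)]) > 1e-9)) {
      stop("frame ", frame_no, ": triclinic box not supported ",
           "(off-diagonal box components nonzero)", call. = FALSE)
    }
    if (frame_no == 1L) {
      atoms <- data.frame(
        index = seq_len(natoms),
        name = trimws(substr(body, 11L, 15L)),
        resname = trimws(substr(body, 6L, 10L)),
        resid = as.integer(substr(body, 1L, 5L)),
        stringsAsFactors = FALSE
      )
      atoms <- assign_atom_properties(atoms, overrides)
    } else if (natoms != nrow(atoms)) {
      stop("frame ", frame_no, ": atom count ", natoms,
           " differs from first frame (", nrow(atoms), ")", call. = FALSE)
    }
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else frame_no - 1
    frames[[frame_no]] <- list(time = time, box = boxvals[1:3],
                               coords = cbind(x, y, z, deparse.level = 0))
    i <- body_end + 2L
  }
  if (frame_no == 0L) stop("no frames found in ", path, call. = FALSE)
  trajectory(atoms, frames)
}

#' Write a trajectory to a (multi-frame) GRO file
#'
#' Coordinates are written in the fixed 8.3 columns (nm, rounded to three
#' decimals), one frame block per frame with the frame time tagged on the
#' title line. Coordinates too large for the fixed columns raise an overflow
#' error rather than producing corrupt records.
#'
#' @param traj A [trajectory()] object with at least one frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "membscreen_traj"))
  if (length(traj$frames) == 0L) {
    stop("empty trajectory: nothing to write", call. = FALSE)
  }
  a <- traj$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in traj$frames) {
    if (any(abs(f$coords) >= 10000 - 5e-4)) {
      stop("coordinate magnitude exceeds the GRO fixed-column width",
           call. = FALSE)
    }
    writeLines(sprintf("membscreen frame t= %.3f", f$time), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resid %% 100000L, a$resname, a$name,
                       a$index %% 100000L,
                       f$coords[, 1L], f$coords[, 2L], f$coords[, 3L]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1L], f$box[2L], f$box[3L]),
               con)
  }
  invisible(path)
}

#' Read an NDX index-group file
#'
#' Bracketed group names followed by whitespace-separated 1-based atom
#' indices, as written by the standard MD analysis ecosystem.
#'
#' @param path Path to an NDX file.
#' @param atoms Atom table the indices are validated against.
#' @return Named list of integer index vectors (1-based, order preserved).
#' @export
read_index_groups <- function(path, atoms) {
  stopifnot(file.exists(path), is.data.frame(atoms))
  lines <- readLines(path, warn = FALSE)
  groups <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    hdr <- regmatches(ln, regexpr("^\\s*\\[\\s*([^]]+?)\\s*\\]\\s*$", ln))
    if (length(hdr)) {
      current <- gsub("^\\s*\\[\\s*|\\s*\\]\\s*$", "", hdr)
      if (current %in% names(groups)) {
        stop("duplicate group name: ", current, call. = FALSE)
      }
      groups[[current]] <- integer(0)
      next
    }
    if (grepl("^\\s*$", ln)) next
    if (is.null(current)) {
      stop("index data before any [ group ] header", call. = FALSE)
    }
    idx <- suppressWarnings(as.integer(strsplit(trimws(ln), "\\s+")[[1L]]))
    if (anyNA(idx)) stop("non-integer index in group ", current, call. = FALSE)
    groups[[current]] <- c(groups[[current]], idx)
  }
  n <- nrow(atoms)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (any(idx < 1L | idx > n)) {
      bad <- idx[idx < 1L | idx > n][1L]
      stop("group ", g, ": index ", bad, " out of range (1..", n, ")",
           call. = FALSE)
    }
    if (anyDuplicated(idx)) {
      stop("group ", g, ": duplicate atom indices", call. = FALSE)
    }
  }
  groups
}

#' Write selection groups to an NDX file
#'
#' @param groups Named list of 1-based integer index vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_groups <- function(groups, path) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (g in names(groups)) {
    writeLines(sprintf("[ %s ]", g), con)
    idx <- groups[[g]]
    if (length(idx)) {
      rows <- split(idx, ceiling(seq_along(idx) / 15))
      writeLines(vapply(rows, function(r) paste(r, collapse = " "),
                        character(1)), con)
    }
  }
  invisible(path)
}
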