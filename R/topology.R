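#' Molecular topology container
#'
#' A `flipsite_topology` holds an ordered atom table, a bond list and the
#' residue grouping implied by `(chain, residue_id, residue_name)`. Atom
#' indices are 1-based throughout the package and atom order is never
#' changed by any operation. Residue ids are kept verbatim from the source
#' file (PDB files are conventionally 1-based and may have gaps).
#'
#' Lennard-Jones well depths are stored as non-negative magnitudes
#' (`lj_epsilon >= 0`); CHARMM parameter files that carry the negative sign
#' convention are normalized on ingest.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_name`,
#'   `residue_id` (integer), `chain`, `charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `mass`, and logical role columns `is_donor`,
#'   `is_hydrogen`, `is_acceptor`, `is_water`. Missing parameter columns
#'   are filled with `NA`; missing role columns with `FALSE`.
#' @param bonds two-column integer matrix of 1-based atom indices (may have
#'   zero rows).
#' @return object of class `flipsite_topology`
#' @export
topology <- function(atoms, bonds = matrix(integer(), ncol = 2L)) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  for (col in c("charge", "lj_epsilon", "lj_rmin_half", "mass")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  for (col in c("is_donor", "is_hydrogen", "is_acceptor", "is_water")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- FALSE
  }
  atoms$residue_id <- as.integer(atoms$residue_id)
  rownames(atoms) <- NULL
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  top <- structure(list(atoms = atoms, bonds = bonds),
                   class = "flipsite_topology")
  validate_topology(top)
  top
}

#' @export
print.flipsite_topology <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<flipsite_topology> %d atoms, %d bonds, %d residues\n",
              n_atoms(x), nrow(x$bonds), nrow(res)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology a `flipsite_topology`
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

validate_topology <- function(top) {
  atoms <- top$atoms
  n <- nrow(atoms)
  if (nrow(top$bonds) > 0) {
    if (any(top$bonds < 1L) || any(top$bonds > n))
      stop("topology bond indices out of range [1, ", n, "]")
    if (any(top$bonds[, 1] == top$bonds[, 2]))
      stop("topology contains a self-bond")
  }
  eps <- atoms$lj_epsilon
  if (any(!is.na(eps) & eps < 0))
    stop("lj_epsilon must be stored as a non-negative magnitude")
  # every hydrogen-role atom is bonded to exactly one heavy atom
  hyd <- which(atoms$is_hydrogen)
  if (length(hyd) > 0 && nrow(top$bonds) > 0) {
    deg <- tabulate(c(top$bonds), nbins = n)
    bad <- hyd[deg[hyd] != 1L]
    if (length(bad) > 0)
      stop("hydrogen-role atoms must be bonded to exactly one heavy atom; ",
           "violated by atom index ", bad[1])
  }
  invisible(top)
}

#' Residue table of a topology
#'
#' One row per residue in order of first appearance, with the atom index
#' range. Residues are identified by `(chain, residue_id, residue_name)`
#' and partition the atom list.
#' @param topology a `flipsite_topology`
#' @return data.frame with columns `chain`, `residue_id`, `residue_name`,
#'   `first_atom`, `last_atom`, `n_atoms`
#' @export
residue_table <- function(topology) {
  a <- topology$atoms
  key <- paste(a$chain, a$residue_id, a$residue_name, sep = "\r")
  runs <- rle(key)
  if (anyDuplicated(runs$values))
    stop("residues must be contiguous blocks of the atom list")
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1L
  data.frame(chain = a$chain[first],
             residue_id = a$residue_id[first],
             residue_name = a$residue_name[first],
             first_atom = first, last_atom = last,
             n_atoms = runs$lengths,
             stringsAsFactors = FALSE)
}

#' Total charge of a topology (sum of atomic partial charges)
#' @param topology a `flipsite_topology`
#' @export
total_charge <- function(topology) sum(topology$atoms$charge)

#' Select atom indices by attribute
#'
#' All supplied filters are combined with AND; vector values mean "any of".
#'
#' @param topology a `flipsite_topology`
#' @param name,element,residue_name,chain character filters
#' @param residue_id integer filter
#' @return integer vector of 1-based atom indices (file order)
#' @export
atom_select <- function(topology, name = NULL, element = NULL,
                        residue_name = NULL, residue_id = NULL,
                        chain = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(residue_name)) keep <- keep & a$residue_name %in% residue_name
  if (!is.null(residue_id)) keep <- keep & a$residue_id %in% residue_id
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

#' Single trajectory frame
#'
#' @param coordinates N x 3 numeric matrix of Cartesian coordinates in
#'   Angstrom
#' @param time time stamp in ps
#' @param box optional length-3 orthorhombic box edge lengths in Angstrom
#' @return object of class `flipsite_frame`
#' @export
frame <- function(coordinates, time = 0, box = NULL) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be an N x 3 matrix")
  if (!all(is.finite(coordinates))) stop("non-finite coordinates in frame")
  if (!is.null(box)) {
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive orthorhombic edge lengths (triclinic ",
           "boxes are not supported)")
  }
  dimnames(coordinates) <- NULL
  structure(list(coordinates = coordinates, time = as.numeric(time),
                 box = box),
            class = "flipsite_frame")
}

#' Trajectory container
#'
#' Frames are stored as a dense `n_atoms x 3 x n_frames` array with a
#' strictly increasing time vector (ps). All frames share the atom count.
#'
#' @param frames list of [frame()] objects, or a 3-d array
#' @param dt frame spacing in ps, used to stamp times when `frames` carry
#'   none (times default to `0, dt, 2*dt, ...`)
#' @param times optional explicit time vector overriding both
#' @return object of class `flipsite_trajectory`
#' @export
trajectory <- function(frames, dt = NULL, times = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    xyz <- frames
  } else {
    stopifnot(length(frames) > 0)
    n <- nrow(frames[[1]]$coordinates)
    if (any(vapply(frames, function(f) nrow(f$coordinates), 1L) != n))
      stop("all frames in a trajectory must share the atom count")
    xyz <- array(0, dim = c(n, 3L, length(frames)))
    for (i in seq_along(frames)) xyz[, , i] <- frames[[i]]$coordinates
    if (is.null(times)) {
      t0 <- vapply(frames, function(f) f$time, 1.0)
      if (length(t0) > 1 && all(diff(t0) > 0)) times <- t0
    }
  }
  nf <- dim(xyz)[3]
  if (is.null(times)) {
    if (is.null(dt)) dt <- 1
    times <- (seq_len(nf) - 1) * dt
  }
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (is.null(dt)) dt <- if (nf > 1) times[2] - times[1] else 1
  structure(list(xyz = xyz, times = as.numeric(times), dt = as.numeric(dt)),
            class = "flipsite_trajectory")
}

#' @export
print.flipsite_trajectory <- function(x, ...) {
  cat(sprintf("<flipsite_trajectory> %d atoms x %d frames, dt = %g ps\n",
              dim(x$xyz)[1], n_frames(x), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `flipsite_trajectory`
#' @export
n_frames <- function(trajectory) dim(trajectory$xyz)[3]

#' Extract one frame of a trajectory
#' @param trajectory a `flipsite_trajectory`
#' @param i frame index (1-based)
#' @return a [frame()] object
#' @export
get_frame <- function(trajectory, i) {
  nf <- n_frames(trajectory)
  if (i < 1L || i > nf) stop("frame index ", i, " out of range [1, ", nf, "]")
  frame(trajectory$xyz[, , i, drop = TRUE], time = trajectory$times[i])
}

# coordinates of frame i as a plain matrix (no validation; hot path)
frame_xyz <- function(trajectory, i) {
  matrix(trajectory$xyz[, , i], ncol = 3L)
}
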