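#' Geometric hydrogen-bond criteria
#'
#' A donor-H-acceptor triplet counts as hydrogen-bonded when the
#' donor-acceptor heavy-atom distance is at most `max_da_distance` and the
#' D-H-A angle (vertex at the hydrogen) is at least `min_dha_angle`. The
#' defaults (3.5 Angstrom, 120 degrees) are the widely used geometric
#' convention; both are configurable and recorded in outputs.
#'
#' @param max_da_distance donor-acceptor cutoff, Angstrom
#' @param min_dha_angle minimum D-H-A angle, degrees, in (0, 180]
#' @param minimum_image use minimum-image displacements when the frame
#'   carries an orthorhombic box (off by default: the complex is kept
#'   whole)
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120,
                           minimum_image = FALSE) {
  stopifnot(max_da_distance > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle,
                 minimum_image = minimum_image),
            class = "flipsite_hbond_criteria")
}

# donor-hydrogen covalent pairs from role annotations + bond list
donor_hydrogen_pairs <- function(topology) {
  a <- topology$atoms
  if (!any(a$is_donor) && !any(a$is_acceptor))
    stop("topology has no donor/acceptor role annotations; ",
         "merge a charge topology first")
  b <- topology$bonds
  if (nrow(b) == 0) stop("topology has no bonds; cannot pair donors with H")
  both <- rbind(b, b[, 2:1, drop = FALSE])
  dh <- both[a$is_donor[both[, 1]] & a$is_hydrogen[both[, 2]], , drop = FALSE]
  colnames(dh) <- c("donor", "hydrogen")
  dh
}

# pairs of atoms separated by <= 2 covalent bonds (matrix lookup closure)
bonded_within_two <- function(topology) {
  n <- n_atoms(topology)
  b <- topology$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  function(i, j) {
    if (j %in% adj[[i]]) return(TRUE)
    length(intersect(adj[[i]], adj[[j]])) > 0
  }
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates donor-hydrogen covalent pairs against all acceptors and
#' applies the geometric criteria. The donor and acceptor must be distinct
#' atoms, and pairs separated by at most two covalent bonds are excluded
#' (a hydroxyl oxygen cannot "bond" to its own neighbor).
#'
#' @param topology a [topology()] with role annotations and bonds
#' @param frame a [frame()] with coordinates for every atom
#' @param criteria a [hbond_criteria()]
#' @return data.frame with integer columns `donor`, `hydrogen`, `acceptor`
#'   (1-based atom indices), ordered by (donor, hydrogen, acceptor)
#' @export
detect_hbonds <- function(topology, frame, criteria = hbond_criteria()) {
  a <- topology$atoms
  xyz <- frame$coordinates
  if (nrow(xyz) != nrow(a))
    stop("frame has ", nrow(xyz), " atoms but topology has ", nrow(a))
  dh <- donor_hydrogen_pairs(topology)
  acc <- which(a$is_acceptor)
  out <- list()
  if (nrow(dh) > 0 && length(acc) > 0) {
    near <- bonded_within_two(topology)
    box <- if (isTRUE(criteria$minimum_image)) frame$box else NULL
    cosmin <- cos(criteria$min_dha_angle * pi / 180)
    for (k in seq_len(nrow(dh))) {
      d <- dh[k, 1]; h <- dh[k, 2]
      vda <- sweep(xyz[acc, , drop = FALSE], 2, xyz[d, ])
      if (!is.null(box)) vda <- min_image(vda, box)
      dist_da <- sqrt(rowSums(vda^2))
      cand <- which(dist_da <= criteria$max_da_distance & acc != d)
      for (ci in cand) {
        aidx <- acc[ci]
        if (near(d, aidx)) next
        vhd <- xyz[d, ] - xyz[h, ]
        vha <- xyz[aidx, ] - xyz[h, ]
        if (!is.null(box)) {
          vhd <- drop(min_image(rbind(vhd), box))
          vha <- drop(min_image(rbind(vha), box))
        }
        cosang <- sum(vhd * vha) / sqrt(sum(vhd^2) * sum(vha^2))
        # angle >= min  <=>  cos(angle) <= cos(min)
        if (cosang <= cosmin) {
          out[[length(out) + 1L]] <- c(d, h, aidx)
        }
      }
    }
  }
  res <- if (length(out)) {
    m <- do.call(rbind, out)
    data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
  } else {
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer())
  }
  res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
}

min_image <- function(v, box) {
  for (d in 1:3) v[, d] <- v[, d] - box[d] * round(v[, d] / box[d])
  v
}

#' Hydrogen-bond occupancy timeline over a trajectory
#'
#' Runs [detect_hbonds()] on every frame and assembles per-bond presence
#' records. Bond identity across frames is the atom-index triplet, so a
#' water keeps its identity by residue. Only bonds with at least one atom
#' in `selection` are kept (binding-site restriction).
#'
#' @param trajectory a [trajectory()]
#' @param topology a [topology()]
#' @param criteria a [hbond_criteria()]
#' @param selection integer atom indices; defaults to all atoms
#' @param labels optional named integer vector of display labels, named
#'   `"donor-hydrogen-acceptor"` index triplets (figure-style numbering is
#'   user-supplied, never derived)
#' @return object of class `flipsite_hbond_timeline`: list with `bonds`
#'   (data.frame `donor`, `hydrogen`, `acceptor`, `label`), `presence`
#'   (logical bonds x frames matrix), `frame_times`, `criteria`
#' @export
hbond_timeline <- function(trajectory, topology,
                           criteria = hbond_criteria(),
                           selection = seq_len(n_atoms(topology)),
                           labels = NULL) {
  nf <- n_frames(trajectory)
  if (nf == 0) stop("empty trajectory")
  if (length(selection) == 0) stop("empty selection")
  per_frame <- vector("list", nf)
  keys <- character(0)
  for (i in seq_len(nf)) {
    det <- detect_hbonds(topology, get_frame(trajectory, i), criteria)
    keep <- det$donor %in% selection | det$hydrogen %in% selection |
      det$acceptor %in% selection
    det <- det[keep, , drop = FALSE]
    k <- paste(det$donor, det$hydrogen, det$acceptor, sep = "-")
    per_frame[[i]] <- k
    keys <- union(keys, k)
  }
  keys <- sort_bond_keys(keys)
  presence <- matrix(FALSE, nrow = length(keys), ncol = nf,
                     dimnames = list(keys, NULL))
  for (i in seq_len(nf)) presence[per_frame[[i]], i] <- TRUE
  if (length(keys) == 0) {
    bonds <- data.frame(donor = integer(), hydrogen = integer(),
                        acceptor = integer(), label = integer())
  } else {
    triple <- do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
    bonds <- data.frame(
      donor = triple[, 1], hydrogen = triple[, 2], acceptor = triple[, 3],
      label = if (is.null(labels)) NA_integer_ else unname(labels[keys]))
  }
  structure(list(bonds = bonds, presence = presence,
                 frame_times = trajectory$times, criteria = criteria),
            class = "flipsite_hbond_timeline")
}

sort_bond_keys <- function(keys) {
  if (length(keys) == 0) return(keys)
  m <- do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
  keys[order(m[, 1], m[, 2], m[, 3])]
}

#' @export
print.flipsite_hbond_timeline <- function(x, ...) {
  cat(sprintf("<hbond_timeline> %d bonds x %d frames\n",
              nrow(x$bonds), ncol(x$presence)))
  invisible(x)
}

#' Per-bond occupancy and the stable-bond subset
#'
#' Occupancy is the fraction of frames in which a bond is present; bonds
#' with occupancy at or above `stable_threshold` form the stable subset
#' (stability of a bond is operationalized as high occupancy).
#'
#' @param timeline a [hbond_timeline()] result
#' @param stable_threshold occupancy fraction in `[0, 1]`
#' @return data.frame `donor`, `hydrogen`, `acceptor`, `label`,
#'   `n_present`, `occupancy`, `stable`
#' @export
occupancy_summary <- function(timeline, stable_threshold = 0.5) {
  stopifnot(stable_threshold >= 0, stable_threshold <= 1)
  n_present <- rowSums(timeline$presence)
  occ <- n_present / ncol(timeline$presence)
  cbind(timeline$bonds,
        data.frame(n_present = as.integer(n_present), occupancy = occ,
                   stable = occ >= stable_threshold))
}

#' Export a timeline as TSV (occurrence-plot layout)
#'
#' One row per bond: triplet, label, occupancy, and the presence record
#' run-length encoded as `start:length` pairs — the data behind an
#' occurrence plot of frame time vs bond label.
#'
#' @param timeline a [hbond_timeline()] result
#' @param path optional output file
#' @return character TSV lines
#' @export
format_hbond_timeline_tsv <- function(timeline, path = NULL) {
  occ <- occupancy_summary(timeline)
  rle_str <- apply(timeline$presence, 1, function(p) {
    r <- rle(p)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    paste(sprintf("%d:%d", starts[r$values], r$lengths[r$values]),
          collapse = ",")
  })
  header <- paste("donor", "hydrogen", "acceptor", "label", "occupancy",
                  "present_runs", sep = "\t")
  body <- sprintf("%d\t%d\t%d\t%s\t%.6f\t%s", occ$donor, occ$hydrogen,
                  occ$acceptor, ifelse(is.na(occ$label), ".",
                                       as.character(occ$label)),
                  occ$occupancy, rle_str)
  lines <- c(header, if (nrow(occ) > 0) body)
  if (!is.null(path)) writeLines(lines, path)
  lines
}
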