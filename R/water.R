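#' Per-frame water occupancy of a binding site
#'
#' A water is counted in a frame when its oxygen lies within `radius` of
#' the geometric centroid of the `site_center` atoms in that same frame
#' (the site moves with the pocket).
#'
#' @param trajectory a [trajectory()]
#' @param topology a [topology()] with waters flagged (`is_water`)
#' @param site_center integer atom indices defining the site centroid
#' @param radius Angstrom, > 0
#' @return list of length `n_frames`; element i is the sorted integer
#'   vector of water `residue_id`s within the site at frame i
#' @export
site_water_occupancy <- function(trajectory, topology, site_center,
                                 radius = 3.5) {
  stopifnot(radius > 0, length(site_center) > 0)
  a <- topology$atoms
  wat_o <- which(a$is_water & a$element == "O")
  nf <- n_frames(trajectory)
  if (length(wat_o) == 0) {
    warning("no water oxygens in topology")
    return(rep(list(integer(0)), nf))
  }
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, i)
    ctr <- colMeans(xyz[site_center, , drop = FALSE])
    d2 <- rowSums(sweep(xyz[wat_o, , drop = FALSE], 2, ctr)^2)
    out[[i]] <- sort(a$residue_id[wat_o[d2 <= radius^2]])
  }
  out
}

#' Conserved water sites in the pocket frame
#'
#' Every frame is superposed onto the first frame using the
#' `pocket_alignment` atoms, water-oxygen positions are pooled in this
#' common pocket frame, and positions are clustered greedily: the point
#' with the most neighbors within `cluster_radius` seeds a site (ties
#' broken by earliest frame, then lowest atom index), its neighbors are
#' assigned and removed, and the procedure repeats. A site's residency is
#' the fraction of frames in which at least one water occupies it. Site
#' identity is positional, not molecular — a persistently occupied
#' location counts as one conserved site even when the occupying molecule
#' exchanges.
#'
#' @param trajectory a [trajectory()]
#' @param topology a [topology()]
#' @param pocket_alignment atom indices to superpose on (>= 3,
#'   non-collinear)
#' @param cluster_radius Angstrom (default 1.5, hydration-site
#'   convention)
#' @param min_residency minimum residency fraction for a reported site
#' @return list of `WaterSite`s sorted by residency (descending), each a
#'   list with `centroid` (pocket-frame Angstrom), `residency`, and
#'   `occupants` (length `n_frames` integer vector of water residue ids,
#'   `NA` when empty)
#' @export
conserved_water_sites <- function(trajectory, topology, pocket_alignment,
                                  cluster_radius = 1.5,
                                  min_residency = 0.5) {
  a <- topology$atoms
  wat_o <- which(a$is_water & a$element == "O")
  nf <- n_frames(trajectory)
  if (length(pocket_alignment) < 3)
    stop("pocket alignment needs >= 3 atoms")
  ref <- frame_xyz(trajectory, 1)[pocket_alignment, , drop = FALSE]
  if (collinear(ref)) stop("pocket alignment atoms are collinear")
  if (length(wat_o) == 0) return(list())

  # pool water-O positions in the pocket-aligned frame
  pos <- matrix(0, nrow = length(wat_o) * nf, ncol = 3)
  pt_frame <- integer(nrow(pos)); pt_atom <- integer(nrow(pos))
  k <- 0L
  for (i in seq_len(nf)) {
    xyz <- frame_xyz(trajectory, i)
    sp <- superpose(ref, xyz[pocket_alignment, , drop = FALSE])
    wat_xyz <- apply_superposition(sp, xyz[wat_o, , drop = FALSE])
    rows <- k + seq_along(wat_o)
    pos[rows, ] <- wat_xyz
    pt_frame[rows] <- i
    pt_atom[rows] <- wat_o
    k <- k + length(wat_o)
  }

  unassigned <- rep(TRUE, nrow(pos))
  sites <- list()
  r2 <- cluster_radius^2
  while (any(unassigned)) {
    live <- which(unassigned)
    P <- pos[live, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rowSums(P^2), `+`) - 2 * P %*% t(P)
    counts <- rowSums(d2 <= r2)
    best <- max(counts)
    cand <- which(counts == best)
    # deterministic seed: earliest frame, then lowest atom index
    ord <- order(pt_frame[live[cand]], pt_atom[live[cand]])
    seed <- cand[ord[1]]
    members <- live[d2[seed, ] <= r2]
    occ_frames <- pt_frame[members]
    occupants <- rep(NA_integer_, nf)
    # nearest member wins a frame occupied by several waters
    seed_pos <- pos[live[seed], ]
    for (f in unique(occ_frames)) {
      m <- members[occ_frames == f]
      dd <- rowSums(sweep(pos[m, , drop = FALSE], 2, seed_pos)^2)
      occupants[f] <- a$residue_id[pt_atom[m[which.min(dd)]]]
    }
    sites[[length(sites) + 1L]] <- list(
      centroid = colMeans(pos[members, , drop = FALSE]),
      residency = length(unique(occ_frames)) / nf,
      occupants = occupants)
    unassigned[members] <- FALSE
  }
  res <- vapply(sites, function(s) s$residency, 1.0)
  sites <- sites[order(-res)]
  sites[vapply(sites, function(s) s$residency, 1.0) >= min_residency]
}

#' Distance from a water site to a reference water position
#'
#' Plain Euclidean distance between a site centroid and a reference
#' (e.g. crystallographic) water-oxygen position, both expressed in the
#' same pocket-aligned coordinates.
#'
#' @param site one element of [conserved_water_sites()] output
#' @param reference_water length-3 coordinates, Angstrom
#' @return distance in Angstrom
#' @export
compare_to_reference <- function(site, reference_water) {
  sqrt(sum((site$centroid - as.numeric(reference_water))^2))
}

#' Water-site TSV report
#' @param sites [conserved_water_sites()] output
#' @param path optional output file
#' @return character TSV lines (centroid, residency, mean exchange count)
#' @export
format_water_sites_tsv <- function(sites, path = NULL) {
  header <- paste("site", "x", "y", "z", "residency", "n_exchanges",
                  sep = "\t")
  body <- vapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    occ <- s$occupants[!is.na(s$occupants)]
    nex <- if (length(occ) > 1) sum(diff(occ) != 0) else 0L
    sprintf("%d\t%.4f\t%.4f\t%.4f\t%.6f\t%d", i, s$centroid[1],
            s$centroid[2], s$centroid[3], s$residency, nex)
  }, "")
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  lines
}
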