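#' Toy charge topology (RTF text) for the synthetic complex
#'
#' CHARMM-RTF-dialect text covering the four residue types of the toy
#' complex: `POC` (a pocket probe with an N-H donor and a carbonyl-like
#' acceptor), `5MC` (a flipped methylcytosine fragment: the 8 backbone
#' atoms plus a C5-methyl base stub), `TIP3` water, and `SER` (a serine
#' fragment whose hydroxyl charges the 5hmC patch copies: O -0.66, H
#' +0.43). ATOM lines carry the dialect's extra columns
#' (epsilon, Rmin/2, mass).
#'
#' @return character vector of RTF lines
#' @export
toy_charge_topology <- function() {
  c("* toy residue topology for the synthetic flipped-base complex",
    "RESI POC -0.67",
    "ATOM N    NH1  -0.47 0.20   1.85   14.007",
    "ATOM HN   H     0.31 0.046  0.2245  1.008",
    "ATOM O    O    -0.51 0.12   1.70   15.999",
    "BOND N HN",
    "DONO HN N",
    "ACCE O",
    "RESI 5MC -1.29",
    "ATOM P    P     1.50 0.585  2.15   30.974",
    "ATOM O1P  ON3  -0.78 0.12   1.70   15.999",
    "ATOM O2P  ON3  -0.78 0.12   1.70   15.999",
    "ATOM O5'  ON2  -0.57 0.1521 1.77   15.999",
    "ATOM C5'  CN8  -0.08 0.056  2.01   12.011",
    "ATOM C4'  CN7   0.16 0.02   2.275  12.011",
    "ATOM C3'  CN7   0.01 0.02   2.275  12.011",
    "ATOM O3'  ON2  -0.57 0.1521 1.77   15.999",
    "ATOM N1   NN2  -0.13 0.20   1.85   14.007",
    "ATOM C5   CN3  -0.05 0.09   1.90   12.011",
    "ATOM C5M  CN9  -0.27 0.078  2.04   12.011",
    "ATOM H51  HN9   0.09 0.024  1.34    1.008",
    "ATOM H52  HN9   0.09 0.024  1.34    1.008",
    "ATOM H53  HN9   0.09 0.024  1.34    1.008",
    "BOND P O1P P O2P P O5' O5' C5'",
    "BOND C5' C4' C4' C3' C3' O3' C4' N1",
    "BOND N1 C5 C5 C5M",
    "BOND C5M H51 C5M H52 C5M H53",
    "ACCE N1",
    "ACCE O1P",
    "ACCE O2P",
    "RESI TIP3 0.00",
    "ATOM OH2  OT   -0.834 0.1521 1.7682 15.999",
    "ATOM H1   HT    0.417 0.046  0.2245  1.008",
    "ATOM H2   HT    0.417 0.046  0.2245  1.008",
    "BOND OH2 H1 OH2 H2",
    "DONO H1 OH2",
    "DONO H2 OH2",
    "ACCE OH2",
    "RESI SER -0.18",
    "ATOM CB   CT2   0.05 0.056  2.01   12.011",
    "ATOM OG   OH1  -0.66 0.1521 1.77   15.999",
    "ATOM HG1  H     0.43 0.046  0.2245  1.008",
    "BOND CB OG OG HG1",
    "DONO HG1 OG",
    "ACCE OG")
}

#' Specification of a synthetic toy complex
#'
#' @param n_frames number of trajectory frames
#' @param dt frame spacing, ps (default 5, the monitoring interval)
#' @param n_waters number of explicit waters
#' @param hbond_schedule list of entries
#'   `list(donor = "chain:resid:name", acceptor = "chain:resid:name",
#'   frames = <1-based frame indices>)`; the donor's covalent hydrogen is
#'   resolved automatically and the acceptor atom is positioned to
#'   satisfy the default geometric criteria with margin (D-A 2.9
#'   Angstrom, angle 165 deg) during `frames` and to violate the distance
#'   criterion (4.6 Angstrom) elsewhere
#' @param water_schedule list of entries
#'   `list(water = <water residue_id>, site = <site number>, frames = ...)`;
#'   the water sits on the site center during `frames` and is parked in
#'   "bulk" (30+ Angstrom away) otherwise
#' @param fluctuation_sigmas per-atom Gaussian positional noise sd
#'   (Angstrom per coordinate); scalar or per-atom vector; default 0
#' @param seed RNG seed; generation is a pure function of (spec, seed)
#' @export
toy_complex_spec <- function(n_frames = 50, dt = 5, n_waters = 3,
                             hbond_schedule = list(),
                             water_schedule = list(),
                             fluctuation_sigmas = 0, seed = 1) {
  stopifnot(n_frames >= 1, dt > 0, n_waters >= 0)
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 n_waters = as.integer(n_waters),
                 hbond_schedule = hbond_schedule,
                 water_schedule = water_schedule,
                 fluctuation_sigmas = fluctuation_sigmas, seed = seed),
            class = "flipsite_toy_spec")
}

parse_atom_ref <- function(ref) {
  p <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(p) != 3) stop("atom reference must be 'chain:resid:name': ", ref)
  list(chain = p[1], residue_id = as.integer(p[2]), name = p[3])
}

resolve_atom <- function(top, ref) {
  r <- parse_atom_ref(ref)
  i <- atom_select(top, name = r$name, residue_id = r$residue_id,
                   chain = r$chain)
  if (length(i) != 1) stop("atom reference '", ref, "' matched ",
                           length(i), " atoms")
  i
}

# water-site centers available to the schedule (4 Angstrom apart, above
# the pocket plane, well separated from every pocket atom)
toy_site_centers <- function(n = 4) {
  t(vapply(seq_len(n), function(i) c(4 * (i - 1), 0, 3), numeric(3)))
}

#' Generate a synthetic toy complex with planted ground truth
#'
#' Builds a small flipped-base system: 7 pocket probe residues (N-H
#' donor + acceptor O each) on an 8 Angstrom ring, one central
#' methylcytosine fragment carrying the full 8-atom backbone set and a
#' patchable C5 methyl group, and `n_waters` explicit waters. Charges,
#' Lennard-Jones parameters, bonds and donor/acceptor roles come from
#' [toy_charge_topology()] through the regular merge path.
#'
#' Scheduled hydrogen bonds and water-site visits are planted
#' geometrically with comfortable margins around the default detection
#' criteria, so downstream occupancy analyses must recover the schedules
#' exactly; the returned `truth` record is the only place tests need to
#' read expectations from.
#'
#' @param spec a [toy_complex_spec()]
#' @return list with `topology`, `trajectory`, and `truth` (elements
#'   `hbonds`: data.frame-backed list of planted triplets with presence
#'   vectors; `waters`: planted site visits; `site_centers`;
#'   `expected_rmsf`)
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "flipsite_toy_spec"))
  nf <- spec$n_frames

  atoms <- list(); pos <- list()
  add_res <- function(chain, rid, rname, names, offsets, center) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = names, element = substr(sub("^[0-9]+", "", names), 1, 1),
      residue_name = rname, residue_id = rid, chain = chain,
      stringsAsFactors = FALSE)
    pos[[length(pos) + 1L]] <<- sweep(offsets, 2, -center)
  }

  # pocket ring: 7 probes on a circle of radius 8 in the z = 0 plane
  n_pocket <- 7L
  for (k in seq_len(n_pocket)) {
    th <- 2 * pi * (k - 1) / n_pocket
    ctr <- c(8 * cos(th), 8 * sin(th), 0)
    add_res("A", k, "POC", c("N", "HN", "O"),
            rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2)), ctr)
  }
  # central flipped nucleotide fragment
  nuc_names <- c("P", "O1P", "O2P", "O5'", "C5'", "C4'", "C3'", "O3'",
                 "N1", "C5", "C5M", "H51", "H52", "H53")
  nuc_off <- rbind(
    c(0.0, 0.0, -2.0), c(1.3, 0.6, -2.5), c(-1.3, 0.6, -2.5),
    c(0.0, -1.4, -2.6), c(0.6, -2.2, -1.6), c(0.0, -1.9, -0.3),
    c(0.8, -2.4, 0.9), c(0.4, -1.9, 2.2),
    c(0.0, 0.0, 0.0), c(0.0, 1.2, 0.7), c(0.0, 2.4, 0.0),
    c(0.9, 2.9, -0.4), c(-0.9, 2.9, -0.4), c(0.0, 2.2, -1.0))
  add_res("B", 10L, "5MC", nuc_names, nuc_off, c(0, 0, 0))
  # waters, parked in "bulk" until scheduled into a site
  bulk <- function(w) c(30 + 5 * w, 30, 30)
  for (w in seq_len(spec$n_waters)) {
    add_res("W", 100L + w, "TIP3", c("OH2", "H1", "H2"),
            rbind(c(0, 0, 0), c(0.7570, 0.5859, 0), c(-0.7570, 0.5859, 0)),
            bulk(w))
  }

  atom_df <- do.call(rbind, atoms)
  atom_df$is_water <- atom_df$residue_name == "TIP3"
  base_top <- topology(atom_df)
  top <- merge_charge_topology(base_top, read_charge_topology(toy_charge_topology()))
  base_xyz <- do.call(rbind, pos)
  n <- nrow(base_xyz)

  sites <- toy_site_centers()

  # validate + expand schedules
  check_frames <- function(fr, what) {
    fr <- as.integer(fr)
    if (length(fr) > 0 && (min(fr) < 1 || max(fr) > nf))
      stop(what, " schedule frames outside [1, ", nf, "]")
    fr
  }
  hb <- lapply(spec$hbond_schedule, function(e) {
    d <- resolve_atom(top, e$donor)
    acc <- resolve_atom(top, e$acceptor)
    hyd <- donor_hydrogen_pairs(top)
    h <- hyd[hyd[, "donor"] == d, "hydrogen"]
    if (length(h) != 1)
      stop("scheduled donor ", e$donor, " has ", length(h),
           " covalent hydrogens (need exactly 1)")
    list(donor = d, hydrogen = h, acceptor = acc,
         frames = check_frames(e$frames, "hbond"))
  })
  if (anyDuplicated(vapply(hb, function(e) e$acceptor, 1L)))
    stop("an acceptor atom may appear in at most one hbond schedule entry")
  wt <- lapply(spec$water_schedule, function(e) {
    o <- atom_select(top, name = "OH2", residue_id = e$water, chain = "W")
    if (length(o) != 1) stop("water residue ", e$water, " not found")
    if (e$site < 1 || e$site > nrow(sites))
      stop("site ", e$site, " does not exist")
    list(water = as.integer(e$water), o = o, site = as.integer(e$site),
         frames = check_frames(e$frames, "water"))
  })
  # infeasibility checks: one water per site per frame; one site per water
  occ_key <- unlist(lapply(wt, function(e) paste(e$site, e$frames)))
  if (anyDuplicated(occ_key))
    stop("infeasible water schedule: two waters in one site in one frame")
  wat_key <- unlist(lapply(wt, function(e) paste(e$water, e$frames)))
  if (anyDuplicated(wat_key))
    stop("infeasible water schedule: one water in two sites in one frame")

  # planted hydrogen-bond geometry (D-A 2.9 / angle 165 on, D-A 4.6 off)
  hb_positions <- lapply(seq_along(hb), function(k) {
    e <- hb[[k]]
    D <- base_xyz[e$donor, ]; H <- base_xyz[e$hydrogen, ]
    u_hd <- (D - H) / sqrt(sum((D - H)^2))
    # any unit vector at 165 deg from u_hd, rotated per entry about u_hd
    perp <- pick_perpendicular(u_hd)
    phi <- 2 * pi * (k - 1) / max(1, length(hb))
    perp <- perp * cos(phi) + cross3(u_hd, perp) * sin(phi)
    v <- cos(165 * pi / 180) * u_hd + sin(165 * pi / 180) * perp
    # solve |H + L v - D| = 2.9 for L > 0
    b <- -2 * sum(v * (D - H)); cc <- sum((D - H)^2) - 2.9^2
    L <- (-b + sqrt(b^2 - 4 * cc)) / 2
    A_on <- H + L * v
    u_da <- (A_on - D) / sqrt(sum((A_on - D)^2))
    list(on = A_on, off = D + 4.6 * u_da)
  })

  sigmas <- rep(spec$fluctuation_sigmas, length.out = n)
  set.seed(spec$seed)
  xyz <- array(0, dim = c(n, 3L, nf))
  wat_rows <- function(o) o + 0:2   # OH2, H1, H2 are contiguous
  for (i in seq_len(nf)) {
    x <- base_xyz
    for (k in seq_along(hb)) {
      e <- hb[[k]]
      x[e$acceptor, ] <- if (i %in% e$frames) hb_positions[[k]]$on
                         else hb_positions[[k]]$off
      # if the planted acceptor is a water oxygen, move the whole water
      if (top$atoms$is_water[e$acceptor]) {
        shift <- x[e$acceptor, ] - base_xyz[e$acceptor, ]
        rows <- wat_rows(e$acceptor)[-1]
        x[rows, ] <- sweep(base_xyz[rows, , drop = FALSE], 2, -shift)
      }
    }
    for (e in wt) {
      if (i %in% e$frames) {
        shift <- sites[e$site, ] - base_xyz[e$o, ]
        rows <- wat_rows(e$o)
        x[rows, ] <- sweep(base_xyz[rows, , drop = FALSE], 2, -shift)
      }
    }
    if (any(sigmas > 0))
      x <- x + matrix(rnorm(3 * n, sd = rep(sigmas, 3)), ncol = 3)
    xyz[, , i] <- x
  }
  traj <- trajectory(xyz, dt = spec$dt,
                     times = (seq_len(nf) - 1) * spec$dt)

  truth <- list(
    hbonds = lapply(hb, function(e) {
      pres <- rep(FALSE, nf); pres[e$frames] <- TRUE
      list(donor = e$donor, hydrogen = e$hydrogen, acceptor = e$acceptor,
           presence = pres, occupancy = mean(pres))
    }),
    waters = lapply(wt, function(e) {
      pres <- rep(FALSE, nf); pres[e$frames] <- TRUE
      list(water = e$water, site = e$site, center = sites[e$site, ],
           presence = pres, residency = mean(pres))
    }),
    site_centers = sites,
    expected_rmsf = sigmas * sqrt(3))
  list(topology = top, trajectory = traj, truth = truth)
}

pick_perpendicular <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(u, a)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Stationary Gaussian interaction-energy series with known truth
#'
#' I.i.d. Gaussian draws about fixed population means — the simplest
#' stationary stand-in for an equilibrated interaction-energy trace,
#' chosen so closed-form expectations are exact.
#'
#' @param mean_el,mean_vdw population means, kcal/mol
#' @param sd_el,sd_vdw population standard deviations (>= 0)
#' @param n number of frames (>= 1)
#' @param seed RNG seed
#' @param state_label series label
#' @param dt frame spacing, ps
#' @return list with `series` (an [energy_series()]) and `truth`
#'   (population means/sds)
#' @export
make_energy_series <- function(mean_el, mean_vdw, sd_el, sd_vdw, n,
                               seed = 1, state_label = "bound", dt = 5) {
  stopifnot(sd_el >= 0, sd_vdw >= 0, n >= 1)
  set.seed(seed)
  v_el <- rnorm(n, mean_el, sd_el)
  v_vdw <- rnorm(n, mean_vdw, sd_vdw)
  list(series = energy_series(state_label, (seq_len(n) - 1) * dt,
                              v_el, v_vdw),
       truth = list(mean_el = mean_el, mean_vdw = mean_vdw,
                    sd_el = sd_el, sd_vdw = sd_vdw))
}

#' Diffusive-fluctuation trajectory with known RMSF
#'
#' Frames are the base structure plus i.i.d. Gaussian displacement noise
#' with per-atom sigma per coordinate, so the expected RMSF of atom i is
#' `sigma_i * sqrt(3)`.
#'
#' @param base a [frame()] (base coordinates)
#' @param sigmas per-atom sd, Angstrom per coordinate (scalar recycled)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param dt frame spacing, ps
#' @return list with `trajectory` and `truth` (`expected_rmsf`)
#' @export
make_fluctuation_trajectory <- function(base, sigmas, n_frames, seed = 1,
                                        dt = 5) {
  n <- nrow(base$coordinates)
  sigmas <- rep(sigmas, length.out = n)
  stopifnot(all(sigmas >= 0), n_frames >= 1)
  set.seed(seed)
  xyz <- array(0, dim = c(n, 3L, n_frames))
  for (i in seq_len(n_frames)) {
    xyz[, , i] <- base$coordinates +
      matrix(rnorm(3 * n, sd = rep(sigmas, 3)), ncol = 3)
  }
  list(trajectory = trajectory(xyz, dt = dt,
                               times = (seq_len(n_frames) - 1) * dt),
       truth = list(expected_rmsf = sigmas * sqrt(3)))
}
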