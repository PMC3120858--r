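#' Nonbonded interaction scheme
#'
#' Direct-space pairwise scheme with CHARMM switching: interactions are
#' unmodified below `switch_start`, smoothly switched to zero between
#' `switch_start` and `cutoff`, and zero beyond. Defaults follow the 12/14
#' Angstrom switching setup. Energies computed under this scheme are
#' direct-space pair sums (no Ewald reciprocal term): LIE conventionally
#' uses pair-decomposable interaction energies, which lattice sums are
#' not. The scheme travels with every result as metadata.
#'
#' @param cutoff Angstrom, beyond which interactions are zero
#' @param switch_start Angstrom, where switching begins (must be below
#'   `cutoff`)
#' @param dielectric relative dielectric constant
#' @param combining_rule only `"lorentz-berthelot-charmm"`:
#'   `Rmin_ij = Rmin_i/2 + Rmin_j/2`, `eps_ij = sqrt(eps_i eps_j)`
#' @export
nonbonded_scheme <- function(cutoff = 14, switch_start = 12, dielectric = 1,
                             combining_rule = "lorentz-berthelot-charmm") {
  stopifnot(switch_start > 0, switch_start < cutoff,
            combining_rule == "lorentz-berthelot-charmm")
  structure(list(cutoff = cutoff, switch_start = switch_start,
                 dielectric = dielectric, combining_rule = combining_rule),
            class = "flipsite_nonbonded_scheme")
}

# CHARMM energy-switching function on r in [switch_start, cutoff]
charmm_switch <- function(r, scheme) {
  ron2 <- scheme$switch_start^2
  roff2 <- scheme$cutoff^2
  r2 <- r^2
  s <- ifelse(r2 <= ron2, 1,
       ifelse(r2 >= roff2, 0,
              (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) /
                (roff2 - ron2)^3))
  s
}

#' Pairwise nonbonded interaction energy between two atom groups
#'
#' Coulomb and Lennard-Jones energies summed over all inter-group pairs,
#' with CHARMM switching applied to both terms:
#' `v_el = sum 332.0636 q_i q_j / (eps_r r_ij) * S(r_ij)` and
#' `v_vdw = sum eps_ij ((Rmin_ij/r_ij)^12 - 2 (Rmin_ij/r_ij)^6) * S(r_ij)`.
#'
#' @param topology a [topology()] with charges and LJ parameters assigned
#'   for every atom of both groups
#' @param frame a [frame()]
#' @param group_a,group_b disjoint integer atom index sets
#' @param scheme a [nonbonded_scheme()]
#' @return named numeric `c(v_el = , v_vdw = )`, kcal/mol
#' @export
nonbonded_interaction <- function(topology, frame, group_a, group_b,
                                  scheme = nonbonded_scheme()) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("interaction groups must be disjoint")
  a <- topology$atoms
  need <- c(group_a, group_b)
  if (anyNA(a$charge[need]) || anyNA(a$lj_epsilon[need]) ||
      anyNA(a$lj_rmin_half[need]))
    stop("charges/LJ parameters missing for atoms in the groups")
  xa <- frame$coordinates[group_a, , drop = FALSE]
  xb <- frame$coordinates[group_b, , drop = FALSE]
  # pair distance matrix |A| x |B| from explicit displacements (the
  # expanded-norm shortcut loses ~1e-7 kcal/mol to cancellation)
  r2 <- outer(xa[, 1], xb[, 1], `-`)^2 +
    outer(xa[, 2], xb[, 2], `-`)^2 +
    outer(xa[, 3], xb[, 3], `-`)^2
  r <- sqrt(r2)
  if (any(r < 0.1))
    stop("atom pair at r < 0.1 Angstrom: steric clash or duplicated atom")
  S <- charmm_switch(r, scheme)
  live <- r < scheme$cutoff

  qq <- outer(a$charge[group_a], a$charge[group_b])
  v_el <- sum((COULOMB_KCAL * qq / (scheme$dielectric * r) * S)[live])

  epsij <- sqrt(outer(a$lj_epsilon[group_a], a$lj_epsilon[group_b]))
  rminij <- outer(a$lj_rmin_half[group_a], a$lj_rmin_half[group_b], `+`)
  sr6 <- (rminij / r)^6
  v_vdw <- sum((epsij * (sr6^2 - 2 * sr6) * S)[live])

  c(v_el = v_el, v_vdw = v_vdw)
}

#' Interaction-energy time series over a trajectory window
#'
#' One `(v_el, v_vdw)` evaluation per frame whose time lies in `window`
#' (inclusive). Window restriction is first-class because the free-energy
#' estimate averages over an equilibrated tail (e.g. the last 10 ns) of a
#' longer trajectory.
#'
#' @param trajectory a [trajectory()]
#' @param topology a [topology()] with parameters
#' @param group_a,group_b disjoint atom index sets
#' @param scheme a [nonbonded_scheme()]
#' @param window numeric `c(t_min, t_max)` in ps (default: all frames)
#' @param state_label label carried into the series
#' @return an [energy_series()] with `meta` recording window and scheme
#' @export
interaction_series <- function(trajectory, topology, group_a, group_b,
                               scheme = nonbonded_scheme(), window = NULL,
                               state_label = "bound") {
  if (is.null(window)) window <- range(trajectory$times)
  sel <- which(trajectory$times >= window[1] & trajectory$times <= window[2])
  if (length(sel) == 0) stop("window selects no frames")
  v_el <- numeric(length(sel)); v_vdw <- numeric(length(sel))
  for (k in seq_along(sel)) {
    v <- nonbonded_interaction(topology, get_frame(trajectory, sel[k]),
                               group_a, group_b, scheme)
    v_el[k] <- v["v_el"]; v_vdw[k] <- v["v_vdw"]
  }
  energy_series(state_label, trajectory$times[sel], v_el, v_vdw,
                meta = list(window = window, scheme = scheme))
}

#' Select frames of an energy series falling in the last `ns` nanoseconds
#' @param series an [energy_series()]
#' @param ns tail length in nanoseconds
#' @return an [energy_series()] restricted to `t > t_end - ns*1000`
#' @export
series_last_ns <- function(series, ns) {
  t_end <- max(series$times)
  keep <- series$times > t_end - ns * 1000
  energy_series(series$state_label, series$times[keep], series$v_el[keep],
                series$v_vdw[keep],
                meta = c(series$meta, list(tail_ns = ns)))
}

#' Linear Interaction Energy binding free energy
#'
#' `dG = alpha * (<v_el>_bound - <v_el>_free) +
#'       beta * (<v_vdw>_bound - <v_vdw>_free)`,
#' the linear-response approximation with default weights `alpha = 1`,
#' `beta = 0.5`. A block-averaging standard error (default 5 blocks per
#' series, combined in quadrature across states) is attached as metadata.
#'
#' @param bound,free [energy_series()] objects
#' @param alpha weight on the electrostatic term
#' @param beta weight on the van-der-Waals term
#' @param n_blocks blocks for the uncertainty estimate
#' @return object of class `flipsite_lie`: `alpha`, `beta`,
#'   `mean_v_el_bound`, `mean_v_vdw_bound`, `mean_v_el_free`,
#'   `mean_v_vdw_free`, `delta_g`, `se_delta_g`, `n_frames_used`, `window`
#' @export
lie_delta_g <- function(bound, free, alpha = 1, beta = 0.5, n_blocks = 5) {
  for (s in list(bound, free)) {
    if (length(s$v_el) == 0) stop("empty energy series")
    if (anyNA(s$v_el) || anyNA(s$v_vdw)) {
      bad <- which(is.na(s$v_el) | is.na(s$v_vdw))[1]
      stop("NaN energy in ", s$state_label, " series at frame ", bad)
    }
  }
  m <- list(el_b = mean(bound$v_el), vdw_b = mean(bound$v_vdw),
            el_f = mean(free$v_el), vdw_f = mean(free$v_vdw))
  dg <- alpha * (m$el_b - m$el_f) + beta * (m$vdw_b - m$vdw_f)
  se <- sqrt(block_se(alpha * bound$v_el + beta * bound$v_vdw, n_blocks)^2 +
             block_se(alpha * free$v_el + beta * free$v_vdw, n_blocks)^2)
  structure(list(
    alpha = alpha, beta = beta,
    mean_v_el_bound = m$el_b, mean_v_vdw_bound = m$vdw_b,
    mean_v_el_free = m$el_f, mean_v_vdw_free = m$vdw_f,
    delta_g = dg, se_delta_g = se,
    n_frames_used = length(bound$v_el) + length(free$v_el),
    window = list(bound = range(bound$times), free = range(free$times))),
    class = "flipsite_lie")
}

# standard error of the mean from contiguous block averages
block_se <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n < 2 * n_blocks) return(NA_real_)
  size <- floor(n / n_blocks)
  idx <- rep(seq_len(n_blocks), each = size)
  means <- tapply(x[seq_along(idx)], idx, mean)
  sd(means) / sqrt(n_blocks)
}

#' @export
print.flipsite_lie <- function(x, ...) {
  cat(sprintf(
    "<LIE> dG = %.3f +/- %.3f kcal/mol (alpha = %g, beta = %g, %d frames)\n",
    x$delta_g, x$se_delta_g, x$alpha, x$beta, x$n_frames_used))
  invisible(x)
}

#' Binding free-energy difference between two complexes
#'
#' `ddG = dG(reference complex) - dG(variant complex)`; negative values
#' mean the variant binds more favorably under the same weights.
#'
#' @param res_ref,res_var [lie_delta_g()] results (same alpha/beta)
#' @param region_label `"whole"` or `"pocket"`, propagated verbatim
#' @return object of class `flipsite_ddg`: `delta_g_ref`, `delta_g_var`,
#'   `ddg`, `region_label`
#' @export
ddg <- function(res_ref, res_var, region_label = "whole") {
  if (res_ref$alpha != res_var$alpha || res_ref$beta != res_var$beta)
    stop("ddG requires matching alpha/beta weights")
  structure(list(delta_g_ref = res_ref$delta_g,
                 delta_g_var = res_var$delta_g,
                 ddg = res_ref$delta_g - res_var$delta_g,
                 se = sqrt(res_ref$se_delta_g^2 + res_var$se_delta_g^2),
                 region_label = region_label),
            class = "flipsite_ddg")
}

#' @export
print.flipsite_ddg <- function(x, ...) {
  cat(sprintf("<ddG %s> %.3f kcal/mol (ref %.3f - var %.3f)\n",
              x$region_label, x$ddg, x$delta_g_ref, x$delta_g_var))
  invisible(x)
}

#' Residue-level pocket selection around a target residue
#'
#' A residue is included iff any of its atoms lies within `cutoff` of any
#' atom of the target residue in the supplied (starting) frame; the
#' selection is then fixed, so downstream analyses use
#' starting-conformation semantics. The target residue is always
#' included.
#'
#' @param topology a [topology()]
#' @param frame0 the starting [frame()]
#' @param chain,residue_id target residue address
#' @param cutoff Angstrom (default 15)
#' @return integer atom indices covering whole residues
#' @export
pocket_selection <- function(topology, frame0, chain, residue_id,
                             cutoff = 15) {
  res <- residue_table(topology)
  r <- which(res$chain == chain & res$residue_id == residue_id)
  if (length(r) != 1)
    stop("target residue ", chain, ":", residue_id, " not found")
  tgt <- res$first_atom[r]:res$last_atom[r]
  xyz <- frame0$coordinates
  xt <- xyz[tgt, , drop = FALSE]
  keep <- integer(0)
  for (k in seq_len(nrow(res))) {
    idx <- res$first_atom[k]:res$last_atom[k]
    if (k == r) { keep <- c(keep, idx); next }
    if (is.infinite(cutoff)) { keep <- c(keep, idx); next }
    xk <- xyz[idx, , drop = FALSE]
    d2 <- outer(rowSums(xk^2), rowSums(xt^2), `+`) - 2 * xk %*% t(xt)
    if (min(d2) <= cutoff^2) keep <- c(keep, idx)
  }
  sort(keep)
}

#' DNA backbone restraint selection for the flipped state
#'
#' Selects exactly the atoms whose names are in the 8-name backbone set
#' (`C4'`, `P`, `O1P`, `O2P`, `O5'`, `C5'`, `C3'`, `O3'`) within the
#' given chains — the atoms harmonically restrained to keep a free DNA in
#' the flipped conformation. Terminal nucleotides naturally contribute
#' fewer atoms.
#'
#' @param topology a [topology()]
#' @param dna_chains chain identifiers treated as DNA
#' @return data.frame `index`, `name`, `chain`, `residue_id`,
#'   `force_constant` (placeholder column, `NA`, for a restraint spec
#'   file); zero rows with a warning if nothing matches
#' @export
flipped_backbone_selection <- function(topology, dna_chains) {
  a <- topology$atoms
  hit <- which(a$chain %in% dna_chains & a$name %in% DNA_BACKBONE_ATOMS)
  if (length(hit) == 0)
    warning("no DNA backbone atoms found in chain(s) ",
            paste(dna_chains, collapse = ", "))
  data.frame(index = hit, name = a$name[hit], chain = a$chain[hit],
             residue_id = a$residue_id[hit],
             force_constant = rep(NA_real_, length(hit)))
}
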