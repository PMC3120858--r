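# two-atom fixture with controllable charges/LJ at distance r
pair_system <- function(r, q = c(1, -1), eps = c(0.1, 0.1),
                        rmin_half = c(1.5, 1.5)) {
  atoms <- data.frame(
    name = c("A", "B"), element = "C", residue_name = c("LIG", "PRT"),
    residue_id = c(1, 2), chain = c("L", "P"),
    charge = q, lj_epsilon = eps, lj_rmin_half = rmin_half, mass = 12,
    stringsAsFactors = FALSE)
  list(topology = topology(atoms),
       frame = frame(rbind(c(0, 0, 0), c(r, 0, 0))))
}

test_that("Coulomb term reproduces the pinned constant and the LJ term
           its analytic minimum", {
  sys <- pair_system(1.0)
  v <- nonbonded_interaction(sys$topology, sys$frame, 1, 2)
  expect_equal(unname(v["v_el"]), -332.0636, tolerance = 1e-12)

  # at r = Rmin_ij the LJ well depth is exactly -eps_ij
  sys2 <- pair_system(3.0, q = c(0, 0), eps = c(0.2, 0.05),
                      rmin_half = c(1.5, 1.5))
  v2 <- nonbonded_interaction(sys2$topology, sys2$frame, 1, 2)
  expect_equal(unname(v2["v_vdw"]), -sqrt(0.2 * 0.05), tolerance = 1e-12)
  expect_equal(unname(v2["v_el"]), 0)

  # dielectric scales the electrostatic term only
  v3 <- nonbonded_interaction(sys$topology, sys$frame, 1, 2,
                              nonbonded_scheme(dielectric = 4))
  expect_equal(unname(v3["v_el"]), -332.0636 / 4, tolerance = 1e-12)
})

test_that("group energies equal the naive double-loop oracle to 1e-10", {
  for (k in 1:5) {
    sys <- make_random_charged_system(n = 100, seed = 40 + k)
    ga <- which(sys$topology$atoms$residue_id == 1)
    gb <- which(sys$topology$atoms$residue_id == 2)
    scheme <- nonbonded_scheme()
    got <- nonbonded_interaction(sys$topology, sys$frame, ga, gb, scheme)
    want <- oracle_nonbonded(sys$topology, sys$frame, ga, gb, scheme)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("electrostatics are linear in any single charge and the energy
           is symmetric under group exchange", {
  sys <- make_random_charged_system(n = 60, seed = 77)
  ga <- 1:30; gb <- 31:60
  v1 <- nonbonded_interaction(sys$topology, sys$frame, ga, gb)
  v2 <- nonbonded_interaction(sys$topology, sys$frame, gb, ga)
  expect_equal(v1, v2, tolerance = 1e-12)
  scaled <- sys$topology
  scaled$atoms$charge[5] <- 2 * scaled$atoms$charge[5]
  v3 <- nonbonded_interaction(scaled, sys$frame, ga, gb)
  # doubling q5 doubles exactly q5's contribution
  only5 <- nonbonded_interaction(sys$topology, sys$frame, 5, gb)
  expect_equal(unname(v3["v_el"] - v1["v_el"]), unname(only5["v_el"]),
               tolerance = 1e-9)
  expect_error(nonbonded_interaction(sys$topology, sys$frame, 1:30, 30:60),
               "disjoint")
  clash <- pair_system(0.05)
  expect_error(nonbonded_interaction(clash$topology, clash$frame, 1, 2),
               "clash")
})

test_that("the switching function is continuous at the switch radius and
           zero beyond the cutoff", {
  scheme <- nonbonded_scheme(cutoff = 14, switch_start = 12)
  sys <- pair_system(1.0)
  r <- seq(10, 15, by = 1e-3)
  v <- vapply(r, function(ri) {
    fr <- frame(rbind(c(0, 0, 0), c(ri, 0, 0)))
    unname(nonbonded_interaction(sys$topology, fr, 1, 2, scheme)["v_el"])
  }, 1.0)
  expect_true(all(v[r >= 14] == 0))
  # numeric continuity scan: adjacent 1e-3 steps never jump
  expect_lt(max(abs(diff(v))), 0.05)
  # switching inactive below switch_start: bare Coulomb there
  i <- which.min(abs(r - 11.5))
  expect_equal(v[i], -332.0636 / r[i], tolerance = 1e-12)
})

test_that("windowing: the last 10 ns of a 57 ns series at 5 ps spacing is
           exactly 2000 frames", {
  n <- 57000 / 5 + 1  # 0, 5, ..., 57000 ps
  es <- energy_series("bound", seq(0, 57000, by = 5), rnorm(n), rnorm(n))
  tail10 <- series_last_ns(es, 10)
  expect_equal(length(tail10$v_el), 2000)
  expect_equal(min(tail10$times), 47005)
  expect_equal(max(tail10$times), 57000)
})

test_that("interaction series over a constant-geometry trajectory is
           constant and matches the frame-wise oracle mean", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 6))
  dna <- atom_select(tc$topology, chain = "B")
  rest <- setdiff(seq_len(n_atoms(tc$topology)), dna)
  es <- interaction_series(tc$trajectory, tc$topology, dna, rest)
  expect_equal(length(es$v_el), 6)
  expect_true(all(abs(es$v_el - es$v_el[1]) < 1e-12))

  jc <- make_toy_complex(toy_complex_spec(n_frames = 6,
                                          fluctuation_sigmas = 0.1,
                                          seed = 2))
  es2 <- interaction_series(jc$trajectory, jc$topology, dna, rest)
  oracle_means <- colMeans(t(vapply(1:6, function(i)
    oracle_nonbonded(jc$topology, get_frame(jc$trajectory, i), dna, rest,
                     nonbonded_scheme()), c(v_el = 0, v_vdw = 0))))
  expect_equal(c(mean(es2$v_el), mean(es2$v_vdw)),
               unname(oracle_means), tolerance = 1e-10)
  expect_error(interaction_series(tc$trajectory, tc$topology, dna, rest,
                                  window = c(1e6, 2e6)), "window")
})

test_that("LIE closed form, degenerate weights, and linearity in alpha
           and beta", {
  bound <- energy_series("bound", 0:9, rep(-10, 10), rep(-4, 10))
  free <- energy_series("free", 0:9, rep(-2, 10), rep(-1, 10))
  res <- lie_delta_g(bound, free)
  expect_equal(res$delta_g, -9.5, tolerance = 1e-12)
  expect_equal(res$mean_v_el_bound, -10)
  expect_equal(res$mean_v_vdw_free, -1)
  # stored-invariant identity
  expect_identical(res$delta_g,
                   res$alpha * (res$mean_v_el_bound - res$mean_v_el_free) +
                     res$beta * (res$mean_v_vdw_bound - res$mean_v_vdw_free))

  expect_equal(lie_delta_g(bound, free, alpha = 0, beta = 0)$delta_g, 0)
  expect_equal(lie_delta_g(bound, bound)$delta_g, 0)

  # finite differences in alpha and beta are exactly the mean gaps
  da <- lie_delta_g(bound, free, alpha = 1.5)$delta_g -
    lie_delta_g(bound, free, alpha = 0.5)$delta_g
  expect_equal(da, 1.0 * (-10 - -2), tolerance = 1e-12)
  db <- lie_delta_g(bound, free, beta = 1)$delta_g -
    lie_delta_g(bound, free, beta = 0)$delta_g
  expect_equal(db, 1.0 * (-4 - -1), tolerance = 1e-12)

  nan_series <- bound
  nan_series$v_el[3] <- NaN
  expect_error(lie_delta_g(nan_series, free), "frame 3")
})

test_that("ddG is the difference of the two complexes' LIE estimates", {
  b1 <- energy_series("bound", 0:9, rep(-10, 10), rep(-4, 10))
  f1 <- energy_series("free", 0:9, rep(-2, 10), rep(-1, 10))
  b2 <- energy_series("bound", 0:9, rep(-3, 10), rep(-2, 10))
  f2 <- energy_series("free", 0:9, rep(-1, 10), rep(-2, 10))
  g1 <- lie_delta_g(b1, f1)   # -9.5
  g2 <- lie_delta_g(b2, f2)   # -2.0
  d <- ddg(g1, g2, region_label = "pocket")
  expect_equal(d$ddg, -7.5)
  expect_identical(d$region_label, "pocket")
  expect_equal(ddg(g1, g1)$ddg, 0)
  g3 <- lie_delta_g(b2, f2, alpha = 0.8)
  expect_error(ddg(g1, g3), "alpha")
})

test_that("LIE recovers planted population means within CLT bounds", {
  n <- 10000
  b <- make_energy_series(-10, -4, 2, 1, n, seed = 21, state_label = "bound")
  f <- make_energy_series(-2, -1, 2, 1, n, seed = 22, state_label = "free")
  res <- lie_delta_g(b$series, f$series)
  truth <- 1 * (-10 - -2) + 0.5 * (-4 - -1)
  analytic_se <- sqrt((2^2 + 0.5^2 * 1^2) / n * 2)
  expect_lt(abs(res$delta_g - truth), 3 * analytic_se)
  expect_gt(res$se_delta_g, 0)
})

test_that("pocket selection honors starting-conformation shells", {
  # planted shells: residues at 10 / 14 / 16 Angstrom from the target
  atoms <- data.frame(
    name = rep("CA", 4), element = "C",
    residue_name = c("TGT", "R10", "R14", "R16"), residue_id = 1:4,
    chain = "A", stringsAsFactors = FALSE)
  top <- topology(atoms)
  fr <- frame(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 14, 0), c(0, 0, 16)))
  sel15 <- pocket_selection(top, fr, "A", 1, cutoff = 15)
  expect_identical(sel15, c(1L, 2L, 3L))
  expect_identical(pocket_selection(top, fr, "A", 1, cutoff = 0), 1L)
  expect_identical(pocket_selection(top, fr, "A", 1, cutoff = Inf), 1:4)
  expect_error(pocket_selection(top, fr, "A", 9, cutoff = 15), "not found")
  # whole residues enter: a residue with one atom inside pulls in all
  tc <- make_toy_complex(toy_complex_spec(n_frames = 1))
  sel <- pocket_selection(tc$topology, get_frame(tc$trajectory, 1),
                          "B", 10, cutoff = 12)
  res <- residue_table(tc$topology)
  for (r in seq_len(nrow(res))) {
    idx <- res$first_atom[r]:res$last_atom[r]
    expect_true(all(idx %in% sel) || !any(idx %in% sel))
  }
})

test_that("flipped-backbone restraint selection is exactly the 8-name set", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 1))
  sel <- flipped_backbone_selection(tc$topology, "B")
  expect_setequal(sel$name,
                  c("C4'", "P", "O1P", "O2P", "O5'", "C5'", "C3'", "O3'"))
  expect_equal(nrow(sel), 8)
  # a 5'-terminal nucleotide missing P/O1P/O2P/O5' contributes 4 atoms
  keep <- !(tc$topology$atoms$chain == "B" &
              tc$topology$atoms$name %in% c("P", "O1P", "O2P", "O5'"))
  term_atoms <- tc$topology$atoms[keep, ]
  bmap <- cumsum(keep)
  old_b <- tc$topology$bonds
  ok <- keep[old_b[, 1]] & keep[old_b[, 2]]
  term <- topology(term_atoms, cbind(bmap[old_b[ok, 1]],
                                     bmap[old_b[ok, 2]]))
  expect_equal(nrow(flipped_backbone_selection(term, "B")), 4)
  expect_warning(out <- flipped_backbone_selection(tc$topology, "A"),
                 "no DNA backbone")
  expect_equal(nrow(out), 0)
})
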