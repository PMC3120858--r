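# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately reimplement the science with different code paths
# (plain loops, BFS, quaternions) so agreement is informative.

# --- exhaustive hydrogen-bond oracle: every (D, H, A) triplet, no pruning ---
oracle_detect_hbonds <- function(top, fr, criteria) {
  a <- top$atoms
  xyz <- fr$coordinates
  b <- top$bonds
  n <- nrow(a)
  adj <- lapply(seq_len(n), function(i)
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1]))
  graph_dist_le2 <- function(i, j) {
    if (j %in% adj[[i]]) return(TRUE)
    any(vapply(adj[[i]], function(k) j %in% adj[[k]], TRUE))
  }
  hits <- list()
  for (d in which(a$is_donor)) {
    for (h in which(a$is_hydrogen)) {
      if (!(h %in% adj[[d]])) next           # H must be covalent to D
      for (acc in which(a$is_acceptor)) {
        if (acc == d) next
        if (graph_dist_le2(d, acc)) next
        rda <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
        if (rda > criteria$max_da_distance) next
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[acc, ] - xyz[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang < criteria$min_dha_angle) next
        hits[[length(hits) + 1L]] <- c(d, h, acc)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  m <- unique(do.call(rbind, hits))
  out <- data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- random small molecules with donor/acceptor roles, for oracle tests ---
make_random_hbond_system <- function(n_mol = 15, box = 10, seed = 1) {
  set.seed(seed)
  rows <- list(); bonds <- list(); xyz <- list()
  idx <- 0L
  rand_unit <- function() {
    v <- rnorm(3); v / sqrt(sum(v^2))
  }
  add <- function(name, elem, rid, donor, hyd, acc) {
    idx <<- idx + 1L
    rows[[idx]] <<- data.frame(name = name, element = elem,
                               residue_name = "MOL", residue_id = rid,
                               chain = "X", is_donor = donor,
                               is_hydrogen = hyd, is_acceptor = acc,
                               is_water = FALSE, stringsAsFactors = FALSE)
    idx
  }
  for (m in seq_len(n_mol)) {
    p <- runif(3, 0, box)
    kind <- sample(c("water", "donor", "acceptor", "branched"), 1)
    if (kind == "water") {
      o <- add("O", "O", m, TRUE, FALSE, TRUE)
      h1 <- add("H1", "H", m, FALSE, TRUE, FALSE)
      h2 <- add("H2", "H", m, FALSE, TRUE, FALSE)
      xyz[[o]] <- p; xyz[[h1]] <- p + rand_unit(); xyz[[h2]] <- p + rand_unit()
      bonds[[length(bonds) + 1L]] <- rbind(c(o, h1), c(o, h2))
    } else if (kind == "donor") {
      d <- add("N", "N", m, TRUE, FALSE, FALSE)
      h <- add("HN", "H", m, FALSE, TRUE, FALSE)
      xyz[[d]] <- p; xyz[[h]] <- p + rand_unit()
      bonds[[length(bonds) + 1L]] <- rbind(c(d, h))
    } else if (kind == "acceptor") {
      o <- add("O", "O", m, FALSE, FALSE, TRUE)
      xyz[[o]] <- p
    } else {
      # C(-O2)(-O1-H): donor hydroxyl with an acceptor 2 bonds away,
      # exercising the covalent exclusion rule
      cc <- add("C", "C", m, FALSE, FALSE, FALSE)
      o1 <- add("O1", "O", m, TRUE, FALSE, TRUE)
      h <- add("HO", "H", m, FALSE, TRUE, FALSE)
      o2 <- add("O2", "O", m, FALSE, FALSE, TRUE)
      xyz[[cc]] <- p
      xyz[[o1]] <- p + 1.4 * rand_unit()
      xyz[[h]] <- xyz[[o1]] + rand_unit()
      xyz[[o2]] <- p + 1.3 * rand_unit()
      bonds[[length(bonds) + 1L]] <- rbind(c(cc, o1), c(o1, h), c(cc, o2))
    }
  }
  top <- topology(do.call(rbind, rows), do.call(rbind, bonds))
  list(topology = top, frame = frame(do.call(rbind, xyz)))
}

# --- quaternion (Horn) superposition: independent optimal-rmsd route ---
oracle_rmsd_quaternion <- function(reference, mobile) {
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  n <- nrow(P)
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * lam) / n))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# --- naive double-loop nonbonded oracle (no vectorization, no masks) ---
oracle_nonbonded <- function(top, fr, ga, gb, scheme) {
  a <- top$atoms
  xyz <- fr$coordinates
  sw <- function(r) {
    ron2 <- scheme$switch_start^2; roff2 <- scheme$cutoff^2; r2 <- r * r
    if (r2 <= ron2) 1
    else if (r2 >= roff2) 0
    else (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  v_el <- 0; v_vdw <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r >= scheme$cutoff) next
    s <- sw(r)
    v_el <- v_el + 332.0636 * a$charge[i] * a$charge[j] /
      (scheme$dielectric * r) * s
    eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
    rmin <- a$lj_rmin_half[i] + a$lj_rmin_half[j]
    v_vdw <- v_vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6) * s
  }
  c(v_el = v_el, v_vdw = v_vdw)
}

# random parameterized atom cloud for nonbonded oracle tests; a 2 A
# minimum separation keeps LJ terms in a physically plausible range
make_random_charged_system <- function(n = 100, box = 20, seed = 1) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n, 0, box), ncol = 3)
  repeat {
    d <- as.matrix(dist(xyz))
    diag(d) <- 10
    clash <- which(d < 2.0, arr.ind = TRUE)
    if (nrow(clash) == 0) break
    xyz[clash[1, 1], ] <- runif(3, 0, box)
  }
  atoms <- data.frame(
    name = paste0("X", seq_len(n)), element = "C",
    residue_name = "LIG", residue_id = rep(1:2, each = n / 2), chain = "X",
    charge = runif(n, -1, 1), lj_epsilon = runif(n, 0.01, 0.3),
    lj_rmin_half = runif(n, 1.2, 2.3), mass = 12,
    stringsAsFactors = FALSE)
  list(topology = topology(atoms), frame = frame(xyz))
}

expect_same_bond_set <- function(got, want) {
  key <- function(df) paste(df$donor, df$hydrogen, df$acceptor, sep = "-")
  expect_setequal(key(got), key(want))
}
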