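# hand-written mini fixture: 2 residues protein-like, 1 water, 8 atoms
mini_pdb <- c(
  "REMARK hand-built fixture",
  "ATOM      1  N   GLY A   4       1.000   2.000   3.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   4       2.450   2.000   3.000  1.00  0.00           C",
  "ATOM      3  O   GLY A   4       3.100   0.900   3.000  1.00  0.00           O",
  "ATOM      4  P   DC  B  12      -4.250   1.125   0.500  1.00  0.00           P",
  "ATOM      5  O1P DC  B  12      -5.500   1.900   0.750  1.00  0.00           O",
  "ATOM      6  C4' DC  B  12      -3.800  -0.250   1.900  1.00  0.00           C",
  "HETATM    7  O   HOH W 101      10.000  10.000  10.000  1.00  0.00           O",
  "HETATM    8  H1  HOH W 101      10.760  10.590  10.000  1.00  0.00           H",
  "END")

test_that("ATOM records parse verbatim: names, residues, coordinates", {
  parsed <- read_structure(mini_pdb)
  top <- parsed$topology
  expect_equal(n_atoms(top), 8)
  # character-level reference parse, transcribed by hand from the fixture
  expect_identical(top$atoms$name,
                   c("N", "CA", "O", "P", "O1P", "C4'", "O", "H1"))
  expect_identical(top$atoms$residue_name,
                   c("GLY", "GLY", "GLY", "DC", "DC", "DC", "HOH", "HOH"))
  expect_identical(top$atoms$residue_id,
                   c(4L, 4L, 4L, 12L, 12L, 12L, 101L, 101L))
  expect_identical(top$atoms$chain, c("A", "A", "A", "B", "B", "B", "W", "W"))
  expect_identical(top$atoms$is_water, c(rep(FALSE, 6), TRUE, TRUE))
  expect_equal(parsed$frames[[1]]$coordinates[1, ], c(1, 2, 3))
  expect_equal(parsed$frames[[1]]$coordinates[6, ], c(-3.8, -0.25, 1.9))
  res <- residue_table(top)
  expect_equal(res$n_atoms, c(3L, 3L, 2L))
  # charges unset until a charge topology is merged
  expect_true(all(is.na(top$atoms$charge)))
})

test_that("malformed and empty PDB input raise informative errors", {
  bad <- mini_pdb
  bad[3] <- sub("2.450", "2.4X5", bad[3], fixed = TRUE)
  expect_error(read_structure(bad), "line 3")
  expect_error(read_structure(c("REMARK nothing", "END")), "empty")
})

test_that("MODEL blocks become frames over one shared topology", {
  body <- mini_pdb[2:9]
  multi <- c("MODEL        1", body, "ENDMDL",
             "MODEL        2", sub("1.000   2.000   3.000",
                                   "1.500   2.000   3.000", body,
                                   fixed = TRUE), "ENDMDL", "END")
  parsed <- read_structure(multi)
  expect_length(parsed$frames, 2)
  expect_equal(n_atoms(parsed$topology), 8)
  expect_equal(parsed$frames[[2]]$coordinates[1, 1], 1.5)
  expect_equal(parsed$frames[[1]]$coordinates[1, 1], 1.0)
})

test_that("unicode primes in atom names are normalized to apostrophes", {
  ln <- mini_pdb[7]
  substr(ln, 13, 16) <- "C4′ "
  expect_message(parsed <- read_structure(c(ln, "END")), "prime")
  expect_identical(parsed$topology$atoms$name, "C4'")
})

test_that("write/read round trip preserves structure to PDB precision", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 1, seed = 7))
  fr <- get_frame(tc$trajectory, 1)
  txt <- write_structure(tc$topology, fr)
  back <- read_structure(txt)
  expect_identical(back$topology$atoms$name, tc$topology$atoms$name)
  expect_identical(back$topology$atoms$residue_id,
                   tc$topology$atoms$residue_id)
  expect_identical(residue_table(back$topology)$residue_name,
                   residue_table(tc$topology)$residue_name)
  expect_lt(max(abs(back$frames[[1]]$coordinates - fr$coordinates)), 1e-3)
})

test_that("internal PDB parser agrees with bio3d on the same file", {
  skip_if_not_installed("bio3d")
  tc <- make_toy_complex(toy_complex_spec(n_frames = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(write_structure(tc$topology, get_frame(tc$trajectory, 1)), path)
  ours <- read_structure(path)
  ref <- bio3d::read.pdb(path)
  expect_equal(unname(matrix(ref$xyz, ncol = 3, byrow = TRUE)),
               ours$frames[[1]]$coordinates, tolerance = 1e-6)
  expect_identical(trimws(ref$atom$resid), ours$topology$atoms$residue_name)
  expect_identical(as.integer(ref$atom$resno), ours$topology$atoms$residue_id)
})

test_that("RTF residue blocks parse to per-residue parameter tables", {
  rtf <- read_charge_topology(c(
    "* three-residue fixture",
    "RESI AAA 0.00",
    "ATOM A1 XT  0.10",
    "ATOM A2 XT -0.10",
    "BOND A1 A2",
    "RESI BBB 0.33",
    "ATOM B1 YT  0.13 0.25 1.9 14.0",
    "ATOM B2 YT  0.20",
    "BOND B1 B2",
    "DONO B2 B1",
    "ACCE B1",
    "RESI SER -0.23",
    "ATOM OG OH1 -0.66",
    "ATOM HG1 H   0.43",
    "BOND OG HG1",
    "DONO HG1 OG"))
  expect_named(rtf, c("AAA", "BBB", "SER"))
  expect_equal(residue_net_charge(rtf$AAA), 0.0)
  # hand-built reference for the fully parameterized atom
  expect_equal(rtf$BBB$atoms$charge, c(0.13, 0.20))
  expect_equal(rtf$BBB$atoms$lj_epsilon[1], 0.25)
  expect_equal(rtf$BBB$atoms$lj_rmin_half[1], 1.9)
  expect_equal(rtf$BBB$atoms$mass[1], 14.0)
  expect_identical(rtf$BBB$donors$heavy, "B1")
  expect_identical(rtf$BBB$acceptors, "B1")
  # serine hydroxyl charge pair retrievable by atom name
  expect_equal(rtf$SER$atoms$charge[rtf$SER$atoms$name == "OG"], -0.66)
  expect_equal(rtf$SER$atoms$charge[rtf$SER$atoms$name == "HG1"], 0.43)
})

test_that("RTF parse errors: non-numeric charge, duplicate atom name", {
  expect_error(read_charge_topology(c("RESI X 0.0", "ATOM A1 XT q")),
               "non-numeric charge")
  expect_error(read_charge_topology(c("RESI X 0.0", "ATOM A1 XT 0.1",
                                      "ATOM A1 XT 0.2")),
               "duplicate atom name")
})

test_that("charge merge assigns every atom without reordering, or raises", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 1))
  bare <- read_structure(write_structure(tc$topology,
                                         get_frame(tc$trajectory, 1)))
  merged <- merge_charge_topology(bare$topology,
                                  read_charge_topology(toy_charge_topology()))
  expect_identical(merged$atoms$name, bare$topology$atoms$name)
  expect_false(anyNA(merged$atoms$charge))
  expect_equal(merged$atoms$charge, tc$topology$atoms$charge)
  expect_true(any(merged$atoms$is_donor) && any(merged$atoms$is_acceptor))
  # unknown residue in the structure -> error rather than silent NA
  bad <- bare$topology
  bad$atoms$residue_name[1:3] <- "ZZZ"
  expect_error(merge_charge_topology(bad, read_charge_topology(
    toy_charge_topology())), "ZZZ")
})

test_that("trajectory formats round trip; times follow dt", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 10, dt = 5,
                                          fluctuation_sigmas = 0.3,
                                          seed = 11))
  # multi-model PDB: 10 frames at 5 ps -> times 0, 5, ..., 45
  txt <- write_trajectory(tc$trajectory, "pdb", topology = tc$topology)
  back <- read_trajectory(txt, "pdb", topology = tc$topology, dt = 5)
  expect_equal(back$times, seq(0, 45, by = 5))
  expect_lt(max(abs(back$xyz - tc$trajectory$xyz)), 1e-3)

  # xyz-csv is lossless to ~double precision
  csv <- write_trajectory(tc$trajectory, "xyz-csv")
  back2 <- read_trajectory(csv, "xyz-csv")
  expect_lt(max(abs(back2$xyz - tc$trajectory$xyz)), 1e-9)
  expect_equal(back2$times, tc$trajectory$times)

  # binary DCD (read through bio3d) stores float32
  skip_if_not_installed("bio3d")
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tc$trajectory, "dcd", path = dcd)
  back3 <- read_trajectory(dcd, "dcd", dt = 5)
  expect_equal(dim(back3$xyz), dim(tc$trajectory$xyz))
  expect_lt(max(abs(back3$xyz - tc$trajectory$xyz)), 1e-4)
  expect_error(read_trajectory(dcd, "dcd"), "dt")
})

test_that("xyz-csv enforces schema and drops a truncated final frame", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 3))
  csv <- write_trajectory(tc$trajectory, "xyz-csv")
  expect_error(read_trajectory(sub("^frame,", "fr,", csv), "xyz-csv"),
               "frame")
  truncated <- csv[1:(length(csv) - 5)]
  expect_warning(back <- read_trajectory(truncated, "xyz-csv"),
                 "truncated")
  expect_equal(n_frames(back), 2)
  # atom-count mismatch against a supplied topology is structural
  expect_error(read_trajectory(csv, "xyz-csv",
                               topology = topology(data.frame(
                                 name = "X", element = "C",
                                 residue_name = "A", residue_id = 1,
                                 chain = "A"))),
               "atom count")
})

test_that("energy tables: schema, identity, and lossless round trip", {
  expect_equal(length(read_energy_table(
    "time_ps,v_el_kcalmol,v_vdw_kcalmol")$v_el), 0)
  tab <- c("time_ps,v_el_kcalmol,v_vdw_kcalmol",
           "0,-10.5,-3.25", "5,-11,-3", "10,-9.75,-3.5")
  es <- read_energy_table(tab, state_label = "free")
  expect_equal(es$v_el, c(-10.5, -11, -9.75))
  expect_equal(es$v_vdw, c(-3.25, -3, -3.5))
  expect_equal(es$times, c(0, 5, 10))
  expect_error(read_energy_table("time_ps,v_el_kcalmol\n0,-1"),
               "v_vdw_kcalmol")

  gen <- make_energy_series(-8, -3, 2, 1, n = 1000, seed = 4)
  back <- read_energy_table(write_energy_table(gen$series))
  expect_lt(max(abs(back$v_el - gen$series$v_el)), 1e-9)
  expect_lt(max(abs(back$v_vdw - gen$series$v_vdw)), 1e-9)
})
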