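pocket_sel <- function(tc) atom_select(tc$topology, chain = "A")

test_that("scripted water exchange is recovered as an exact id schedule", {
  tc <- make_toy_complex(toy_complex_spec(
    n_frames = 20, n_waters = 2,
    water_schedule = list(list(water = 101, site = 1, frames = 1:10),
                          list(water = 102, site = 1, frames = 11:20))))
  # site 1 center is a fixed point of the rigid pocket; probe it directly
  ctr_atoms <- pocket_sel(tc)
  occ <- site_water_occupancy(tc$trajectory, tc$topology,
                              site_center = ctr_atoms, radius = 6)
  expect_identical(occ[1:10], rep(list(101L), 10))
  expect_identical(occ[11:20], rep(list(102L), 10))
})

test_that("occupancy boundaries: far waters never count, infinite radius
           counts every water in every frame", {
  tc <- make_toy_complex(toy_complex_spec(n_frames = 5, n_waters = 3))
  occ <- site_water_occupancy(tc$trajectory, tc$topology,
                              site_center = pocket_sel(tc), radius = 3)
  expect_identical(occ, rep(list(integer(0)), 5))  # all parked in bulk
  occ_all <- site_water_occupancy(tc$trajectory, tc$topology,
                                  site_center = pocket_sel(tc),
                                  radius = 1e9)
  expect_identical(occ_all, rep(list(c(101L, 102L, 103L)), 5))
  # no waters at all -> warning and empty lists
  dry <- make_toy_complex(toy_complex_spec(n_frames = 2, n_waters = 0))
  expect_warning(occ0 <- site_water_occupancy(dry$trajectory, dry$topology,
                                              pocket_sel(dry), 3),
                 "no water")
  expect_identical(occ0, rep(list(integer(0)), 2))
})

test_that("a persistently occupied position is one conserved site even
           when the occupying molecules swap", {
  tc <- make_toy_complex(toy_complex_spec(
    n_frames = 20, n_waters = 2,
    water_schedule = list(
      list(water = 101, site = 1, frames = c(1:10)),
      list(water = 102, site = 1, frames = c(11:20)),
      list(water = 102, site = 2, frames = c(1:10)),
      list(water = 101, site = 2, frames = c(11:20)))))
  sites <- conserved_water_sites(tc$trajectory, tc$topology,
                                 pocket_alignment = pocket_sel(tc),
                                 min_residency = 0.9)
  expect_length(sites, 2)
  expect_equal(sites[[1]]$residency, 1.0)
  expect_equal(sites[[2]]$residency, 1.0)
  cents <- rbind(sites[[1]]$centroid, sites[[2]]$centroid)
  cents <- cents[order(cents[, 1]), ]
  expect_equal(cents, unname(tc$truth$site_centers[1:2, ]),
               tolerance = 1e-8)
  # identity-agnostic residency, but occupants record the exchange
  s1 <- sites[[which.min(c(sites[[1]]$centroid[1], sites[[2]]$centroid[1]))]]
  expect_identical(unname(s1$occupants), c(rep(101L, 10), rep(102L, 10)))
})

test_that("residency equals the mean occupancy indicator exactly", {
  tc <- make_toy_complex(toy_complex_spec(
    n_frames = 40, n_waters = 1,
    water_schedule = list(list(water = 101, site = 2,
                               frames = c(3:17, 25:30)))))
  sites <- conserved_water_sites(tc$trajectory, tc$topology,
                                 pocket_alignment = pocket_sel(tc),
                                 min_residency = 0.2)
  truth <- tc$truth$waters[[1]]
  site <- sites[[which.min(vapply(sites, function(s)
    sum((s$centroid - truth$center)^2), 1.0))]]
  expect_identical(site$residency, mean(truth$presence))
  expect_identical(unname(!is.na(site$occupants)), truth$presence)
  # min_residency 1.0 excludes a site that misses even one frame
  strict <- conserved_water_sites(tc$trajectory, tc$topology,
                                  pocket_alignment = pocket_sel(tc),
                                  min_residency = 1.0)
  expect_false(any(vapply(strict, function(s)
    sum((s$centroid - truth$center)^2) < 1, TRUE)))
})

test_that("an immobile water in a rigid pocket is a single full-residency
           site at the water position, invariant to rigid motion", {
  tc <- make_toy_complex(toy_complex_spec(
    n_frames = 10, n_waters = 1,
    water_schedule = list(list(water = 101, site = 1, frames = 1:10))))
  sites <- conserved_water_sites(tc$trajectory, tc$topology,
                                 pocket_alignment = pocket_sel(tc))
  top_site <- sites[[1]]
  expect_equal(top_site$residency, 1.0)
  expect_equal(unname(top_site$centroid),
               unname(tc$truth$site_centers[1, ]), tolerance = 1e-8)

  # apply a different random rigid transform to every later frame (the
  # first frame anchors the pocket reference): alignment must remove it
  set.seed(5)
  xyz <- tc$trajectory$xyz
  for (i in 2:dim(xyz)[3]) {
    R <- random_rotation()
    tr <- runif(3, -15, 15)
    xyz[, , i] <- sweep(xyz[, , i] %*% t(R), 2, -tr)
  }
  moved <- trajectory(xyz, dt = tc$trajectory$dt,
                      times = tc$trajectory$times)
  sites2 <- conserved_water_sites(moved, tc$topology,
                                  pocket_alignment = pocket_sel(tc))
  expect_equal(sites2[[1]]$residency, 1.0)
  expect_equal(unname(sites2[[1]]$centroid), unname(top_site$centroid),
               tolerance = 1e-8)
})

test_that("per-frame site occupants never exceed the waters in the pocket", {
  tc <- make_toy_complex(toy_complex_spec(
    n_frames = 15, n_waters = 3,
    water_schedule = list(list(water = 101, site = 1, frames = 1:15),
                          list(water = 102, site = 2, frames = 4:12),
                          list(water = 103, site = 3, frames = 8:15))))
  sites <- conserved_water_sites(tc$trajectory, tc$topology,
                                 pocket_alignment = pocket_sel(tc),
                                 min_residency = 0)
  for (f in 1:15) {
    occupants <- vapply(sites, function(s) s$occupants[f], 1L)
    occupants <- occupants[!is.na(occupants)]
    expect_equal(anyDuplicated(occupants), 0L)
    expect_lte(length(occupants), 3)
  }
})

test_that("reference-water comparison is a plain Euclidean distance", {
  site <- list(centroid = c(0, 0, 0))
  expect_equal(compare_to_reference(site, c(0, 0, 0)), 0.0)
  expect_equal(compare_to_reference(site, c(0, 0, 1.1)), 1.1)
  set.seed(12)
  for (k in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(compare_to_reference(list(centroid = a), b),
                 sqrt(sum((a - b)^2)))
  }
  expect_error(conserved_water_sites(
    make_toy_complex(toy_complex_spec(n_frames = 2))$trajectory,
    make_toy_complex(toy_complex_spec(n_frames = 2))$topology,
    pocket_alignment = 1:2), "3 atoms")
})
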