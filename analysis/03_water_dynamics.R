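#!/usr/bin/env Rscript
# Water entry and conserved-site analysis: a water exchanges into the
# pocket site partway through the run and a second water visits another
# site; the clustered sites are compared to a reference position.

source(file.path(dirname(sub("--file=", "", grep("--file=",
  commandArgs(FALSE), value = TRUE))), "00_common.R"))

nf <- 300
wsched <- list(
  list(water = 101, site = 1, frames = 31:nf),   # settles and stays
  list(water = 102, site = 2, frames = 1:150),   # leaves mid-run
  list(water = 103, site = 2, frames = 151:nf))  # replaced by another
tc <- make_toy_complex(study_spec(nf, water_schedule = wsched))

pocket <- atom_select(tc$topology, chain = "A")
occ <- site_water_occupancy(tc$trajectory, tc$topology,
                            site_center = pocket, radius = 6)
first_entry <- which(vapply(occ, length, 1L) > 0)[1]
cat("first water enters the site region at frame", first_entry,
    "(", tc$trajectory$times[first_entry], "ps )\n")

sites <- conserved_water_sites(tc$trajectory, tc$topology,
                               pocket_alignment = pocket,
                               min_residency = 0.5)
writeLines(format_water_sites_tsv(sites),
           file.path(RESULTS_DIR, "water_sites.tsv"))
cat(length(sites), "conserved sites (residency >= 0.5)\n")

# the exchanging site stays fully occupied although the molecule swaps
exch <- sites[[which.min(vapply(sites, function(s)
  sum((s$centroid - tc$truth$site_centers[2, ])^2), 1.0))]]
cat(sprintf("exchanging site residency: %.3f (occupant swaps at frame %d)\n",
            exch$residency, which(diff(exch$occupants) != 0)[1] + 1L))

# distance of the settled site to a reference water position given in
# the same pocket-aligned coordinates
settled <- sites[[which.min(vapply(sites, function(s)
  sum((s$centroid - tc$truth$site_centers[1, ])^2), 1.0))]]
reference_water <- tc$truth$site_centers[1, ] + c(0, 0, 1.1)
d <- compare_to_reference(settled, reference_water)
cat(sprintf("distance of settled site to reference water: %.2f A\n", d))
cat(sprintf("settled site residency: %.3f (planted %.3f)\n",
            settled$residency, tc$truth$waters[[1]]$residency))
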