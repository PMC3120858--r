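# Shared setup for the analysis drivers: one study seed, one output dir.
suppressPackageStartupMessages(library(flipsite))

STUDY_SEED <- 20260923L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# The synthetic study complex used throughout: a rigid 7-probe pocket
# around a flipped methylcytosine fragment with three waters. Frames are
# 5 ps apart (the monitoring interval); bonds and water visits follow
# the schedules each driver plants.
study_spec <- function(n_frames, hbond_schedule = list(),
                       water_schedule = list(), sigmas = 0) {
  toy_complex_spec(n_frames = n_frames, dt = 5, n_waters = 3,
                   hbond_schedule = hbond_schedule,
                   water_schedule = water_schedule,
                   fluctuation_sigmas = sigmas, seed = STUDY_SEED)
}
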