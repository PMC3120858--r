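#' Read a trajectory from disk or text
#'
#' Three interchange formats are supported:
#' \describe{
#'   \item{`"pdb"`}{multi-model PDB text (via [read_structure()])}
#'   \item{`"xyz-csv"`}{plain CSV with columns `frame`, `time_ps`, `atom`,
#'     `x`, `y`, `z`, one row per atom per frame — the documented text
#'     fallback, lossless to full double precision}
#'   \item{`"dcd"`}{CHARMM/NAMD binary DCD, read with [bio3d::read.dcd];
#'     requires a file path. DCD stores no time axis, so `dt` is required}
#' }
#'
#' @param source file path (any format) or text (pdb, xyz-csv)
#' @param format one of `"pdb"`, `"xyz-csv"`, `"dcd"`
#' @param topology optional [topology()]; when given, the frame atom count
#'   is checked against it
#' @param dt frame spacing in ps, used when the format carries no time
#'   stamps (required for `"dcd"`; defaults to 5 ps for `"pdb"` in line
#'   with the monitoring interval used throughout the package)
#' @return a [trajectory()]
#' @export
read_trajectory <- function(source, format = c("pdb", "xyz-csv", "dcd"),
                            topology = NULL, dt = NULL) {
  format <- match.arg(format)
  traj <- switch(format,
    "pdb" = {
      if (is.null(dt)) dt <- 5
      parsed <- read_structure(source)
      trajectory(parsed$frames, dt = dt,
                 times = (seq_along(parsed$frames) - 1) * dt)
    },
    "xyz-csv" = read_xyz_csv(source, dt = dt),
    "dcd" = {
      if (is.null(dt)) stop("dt is required for DCD input (no time axis)")
      if (!(length(source) == 1 && file.exists(source)))
        stop("DCD input must be a file path")
      m <- bio3d::read.dcd(source, verbose = FALSE)
      nf <- nrow(m)
      n <- ncol(m) / 3L
      xyz <- array(0, dim = c(n, 3L, nf))
      for (i in seq_len(nf)) xyz[, , i] <- matrix(m[i, ], ncol = 3L, byrow = TRUE)
      trajectory(xyz, dt = dt, times = (seq_len(nf) - 1) * dt)
    })
  if (!is.null(topology) && dim(traj$xyz)[1] != n_atoms(topology))
    stop("trajectory atom count (", dim(traj$xyz)[1],
         ") does not match topology (", n_atoms(topology), ")")
  traj
}

read_xyz_csv <- function(source, dt = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    tab <- read.csv(source, stringsAsFactors = FALSE)
  } else {
    tab <- read.csv(text = paste(as_text_lines(source), collapse = "\n"),
                    stringsAsFactors = FALSE)
  }
  need <- c("frame", "time_ps", "atom", "x", "y", "z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("xyz-csv is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  fr_ids <- unique(tab$frame)
  n <- sum(tab$frame == fr_ids[1])
  counts <- table(factor(tab$frame, levels = fr_ids))
  if (counts[length(counts)] != n && length(fr_ids) > 1) {
    warning("dropping truncated final frame (", counts[length(counts)],
            " of ", n, " atoms)")
    tab <- tab[tab$frame != fr_ids[length(fr_ids)], , drop = FALSE]
    fr_ids <- fr_ids[-length(fr_ids)]
    counts <- counts[-length(counts)]
  }
  if (any(counts != n)) stop("inconsistent atom count across xyz-csv frames")
  nf <- length(fr_ids)
  xyz <- array(0, dim = c(n, 3L, nf))
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    blk <- tab[tab$frame == fr_ids[i], , drop = FALSE]
    blk <- blk[order(blk$atom), , drop = FALSE]
    xyz[, , i] <- as.matrix(blk[, c("x", "y", "z")])
    times[i] <- blk$time_ps[1]
  }
  if (!is.null(dt)) times <- (seq_len(nf) - 1) * dt
  trajectory(xyz, dt = dt, times = times)
}

#' Write a trajectory
#'
#' Inverse of [read_trajectory()] for all three formats. `"pdb"` and
#' `"xyz-csv"` return (and optionally write) text; `"dcd"` writes a
#' CHARMM-format binary file and requires `path`.
#'
#' @param trajectory a [trajectory()]
#' @param format one of `"pdb"`, `"xyz-csv"`, `"dcd"`
#' @param topology required for `"pdb"` (atom records need names/residues)
#' @param path optional output file; required for `"dcd"`
#' @return the text lines (invisibly for `"dcd"`: the path)
#' @export
write_trajectory <- function(trajectory, format = c("pdb", "xyz-csv", "dcd"),
                             topology = NULL, path = NULL) {
  format <- match.arg(format)
  if (format == "pdb") {
    if (is.null(topology)) stop("PDB output requires a topology")
    frames <- lapply(seq_len(n_frames(trajectory)),
                     function(i) get_frame(trajectory, i))
    out <- write_structure(topology, frames)
    if (!is.null(path)) writeLines(out, path)
    return(out)
  }
  if (format == "xyz-csv") {
    nf <- n_frames(trajectory)
    n <- dim(trajectory$xyz)[1]
    tab <- data.frame(
      frame = rep(seq_len(nf), each = n),
      time_ps = rep(trajectory$times, each = n),
      atom = rep(seq_len(n), nf),
      x = as.vector(trajectory$xyz[, 1, ]),
      y = as.vector(trajectory$xyz[, 2, ]),
      z = as.vector(trajectory$xyz[, 3, ]))
    con <- textConnection("out_lines", "w", local = TRUE)
    write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, quote = FALSE)
    close(con)
    if (!is.null(path)) writeLines(out_lines, path)
    return(out_lines)
  }
  # dcd
  if (is.null(path)) stop("DCD output requires a path")
  write_dcd(trajectory, path)
  invisible(path)
}

# Minimal CHARMM-format DCD writer (single-precision, no unit cell).
# Fortran unformatted records: 4-byte length markers around each payload.
write_dcd <- function(trajectory, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(trajectory)
  n <- dim(trajectory$xyz)[1]
  wmark <- function(k) writeBin(as.integer(k), con, size = 4L)
  # header record: 'CORD' + 20 int control array (CHARMM version 24)
  wmark(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf          # frames in file
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # save interval
  icntrl[4] <- nf
  icntrl[20] <- 24L        # CHARMM version flag
  writeBin(icntrl[1:9], con, size = 4L)
  writeBin(as.numeric(trajectory$dt), con, size = 4L)  # delta as float32
  writeBin(icntrl[11:20], con, size = 4L)
  wmark(84L)
  # title record
  title <- sprintf("%-80s", "written by flipsite")
  wmark(4L + 80L)
  writeBin(1L, con, size = 4L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wmark(4L + 80L)
  # atom-count record
  wmark(4L); writeBin(as.integer(n), con, size = 4L); wmark(4L)
  for (i in seq_len(nf)) {
    for (d in 1:3) {
      wmark(4L * n)
      writeBin(as.numeric(trajectory$xyz[, d, i]), con, size = 4L)
      wmark(4L * n)
    }
  }
  invisible(path)
}

#' Per-frame interaction energy series
#'
#' Container for the electrostatic and van-der-Waals interaction energy of
#' a ligand with its surroundings in one simulation state, the quantities
#' whose trajectory averages enter the LIE estimate.
#'
#' @param state_label `"bound"` or `"free"`
#' @param times frame times, ps
#' @param v_el per-frame electrostatic interaction energy, kcal/mol
#' @param v_vdw per-frame van-der-Waals interaction energy, kcal/mol
#' @param meta optional list of provenance metadata (window, scheme, ...)
#' @return object of class `flipsite_energy_series`
#' @export
energy_series <- function(state_label, times, v_el, v_vdw, meta = list()) {
  state_label <- match.arg(state_label, c("bound", "free"))
  if (length(times) != length(v_el) || length(v_el) != length(v_vdw))
    stop("times, v_el and v_vdw must have equal length")
  if (length(v_el) > 0 && (!all(is.finite(v_el)) || !all(is.finite(v_vdw)))) {
    bad <- which(!is.finite(v_el) | !is.finite(v_vdw))[1]
    stop("non-finite energy at frame ", bad)
  }
  structure(list(state_label = state_label, times = as.numeric(times),
                 v_el = as.numeric(v_el), v_vdw = as.numeric(v_vdw),
                 meta = meta),
            class = "flipsite_energy_series")
}

#' @export
print.flipsite_energy_series <- function(x, ...) {
  cat(sprintf(
    "<energy_series '%s'> %d frames; <v_el> = %.4f, <v_vdw> = %.4f kcal/mol\n",
    x$state_label, length(x$times),
    if (length(x$v_el)) mean(x$v_el) else NA, if (length(x$v_vdw)) mean(x$v_vdw) else NA))
  invisible(x)
}

#' Read / write an energy table (CSV schema `time_ps, v_el_kcalmol,
#' v_vdw_kcalmol`)
#'
#' @param csv_text CSV lines, a string, or a file path
#' @param state_label label for the resulting series
#' @return [energy_series()] (read) / character CSV lines (write)
#' @export
read_energy_table <- function(csv_text, state_label = "bound") {
  if (length(csv_text) == 1 && !grepl("\n", csv_text) && file.exists(csv_text)) {
    tab <- read.csv(csv_text, stringsAsFactors = FALSE)
  } else {
    tab <- read.csv(text = paste(as_text_lines(csv_text), collapse = "\n"),
                    stringsAsFactors = FALSE)
  }
  need <- c("time_ps", "v_el_kcalmol", "v_vdw_kcalmol")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("energy table is missing required column(s): ",
         paste(miss, collapse = ", "))
  energy_series(state_label, tab$time_ps, tab$v_el_kcalmol, tab$v_vdw_kcalmol)
}

#' @rdname read_energy_table
#' @param series an [energy_series()]
#' @param path optional output file
#' @export
write_energy_table <- function(series, path = NULL) {
  tab <- data.frame(time_ps = series$times,
                    v_el_kcalmol = series$v_el,
                    v_vdw_kcalmol = series$v_vdw)
  lines <- c("time_ps,v_el_kcalmol,v_vdw_kcalmol",
             if (nrow(tab) > 0)
               sprintf("%s,%s,%s",
                       format(tab$time_ps, digits = 15, trim = TRUE),
                       format(tab$v_el_kcalmol, digits = 15, trim = TRUE),
                       format(tab$v_vdw_kcalmol, digits = 15, trim = TRUE)))
  if (!is.null(path)) writeLines(lines, path)
  lines
}
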