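#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over proper rotations
#' and translations, solved with the SVD form of the Kabsch algorithm.
#' The sign of the smallest singular vector pair is corrected so the
#' rotation is proper (det = +1): allowing reflections would silently
#' corrupt RMSD values for chiral structures.
#'
#' @param reference,mobile N x 3 coordinate matrices, N >= 3 and not
#'   collinear
#' @param weights optional non-negative per-atom weights (e.g. masses)
#' @return object of class `flipsite_superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3), `rmsd` (Angstrom, the
#'   weighted minimum). The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (see [apply_superposition()]).
#' @export
superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  n <- nrow(reference)
  if (n < 3 || nrow(mobile) != n)
    stop("superposition needs matched coordinate sets of >= 3 atoms")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) == 0) stop("invalid weights")
  w <- weights / sum(weights)

  cref <- colSums(reference * w)
  cmob <- colSums(mobile * w)
  P <- sweep(mobile, 2, cmob)      # mobile, centered
  Q <- sweep(reference, 2, cref)   # reference, centered
  if (collinear(Q)) stop("reference coordinates are collinear")

  H <- t(P * w) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)        # x_fit = R x_mob

  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cref - R %*% cmob),
                 rmsd = rmsd),
            class = "flipsite_superposition")
}

collinear <- function(X, tol = 1e-10) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Apply a superposition transform to coordinates
#' @param sp a [superpose()] result
#' @param coordinates N x 3 matrix
#' @export
apply_superposition <- function(sp, coordinates) {
  sweep(as.matrix(coordinates) %*% t(sp$rotation), 2, -sp$translation)
}

rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD series after superposition
#'
#' Each frame is fitted to the reference on `fit_selection` and the RMSD
#' is reported over `selection`. The two selections are independent,
#' supporting "subset" reporting such as excluding mobile terminal
#' residues from the reported set while fitting on the full backbone (or
#' vice versa).
#'
#' @param trajectory a [trajectory()]
#' @param reference a [frame()] (same atom count as the trajectory)
#' @param selection atom indices the RMSD is reported over
#' @param fit_selection atom indices the fit uses (default: `selection`)
#' @param weights optional per-atom weights over `fit_selection`
#'   (mass-weighting is off by default: the profiles are atom-positional)
#' @return data.frame `time_ps`, `rmsd`
#' @export
rmsd_series <- function(trajectory, reference, selection,
                        fit_selection = selection, weights = NULL) {
  if (length(selection) == 0 || length(fit_selection) == 0)
    stop("selections must be nonempty")
  n <- dim(trajectory$xyz)[1]
  if (max(selection, fit_selection) > n)
    stop("selection indices exceed trajectory atom count")
  ref <- reference$coordinates
  if (nrow(ref) != n) stop("reference atom count does not match trajectory")
  nf <- n_frames(trajectory)
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    x <- frame_xyz(trajectory, i)
    sp <- superpose(ref[fit_selection, , drop = FALSE],
                    x[fit_selection, , drop = FALSE], weights = weights)
    fitted <- apply_superposition(sp, x[selection, , drop = FALSE])
    out[i] <- rmsd_between(fitted, ref[selection, , drop = FALSE])
  }
  data.frame(time_ps = trajectory$times, rmsd = out)
}

#' Root-mean-square fluctuation profile
#'
#' Frames in `window` are first aligned on `selection` to the first
#' window frame, then per-atom fluctuations about the time-mean position
#' are computed: `rmsf_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`. Optionally
#' averaged per residue.
#'
#' @param trajectory a [trajectory()]
#' @param selection atom indices to align on and report
#' @param window integer frame range (default: all frames); must contain
#'   at least 2 frames
#' @param topology optional [topology()]; when given together with
#'   `per_residue = TRUE`, per-residue means are returned
#' @param per_residue average atom RMSF within each residue
#' @return data.frame `atom`, `rmsf` (or `chain`, `residue_id`, `rmsf`)
#' @export
rmsf <- function(trajectory, selection, window = NULL, topology = NULL,
                 per_residue = FALSE) {
  nf <- n_frames(trajectory)
  if (is.null(window)) window <- seq_len(nf)
  if (length(window) < 2) stop("RMSF window must span at least 2 frames")
  if (any(window < 1 | window > nf)) stop("window outside trajectory")
  ref <- frame_xyz(trajectory, window[1])[selection, , drop = FALSE]
  aligned <- array(0, dim = c(length(selection), 3L, length(window)))
  for (k in seq_along(window)) {
    x <- frame_xyz(trajectory, window[k])[selection, , drop = FALSE]
    sp <- superpose(ref, x)
    aligned[, , k] <- apply_superposition(sp, x)
  }
  mean_pos <- apply(aligned, c(1, 2), mean)
  dev2 <- sweep(aligned, c(1, 2), mean_pos)^2
  vals <- sqrt(apply(dev2, 1, mean) * 3)  # mean over (xyz, frames) * 3
  out <- data.frame(atom = selection, rmsf = vals)
  if (per_residue) {
    if (is.null(topology)) stop("per-residue RMSF needs a topology")
    a <- topology$atoms[selection, , drop = FALSE]
    key <- paste(a$chain, a$residue_id, sep = ":")
    agg <- tapply(out$rmsf, key, mean)
    parts <- strsplit(names(agg), ":", fixed = TRUE)
    out <- data.frame(chain = vapply(parts, `[`, "", 1),
                      residue_id = as.integer(vapply(parts, `[`, "", 2)),
                      rmsf = as.numeric(agg))
    out <- out[order(out$chain, out$residue_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
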