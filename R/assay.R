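#' One replicate of a two-substrate competition pull-down measurement
#'
#' Background-subtracted fluorescence intensities of the two bound DNA
#' substrates and of the immobilized fluorescent-protein fusion, together
#' with the calibration factors (a.u. per nM) that convert each channel
#' to a concentration.
#'
#' @param substrate_a_fluor,substrate_b_fluor net intensities (a.u., >= 0)
#' @param protein_fluor net protein intensity (a.u.)
#' @param calib_a,calib_b,calib_protein conversion factors (> 0)
#' @param replicate_id identifier
#' @export
competition_measurement <- function(substrate_a_fluor, substrate_b_fluor,
                                    protein_fluor, calib_a = 1,
                                    calib_b = 1, calib_protein = 1,
                                    replicate_id = NA) {
  stopifnot(calib_a > 0, calib_b > 0, calib_protein > 0,
            substrate_a_fluor >= 0, substrate_b_fluor >= 0)
  structure(list(substrate_a_fluor = substrate_a_fluor,
                 substrate_b_fluor = substrate_b_fluor,
                 protein_fluor = protein_fluor,
                 calib_a = calib_a, calib_b = calib_b,
                 calib_protein = calib_protein,
                 replicate_id = replicate_id),
            class = "flipsite_competition_measurement")
}

#' Bound-DNA per protein ratios for both substrates
#'
#' Each substrate's bound concentration (intensity / calibration) divided
#' by the immobilized-protein concentration; unitless.
#'
#' @param m a [competition_measurement()]
#' @return named numeric `c(ratio_a = , ratio_b = )`
#' @export
binding_ratios <- function(m) {
  prot <- m$protein_fluor / m$calib_protein
  if (!is.finite(prot) || prot <= 0)
    stop("protein signal must be positive to form binding ratios")
  c(ratio_a = (m$substrate_a_fluor / m$calib_a) / prot,
    ratio_b = (m$substrate_b_fluor / m$calib_b) / prot)
}

#' Label-bias correction and total-DNA normalization
#'
#' Divides each substrate's binding ratio by the corresponding ratio from
#' a control experiment in which both substrates share one sequence but
#' carry the two labels — a ratiometric model of label/detection
#' efficiency (assumption: the control correction is a per-channel
#' multiplicative factor). The corrected ratios are then normalized by
#' their total, so the two outputs are relative bound-DNA fractions
#' summing to one.
#'
#' @param ratios numeric length 2 (substrates a, b) from
#'   [binding_ratios()]
#' @param control_ratios numeric length 2, both > 0, from the label-swap
#'   control
#' @return named numeric `c(rel_a = , rel_b = )`, in `[0, 1]`, summing
#'   to 1
#' @export
correct_and_normalize <- function(ratios, control_ratios) {
  if (any(control_ratios <= 0)) stop("control ratios must be positive")
  corrected <- as.numeric(ratios) / as.numeric(control_ratios)
  tot <- sum(corrected)
  if (tot == 0)
    stop("both corrected ratios are zero: relative binding is undefined")
  setNames(corrected / tot, c("rel_a", "rel_b"))
}

#' Mean and standard deviation across replicates
#'
#' @param values numeric matrix or data.frame, one row per replicate, one
#'   column per substrate (>= 2 replicates)
#' @return data.frame `substrate`, `mean`, `sd` (sample SD, n-1)
#' @export
replicate_summary <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 replicates")
  nm <- colnames(values)
  if (is.null(nm)) nm <- paste0("substrate_", seq_len(ncol(values)))
  data.frame(substrate = nm,
             mean = colMeans(values),
             sd = apply(values, 2, sd),
             row.names = NULL)
}

#' Run the full assay pipeline on replicate tables
#'
#' Convenience wrapper: computes per-replicate binding ratios, applies
#' the control correction and normalization, and summarizes across
#' replicates.
#'
#' @param measurements list of [competition_measurement()]s
#' @param controls list of matching control measurements (recycled if
#'   length 1)
#' @return list with `per_replicate` (matrix of `rel_a`, `rel_b`) and
#'   `summary` (a [replicate_summary()])
#' @export
assay_pipeline <- function(measurements, controls) {
  if (length(controls) == 1)
    controls <- rep(controls, length(measurements))
  stopifnot(length(controls) == length(measurements))
  per <- t(vapply(seq_along(measurements), function(i) {
    correct_and_normalize(binding_ratios(measurements[[i]]),
                          binding_ratios(controls[[i]]))
  }, c(rel_a = 0, rel_b = 0)))
  list(per_replicate = per, summary = replicate_summary(per))
}
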