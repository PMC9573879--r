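#' Low-molecular-weight filtration as an abundance transform
#'
#' Models molecular-weight cut-off filtration of solubilised organelle IPs:
#' each monitored peptide belongs to a carrier species (free ~4.5 kDa
#' A-beta versus full-length substrate / membrane-tethered C-terminal
#' fragments) whose transmission through the filter rescales its
#' abundance. Small species pass into the filtrate with high transmission;
#' large ones are retained. Filtrate and retentate abundances sum exactly
#' to the input for every species.
#'
#' @param truth A `"ground_truth"` object (see [simulate_run()]).
#' @param cutoff_mass_da Filter cut-off (Da); default 50 kDa.
#' @param retention_curve Either a function `mass -> transmission in [0,1]`,
#'   or a named numeric vector mapping `peptide_id` to transmission. The
#'   default is a logistic edge around the cut-off
#'   (`plogis((cutoff - mass)/width)`).
#' @param width_da Softness of the default logistic edge.
#' @param fraction Return the `"filtrate"` (default) or `"retentate"` truth.
#' @return A `"ground_truth"` with rescaled abundances and trigger spikes
#'   unchanged (triggers are spiked after filtration).
#' @export
apply_lmw_filtration <- function(truth, cutoff_mass_da = 5e4,
                                 retention_curve = NULL, width_da = 5e3,
                                 fraction = c("filtrate", "retentate")) {
  fraction <- match.arg(fraction)
  pep <- truth$peptide
  tr <- if (is.null(retention_curve)) {
    stats::plogis((cutoff_mass_da - pep$carrier_mass_da) / width_da)
  } else if (is.function(retention_curve)) {
    retention_curve(pep$carrier_mass_da)
  } else {
    unname(retention_curve[pep$peptide_id])
  }
  if (anyNA(tr) || any(tr < 0) || any(tr > 1)) {
    stop("transmission must lie in [0, 1] for every peptide", call. = FALSE)
  }
  keep <- if (fraction == "filtrate") tr else 1 - tr
  keep_by_pep <- stats::setNames(keep, pep$peptide_id)
  out <- truth
  out$abundance$amol <- unname(out$abundance$amol *
                                 keep_by_pep[out$abundance$peptide_id])
  out$peptide$base_amol <- out$peptide$base_amol * keep
  out
}

#' Rebuild a run after transforming its ground truth
#'
#' Regenerates the scan stream from a (possibly transformed) ground truth,
#' e.g. after [apply_lmw_filtration()].
#'
#' @param run A `"sim_run"`.
#' @param truth Replacement `"ground_truth"`.
#' @return A `"sim_run"`.
#' @export
rebuild_run <- function(run, truth) {
  scans <- if (run$mode == "triggered") build_ms1_stream(truth) else
    build_sim_stream(truth)
  structure(list(scans = scans$scans, peaks = scans$peaks, truth = truth,
                 mode = run$mode, seed = run$seed, params = truth$params),
            class = "sim_run")
}
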