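#' Trapezoidal area of an extracted-ion chromatogram
#' @keywords internal
trapz_area <- function(rt, intensity) {
  if (length(rt) < 2) return(0)
  o <- order(rt)
  sum(diff(rt[o]) * (utils::head(intensity[o], -1) +
                       utils::tail(intensity[o], -1)) / 2)
}

#' Extract SIM peak areas for trigger/target pairs
#'
#' From a `"sim"`-mode run, extracts the precursor ion traces of each
#' target peptide and its spiked trigger within +/-10 ppm across the
#' scheduled window and integrates them trapezoidally. Because the
#' TMT-labelled target and the TMTsh-labelled trigger co-elute, the
#' target/trigger area ratio times the known spike amount gives the total
#' absolute amount of target.
#'
#' @param run A `"sim_run"` with `mode == "sim"`.
#' @param xic_ppm Extraction tolerance (ppm).
#' @return Tibble of class `"sim_measurement"`: `peptide_id`,
#'   `target_area`, `trigger_area`, `trigger_amol`.
#' @export
sim_peak_areas <- function(run, xic_ppm = 10) {
  stopifnot(inherits(run, "sim_run"), run$mode == "sim")
  pep <- run$truth$peptide
  purrr::map_dfr(seq_len(nrow(pep)), function(i) {
    idx <- which(run$scans$peptide_id == pep$peptide_id[i])
    xic <- function(mz_ref) {
      vapply(idx, function(k) {
        pk <- run$peaks[[k]]
        if (nrow(pk) == 0) return(0)
        sum(pk$intensity[ppm_diff(pk$mz, mz_ref) <= xic_ppm])
      }, 0)
    }
    rts <- run$scans$rt_min[idx]
    tibble::tibble(
      peptide_id = pep$peptide_id[i],
      target_area = trapz_area(rts, xic(pep$target_mz[i])),
      trigger_area = trapz_area(rts, xic(pep$trigger_mz[i])),
      trigger_amol = pep$trigger_amol[i]
    )
  })
}

#' Absolute quantification from SIM target/trigger ratios
#'
#' `total_amol = (target_area / trigger_area) * trigger_amol`.
#'
#' @param m A tibble from [sim_peak_areas()] (columns `target_area`,
#'   `trigger_area`, `trigger_amol`).
#' @return `m` with `total_amol` added.
#' @export
sim_absolute <- function(m) {
  if (any(m$trigger_area == 0)) {
    stop("trigger peak area is zero for: ",
         paste(m$peptide_id[m$trigger_area == 0], collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(m, total_amol = .data$target_area / .data$trigger_area *
                  .data$trigger_amol)
}

#' Apportion a total absolute amount over multiplexed channels
#'
#' Distributes each peptide's SIM-derived total amount over channels in
#' proportion to the impurity-corrected (unnormalised) reporter S/N:
#' `channel_amol = total_amol * s_c / sum(s)`. Channel amounts always sum
#' to the total.
#'
#' @param sim_abs Output of [sim_absolute()].
#' @param qt A `"quant_table"` (use corrected, unnormalised S/N so channel
#'   fractions reflect composition, not loading adjustment).
#' @return Long tibble `peptide_id`, `channel_id`, `condition`, `is_ko`,
#'   `amol`.
#' @export
per_channel_absolute <- function(sim_abs, qt) {
  stopifnot(inherits(qt, "quant_table"))
  if (isTRUE(qt$normalized)) {
    warning("apportioning over normalised S/N; pass the unnormalised ",
            "quant_table for composition-faithful amounts")
  }
  d <- dplyr::left_join(qt$sn,
                        dplyr::select(sim_abs, "peptide_id", "total_amol"),
                        by = "peptide_id")
  d <- dplyr::mutate(d, frac = .data$sn / sum(.data$sn),
                     .by = "peptide_id")
  dplyr::transmute(d, .data$peptide_id, .data$channel_id, .data$condition,
                   .data$is_ko, amol = .data$total_amol * .data$frac)
}
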