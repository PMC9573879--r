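#' Triggered-acquisition engine configuration
#'
#' Every tolerance and threshold of the real-time decision cascade. The
#' defaults are the published instrument-method values: triggers must match
#' precursor m/z within +/-10 ppm at the correct charge with intensity at
#' least 5e4; real-time peak matching (RTPM) requires more than 6 fragment
#' matches within +/-10 ppm; target isolation uses a 0.5 Th window; SPS
#' candidates must sit within +/-50% of the stored library relative
#' intensity and pass a 0.5 purity filter over a 3 Th window; the SPS-MS3
#' injection time, scaled from a 10 ms prescan, is capped at 5000 ms.
#'
#' @param ms1_match_ppm Precursor match tolerance (ppm).
#' @param trigger_min_intensity Minimum trigger precursor intensity.
#' @param rtpm_min_peaks Minimum fragment matches (strict "more than 6"
#'   reading: 7).
#' @param rtpm_ppm Fragment match tolerance (ppm).
#' @param isolation_window Precursor isolation width (Th).
#' @param sps_ratio_tolerance Fractional deviation allowed between observed
#'   and library relative fragment intensity.
#' @param sps_purity_min Minimum fraction of window signal attributable to
#'   the candidate.
#' @param sps_purity_window Purity window width (Th; signal integrated over
#'   +/- half this width).
#' @param sps_max_ions Maximum SPS ions per MS3.
#' @param ms3_max_inject_ms Injection-time cap for the MS3 scan.
#' @param prescan_inject_ms Prescan injection time.
#' @param target_agc_ms3 AGC target for the MS3 scan (counts).
#' @param target_check_count,target_check_rank Whether target-MS2
#'   confirmation re-applies the match-count rule and/or the intensity
#'   rank-order rule against the trigger library spectrum.
#' @param rtpm_rank_min_cor Minimum Spearman correlation between observed
#'   and library intensity ranks for the rank-order rule (1 demands the
#'   identical ordering; the default tolerates occasional adjacent swaps
#'   from shot noise while rejecting scrambled spectra).
#' @return List of class `"engine_config"`.
#' @export
engine_config <- function(ms1_match_ppm = 10,
                          trigger_min_intensity = 5e4,
                          rtpm_min_peaks = 7L,
                          rtpm_ppm = 10,
                          isolation_window = 0.5,
                          sps_ratio_tolerance = 0.5,
                          sps_purity_min = 0.5,
                          sps_purity_window = 3,
                          sps_max_ions = 10L,
                          ms3_max_inject_ms = 5000,
                          prescan_inject_ms = 10,
                          target_agc_ms3 = 1e5,
                          target_check_count = TRUE,
                          target_check_rank = TRUE,
                          rtpm_rank_min_cor = 0.9) {
  cfg <- as.list(environment())
  stopifnot(cfg$ms1_match_ppm > 0, cfg$rtpm_ppm > 0, cfg$rtpm_min_peaks >= 1,
            cfg$isolation_window > 0, cfg$sps_ratio_tolerance > 0,
            cfg$sps_purity_min > 0, cfg$sps_purity_window > 0,
            cfg$ms3_max_inject_ms > 0, cfg$prescan_inject_ms > 0)
  structure(cfg, class = "engine_config")
}

ppm_diff <- function(obs, ref) abs(obs - ref) / ref * 1e6

#' Match an MS1 scan against the trigger list
#'
#' Returns the triggers whose precursor m/z is matched by an MS1 peak
#' within the ppm tolerance, at the right charge state (peaks without a
#' charge assignment match any charge), and with intensity at or above the
#' trigger minimum.
#'
#' @param peaks MS1 peak tibble (`mz`, `intensity`, optional `charge`).
#' @param triggers Tibble with `peptide_id`, `trigger_mz`, `charge`.
#' @param config An [engine_config()].
#' @return The matching rows of `triggers`, with the matched peak intensity
#'   in `matched_intensity`, ordered by descending intensity.
#' @export
monitor_ms1 <- function(peaks, triggers, config = engine_config()) {
  out <- triggers[0, ]
  out$matched_intensity <- numeric(0)
  if (is.null(peaks) || nrow(peaks) == 0 || nrow(triggers) == 0) return(out)
  best <- vapply(seq_len(nrow(triggers)), function(i) {
    ok <- ppm_diff(peaks$mz, triggers$trigger_mz[i]) <= config$ms1_match_ppm &
      peaks$intensity >= config$trigger_min_intensity
    if ("charge" %in% names(peaks)) {
      ok <- ok & (is.na(peaks$charge) | peaks$charge == triggers$charge[i])
    }
    if (any(ok)) max(peaks$intensity[ok]) else NA_real_
  }, 0)
  if (all(is.na(best))) return(out)
  hits <- triggers[!is.na(best), ]
  hits$matched_intensity <- best[!is.na(best)]
  dplyr::arrange(hits, dplyr::desc(.data$matched_intensity))
}

#' Real-time peak matching
#'
#' Confirms a spectrum's identity by counting library fragments matched
#' within the ppm tolerance; passes when strictly more than 6 (i.e. at
#' least `rtpm_min_peaks`) match. Optionally also requires the matched
#' fragments' observed intensities to rank-order identically to the library
#' (used for target-MS2 confirmation against the stored trigger spectrum).
#'
#' @param peaks Observed spectrum tibble (`mz`, `intensity`).
#' @param library Library spectrum tibble (`mz`, `rel_intensity` normalised
#'   to max 1; `rel_intensity` may be `NA` when only m/z matching applies).
#' @param config An [engine_config()].
#' @param check_count Apply the minimum-match-count rule.
#' @param check_rank Apply the intensity rank-order rule.
#' @return List with `pass` (logical) and `matched_count`.
#' @export
rtpm_match <- function(peaks, library, config = engine_config(),
                       check_count = TRUE, check_rank = FALSE) {
  if (is.null(library) || nrow(library) == 0) {
    stop("empty library spectrum", call. = FALSE)
  }
  matched_int <- rep(NA_real_, nrow(library))
  if (!is.null(peaks) && nrow(peaks) > 0) {
    matched_int <- best_match_intensity(peaks, library$mz, config$rtpm_ppm)
  }
  matched <- !is.na(matched_int)
  pass <- TRUE
  if (check_count) pass <- sum(matched) >= config$rtpm_min_peaks
  if (pass && check_rank) {
    lib_rel <- library$rel_intensity[matched]
    if (sum(matched) >= 2 && !anyNA(lib_rel) && stats::sd(lib_rel) > 0 &&
        stats::sd(matched_int[matched]) > 0) {
      rho <- stats::cor(rank(matched_int[matched]), rank(lib_rel))
      pass <- rho >= config$rtpm_rank_min_cor
    }
  }
  list(pass = pass, matched_count = sum(matched))
}

#' Build a library spectrum from a trigger MS2
#'
#' @param peaks Trigger MS2 peak tibble.
#' @param fragments Theoretical fragment table for the trigger peptide
#'   ([fragment_ions()]); only peaks matching a theoretical fragment are
#'   stored.
#' @param config An [engine_config()].
#' @return Tibble (`mz`, `rel_intensity`, `series`, `index`,
#'   `carries_label`) with intensities normalised to max 1.
#' @export
library_spectrum <- function(peaks, fragments, config = engine_config()) {
  best <- best_match_intensity(peaks, fragments$mz, config$rtpm_ppm)
  keep <- !is.na(best)
  rows <- fragments[keep, c("mz", "series", "index", "carries_label")]
  if (nrow(rows) == 0) {
    rows$rel_intensity <- numeric(0)
    return(rows[, c("mz", "rel_intensity", "series", "index",
                    "carries_label")])
  }
  rows$rel_intensity <- best[keep] / max(best[keep])
  rows[, c("mz", "rel_intensity", "series", "index", "carries_label")]
}

# highest-intensity peak within ppm of each reference m/z (NA when none)
best_match_intensity <- function(peaks, ref_mz, ppm) {
  if (is.null(peaks) || nrow(peaks) == 0) return(rep(NA_real_, length(ref_mz)))
  ok <- abs(outer(peaks$mz, ref_mz, "-")) <=
    outer(rep(1, nrow(peaks)), ref_mz) * ppm * 1e-6
  vapply(seq_along(ref_mz), function(i) {
    if (any(ok[, i])) max(peaks$intensity[ok[, i]]) else NA_real_
  }, 0)
}

#' Select SPS ions from a target MS2
#'
#' Candidates are label-carrying b/y fragments present in the stored
#' library; each must (i) match an observed peak within the ppm tolerance,
#' (ii) have observed relative intensity within the fractional ratio
#' tolerance of the library relative intensity, and (iii) pass the purity
#' filter: the candidate's intensity must account for at least
#' `sps_purity_min` of all signal within the purity window centred on it.
#' At most `sps_max_ions` survivors are returned, most intense first.
#'
#' @param peaks Target MS2 peak tibble (`mz`, `intensity`).
#' @param library A [library_spectrum()] (from the paired trigger MS2; the
#'   target fragments sit at the same m/z only for label-free fragments, so
#'   the library is matched against the target's own theoretical m/z via
#'   `target_fragments`).
#' @param target_fragments Theoretical fragments of the target peptide with
#'   `series`, `index`, `mz`, `carries_label`.
#' @param config An [engine_config()].
#' @return Tibble of selected peaks (`mz`, `intensity`, `series`, `index`,
#'   `purity`); zero rows when no candidate survives.
#' @export
select_sps_ions <- function(peaks, library, target_fragments,
                            config = engine_config()) {
  empty <- tibble::tibble(mz = numeric(0), intensity = numeric(0),
                          series = character(0), index = integer(0),
                          purity = numeric(0))
  if (is.null(peaks) || nrow(peaks) == 0 || nrow(library) == 0) return(empty)
  cand <- dplyr::inner_join(
    library[library$carries_label, c("series", "index", "rel_intensity")],
    target_fragments[target_fragments$carries_label,
                     c("series", "index", "mz")],
    by = c("series", "index"))
  if (nrow(cand) == 0) return(empty)
  base_peak <- max(peaks$intensity)
  half_win <- config$sps_purity_window / 2
  obs <- best_match_intensity(peaks, cand$mz, config$rtpm_ppm)
  ratio_ok <- !is.na(obs) &
    abs(obs / base_peak - cand$rel_intensity) / cand$rel_intensity <=
      config$sps_ratio_tolerance
  purity <- vapply(seq_len(nrow(cand)), function(i) {
    if (!ratio_ok[i]) return(NA_real_)
    obs[i] / sum(peaks$intensity[abs(peaks$mz - cand$mz[i]) <= half_win])
  }, 0)
  keep <- ratio_ok & !is.na(purity) & purity >= config$sps_purity_min
  if (!any(keep)) return(empty)
  rows <- tibble::tibble(mz = cand$mz[keep], intensity = obs[keep],
                         series = cand$series[keep],
                         index = cand$index[keep], purity = purity[keep])
  rows <- dplyr::arrange(rows, dplyr::desc(.data$intensity))
  utils::head(rows, config$sps_max_ions)
}

#' Prescan-scaled MS3 injection time
#'
#' Scales the MS3 injection time from the short reporter prescan so that
#' the expected accumulated signal reaches the MS3 AGC target, capped at
#' the configured maximum: weak prescan signal yields the cap, and doubling
#' the prescan signal halves the returned time below the cap.
#'
#' @param prescan_signal Total reporter signal observed in the prescan.
#' @param config An [engine_config()].
#' @return Injection time in milliseconds.
#' @export
prescan_injection_time <- function(prescan_signal, config = engine_config()) {
  if (any(prescan_signal < 0)) stop("negative prescan signal", call. = FALSE)
  pmin(config$ms3_max_inject_ms,
       config$prescan_inject_ms * config$target_agc_ms3 /
         pmax(prescan_signal, .Machine$double.eps))
}

#' Run the triggered-acquisition cascade over a simulated run
#'
#' Iterates the MS1 survey stream in time order and replays the real-time
#' decision cascade for each matched trigger: (1) MS1 precursor match;
#' (2) trigger MS2 insertion and RTPM identity confirmation against the
#' trigger's theoretical fragments, storing the spectrum as the library;
#' (3) target MS2 insertion at the known label-offset m/z, confirmation
#' against the library, and SPS ion selection; (4) reporter prescan and
#' injection-time estimation; (5) SPS-MS3 quantification scan. Dependent
#' scans are materialised deterministically from ground truth at the
#' request's retention time, so the whole cascade is reproducible given
#' (run, config). Multiple trigger matches within one MS1 are serviced in
#' descending precursor intensity, one cascade per trigger per cycle.
#'
#' @param run A `"sim_run"` in `"triggered"` mode.
#' @param config An [engine_config()].
#' @param triggers Optional trigger table override (defaults to the run's
#'   own peptides).
#' @return List of class `"acquisition"`: `log` (tibble `rt_min`, `event`,
#'   `peptide_id`, `detail`), `ms3` (tibble of emitted MS3 scans:
#'   `peptide_id`, `rt_min`, `inject_ms`, `n_sps`, `noise`, list-column
#'   `peaks`), `config`.
#' @export
run_engine <- function(run, config = engine_config(), triggers = NULL) {
  if (!inherits(run, "sim_run") || run$mode != "triggered") {
    stop("`run` must be a sim_run in triggered mode", call. = FALSE)
  }
  if (is.null(triggers)) {
    triggers <- dplyr::select(run$truth$peptide, "peptide_id", "trigger_mz",
                              "target_mz", "charge", "sequence", "label")
  }
  scans <- run$scans
  if (is.unsorted(scans$rt_min)) {
    stop("malformed scan stream: scans not time-ordered (first offending ",
         "scan index ", which(diff(scans$rt_min) < 0)[1] + 1L, ")",
         call. = FALSE)
  }
  mods <- run$truth$mods
  log_rows <- list(); ms3_rows <- list()
  note <- function(rt, event, pid, detail = NA_character_) {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      rt_min = rt, event = event, peptide_id = pid, detail = detail)
  }
  frags_of <- function(seq, lab) fragments_cached(seq, lab, mods)

  ms1_idx <- which(scans$level == "MS1")
  for (k in ms1_idx) {
    rt <- scans$rt_min[k]
    hits <- monitor_ms1(run$peaks[[k]], triggers, config)
    for (h in seq_len(nrow(hits))) {
      pid <- hits$peptide_id[h]
      note(rt, "MS1_MATCH", pid, sprintf("intensity=%.4g",
                                         hits$matched_intensity[h]))
      trig_frags <- frags_of(hits$sequence[h], "tmtsh")
      tms2 <- materialize_scan(run, pid, "TRIGGER_MS2", rt)
      note(rt, "TRIGGER_MS2", pid)
      chk <- rtpm_match(tms2$peaks,
                        tibble::tibble(mz = trig_frags$mz,
                                       rel_intensity = NA_real_),
                        config, check_count = TRUE, check_rank = FALSE)
      note(rt, if (chk$pass) "RTPM_PASS" else "RTPM_FAIL", pid,
           sprintf("matched=%d", chk$matched_count))
      if (!chk$pass) next
      lib <- library_spectrum(tms2$peaks, trig_frags, config)
      if (nrow(lib) == 0) next
      tgt_frags <- frags_of(hits$sequence[h], hits$label[h])
      gms2 <- materialize_scan(run, pid, "TARGET_MS2", rt)
      note(rt, "TARGET_MS2", pid)
      # confirm the target against the library, at the target's own fragment m/z
      lib_target <- dplyr::inner_join(
        dplyr::select(lib, "series", "index", "rel_intensity"),
        dplyr::select(tgt_frags, "series", "index", "mz"),
        by = c("series", "index"))
      conf <- rtpm_match(gms2$peaks, lib_target, config,
                         check_count = config$target_check_count,
                         check_rank = config$target_check_rank)
      note(rt, if (conf$pass) "TARGET_CONFIRM" else "TARGET_FAIL", pid,
           sprintf("matched=%d", conf$matched_count))
      if (!conf$pass) next
      sps <- select_sps_ions(gms2$peaks, lib, tgt_frags, config)
      if (nrow(sps) == 0) next
      note(rt, "SPS_SELECTED", pid, sprintf("n=%d", nrow(sps)))
      pre <- materialize_scan(run, pid, "PRESCAN", rt)
      pre_signal <- sum(pre$peaks$intensity)
      inject <- prescan_injection_time(pre_signal, config)
      note(rt, "PRESCAN", pid, sprintf("signal=%.4g inject=%.4g",
                                       pre_signal, inject))
      q <- materialize_scan(run, pid, "MS3", rt)
      ms3_rows[[length(ms3_rows) + 1L]] <- tibble::tibble(
        peptide_id = pid, rt_min = rt, inject_ms = inject,
        n_sps = nrow(sps), noise = q$noise, peaks = list(q$peaks),
        sps = list(sps))
      note(rt, "MS3", pid)
    }
  }
  structure(
    list(log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
           tibble::tibble(rt_min = numeric(0), event = character(0),
                          peptide_id = character(0), detail = character(0)),
         ms3 = if (length(ms3_rows)) dplyr::bind_rows(ms3_rows) else
           tibble::tibble(peptide_id = character(0), rt_min = numeric(0),
                          inject_ms = numeric(0), n_sps = integer(0),
                          noise = numeric(0), peaks = list(), sps = list()),
         config = config),
    class = "acquisition"
  )
}

#' @export
print.acquisition <- function(x, ...) {
  cat("<acquisition>", nrow(x$log), "events,", nrow(x$ms3), "MS3 scans\n")
  if (nrow(x$log) > 0) {
    print(dplyr::count(x$log, .data$event))
  }
  invisible(x)
}
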