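#' Simulation parameters
#'
#' Tunable knobs of the synthetic LC-MS run generator. Intensities are in
#' arbitrary instrument counts; abundances in amol; retention times in
#' minutes.
#'
#' @param ms1_interval_min Spacing of the MS1 survey grid.
#' @param rt_pad_min Grid padding before the first / after the last apex.
#' @param peak_sigma_min Chromatographic Gaussian sigma (trigger and paired
#'   target co-elute exactly).
#' @param precursor_ion_factor Precursor counts per amol at the elution apex.
#' @param reporter_ion_factor Reporter counts per amol at the apex.
#' @param ms2_yield Fraction of precursor signal converted to the fragment
#'   base peak.
#' @param noise_cv Lognormal per-peak intensity noise (sdlog); 0 = noiseless.
#' @param noise_floor_ms1,noise_floor_ms2,noise_floor_ms3 Per-scan Orbitrap
#'   noise floors (counts) defining S/N at each level.
#' @param interference_density Expected number of injected interference
#'   peaks per MS2 spectrum.
#' @param interference_rel_max Interference intensity ceiling, relative to
#'   the fragment base peak.
#' @param ko_floor_amol Background floor (amol-equivalent) present in every
#'   channel for every analyte species; knockout channels sit at this floor.
#' @param tmtsh_mass Monoisotopic mass of the TMTsh trigger label. The
#'   reagent's mass is not public; this stand-in value is a simulation
#'   parameter, consistent between run generation and engine arithmetic.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(ms1_interval_min = 0.1,
                       rt_pad_min = 0.4,
                       peak_sigma_min = 0.1,
                       precursor_ion_factor = 5e3,
                       reporter_ion_factor = 50,
                       ms2_yield = 0.2,
                       noise_cv = 0,
                       noise_floor_ms1 = 500,
                       noise_floor_ms2 = 50,
                       noise_floor_ms3 = 100,
                       interference_density = 0,
                       interference_rel_max = 0.8,
                       ko_floor_amol = 1,
                       tmtsh_mass = 235.1767) {
  p <- as.list(environment())
  stopifnot(p$ms1_interval_min > 0, p$peak_sigma_min > 0,
            p$noise_cv >= 0, p$ko_floor_amol >= 0)
  structure(p, class = "sim_params")
}

# deterministic substream seed from a master seed and a text tag
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * (seq_len(nchar(tag)) %% 31 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

gauss_profile <- function(rt, apex, sigma) exp(-0.5 * ((rt - apex) / sigma)^2)

# deterministic per-sequence fragment intensity pattern in (0.2, 1]
fragment_pattern <- function(sequence, n) {
  withr::with_seed(substream_seed(7919L, sequence), {
    rel <- stats::runif(n, 0.2, 1)
    rel / max(rel)
  })
}

# Measurement noise: one multiplicative lognormal factor shared by every
# peak in the scan (spray/injection fluctuation; cancels in within-scan
# ratios, as co-eluting trigger/target pairs do on a real instrument) plus
# independent additive detector noise at the scan's noise-floor scale
# (which is what the Orbitrap S/N denominator measures).
apply_scan_noise <- function(intensity, noise_cv, floor_sd) {
  if (noise_cv <= 0) return(intensity)
  fac <- stats::rlnorm(1, -noise_cv^2 / 2, noise_cv)
  pmax(intensity * fac + stats::rnorm(length(intensity), 0, floor_sd), 0)
}

#' Simulate a multiplexed targeted LC-MS run with ground truth
#'
#' Generates a synthetic acquisition with fully known per-(peptide, channel)
#' truth: condition-dependent abundances from the [condition_effects()]
#' model, Gaussian co-eluting trigger/target chromatography, label-aware
#' precursor m/z, and reporter ions mixed through the isotopic impurity
#' matrix. In `"triggered"` mode the pre-generated stream holds the MS1
#' survey scans; dependent scans (trigger/target MS2, prescan, SPS-MS3) are
#' materialised deterministically on request by the acquisition engine via
#' [materialize_scan()]. In `"sim"` mode the stream holds narrow-window SIM
#' scans carrying the trigger and target precursor traces for absolute
#' quantification.
#'
#' @param design A validated design table ([build_design()]).
#' @param channels A [channel_design()].
#' @param effects A [condition_effects()] model.
#' @param engine_mode `"triggered"` or `"sim"`.
#' @param seed Master seed; all stochastic draws descend from it through
#'   named substreams, so equal seeds give identical runs.
#' @param params A [sim_params()].
#' @param impurity Impurity matrix (defaults to [impurity_matrix()] of the
#'   channel count).
#' @return List of class `"sim_run"`: `scans` (tibble: `scan_id`, `level`,
#'   `rt_min`, `peptide_id`, `precursor_mz`, `noise`), `peaks` (list of
#'   per-scan tibbles `mz`, `intensity`, `charge`), `truth` (class
#'   `"ground_truth"`), `mode`, `seed`, `params`.
#' @export
simulate_run <- function(design, channels, effects = condition_effects(),
                         engine_mode = c("triggered", "sim"),
                         seed = 1L, params = sim_params(),
                         impurity = NULL) {
  engine_mode <- match.arg(engine_mode)
  validate_design(design)
  if (nrow(channels) == 0) stop("design without channels", call. = FALSE)
  if (is.null(impurity)) {
    impurity <- impurity_matrix(nrow(channels), channel_ids = channels$channel_id)
  }
  check_impurity(impurity)
  mods <- mod_table(tmtsh_mass = params$tmtsh_mass)

  tg <- design[design$role == "TARGET", ]
  tr <- design[design$role == "TRIGGER", ]
  tr <- tr[match(tg$pair_id, tr$pair_id), ]

  pep <- tibble::tibble(
    peptide_id = tg$peptide_id,
    sequence = tg$sequence,
    charge = tg$charge,
    label = tg$label,
    n_label_sites = tg$n_label_sites,
    sim_group = if ("sim_group" %in% names(tg)) tg$sim_group else "other",
    apex_rt = tg$scheduled_rt_min,
    sigma_rt = params$peak_sigma_min,
    trigger_amol = tr$amount_amol,
    base_amol = tg$amount_amol,
    target_mz = precursor_mz(peptide_mass(tg$sequence, tg$label, mods), tg$charge),
    trigger_mz = precursor_mz(peptide_mass(tg$sequence, "tmtsh", mods), tg$charge),
    carrier_mass_da = ifelse(
      (if ("sim_group" %in% names(tg)) tg$sim_group else "other") %in%
        c("gamma_short", "gamma_long"), 4500, 87000)
  )

  org_scale <- ifelse(channels$organelle == "LYSO", effects$lyso_scale, 1)
  abundance <- purrr::map_dfr(seq_len(nrow(pep)), function(i) {
    mult <- effect_multiplier(effects, pep$sim_group[i], channels$condition)
    tibble::tibble(
      peptide_id = pep$peptide_id[i],
      channel_id = channels$channel_id,
      condition = channels$condition,
      is_ko = channels$is_ko,
      amol = pmax(pep$base_amol[i] * org_scale * mult,
                  if (pep$base_amol[i] > 0) params$ko_floor_amol else 0)
    )
  })

  truth <- structure(
    list(peptide = pep, abundance = abundance, channels = channels,
         impurity = impurity, params = params, seed = as.integer(seed),
         mods = mods),
    class = "ground_truth"
  )

  scans <- if (engine_mode == "triggered") {
    build_ms1_stream(truth)
  } else {
    build_sim_stream(truth)
  }
  structure(
    list(scans = scans$scans, peaks = scans$peaks, truth = truth,
         mode = engine_mode, seed = as.integer(seed), params = params),
    class = "sim_run"
  )
}

# total target abundance (all channels) per peptide, amol
total_target_amol <- function(truth) {
  dplyr::summarise(truth$abundance, amol = sum(.data$amol),
                   .by = "peptide_id")
}

build_ms1_stream <- function(truth) {
  p <- truth$params
  pep <- truth$peptide
  rts <- seq(min(pep$apex_rt) - p$rt_pad_min, max(pep$apex_rt) + p$rt_pad_min,
             by = p$ms1_interval_min)
  tot <- total_target_amol(truth)
  tot <- tot$amol[match(pep$peptide_id, tot$peptide_id)]
  peaks <- vector("list", length(rts))
  for (k in seq_along(rts)) {
    g <- gauss_profile(rts[k], pep$apex_rt, pep$sigma_rt)
    pk <- tibble::tibble(
      mz = c(pep$trigger_mz, pep$target_mz),
      intensity = c(pep$trigger_amol * p$precursor_ion_factor * g,
                    tot * p$precursor_ion_factor * g),
      charge = rep(pep$charge, 2)
    )
    pk <- pk[pk$intensity > 0, ]
    if (nrow(pk) > 0 && p$noise_cv > 0) {
      withr::with_seed(substream_seed(truth$seed, paste0("ms1:", k)), {
        pk$intensity <- apply_scan_noise(pk$intensity, p$noise_cv,
                                         p$noise_floor_ms1)
      })
      pk <- pk[pk$intensity > 0, ]
    }
    peaks[[k]] <- dplyr::arrange(pk, .data$mz)
  }
  list(
    scans = tibble::tibble(scan_id = seq_along(rts), level = "MS1",
                           rt_min = rts, peptide_id = NA_character_,
                           precursor_mz = NA_real_,
                           noise = truth$params$noise_floor_ms1),
    peaks = peaks
  )
}

build_sim_stream <- function(truth) {
  p <- truth$params
  pep <- truth$peptide
  tot <- total_target_amol(truth)
  tot <- tot$amol[match(pep$peptide_id, tot$peptide_id)]
  rows <- list(); peaks <- list()
  for (i in seq_len(nrow(pep))) {
    rts <- seq(pep$apex_rt[i] - 4 * pep$sigma_rt[i],
               pep$apex_rt[i] + 4 * pep$sigma_rt[i],
               by = p$ms1_interval_min)
    for (k in seq_along(rts)) {
      g <- gauss_profile(rts[k], pep$apex_rt[i], pep$sigma_rt[i])
      pk <- tibble::tibble(
        mz = c(pep$trigger_mz[i], pep$target_mz[i]),
        intensity = c(pep$trigger_amol[i], tot[i]) * p$precursor_ion_factor * g,
        charge = pep$charge[i]
      )
      pk <- pk[pk$intensity > 0, ]
      if (nrow(pk) > 0 && p$noise_cv > 0) {
        withr::with_seed(
          substream_seed(truth$seed, paste0("sim:", pep$peptide_id[i], ":", k)), {
            pk$intensity <- apply_scan_noise(pk$intensity, p$noise_cv,
                                             p$noise_floor_ms1)
          })
        pk <- pk[pk$intensity > 0, ]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        level = "SIM", rt_min = rts[k], peptide_id = pep$peptide_id[i],
        precursor_mz = pep$target_mz[i], noise = p$noise_floor_ms1)
      peaks[[length(peaks) + 1L]] <- pk
    }
  }
  scans <- dplyr::bind_rows(rows)
  scans <- dplyr::mutate(scans, scan_id = dplyr::row_number(), .before = 1)
  ord <- order(scans$rt_min)
  list(scans = scans[ord, ], peaks = peaks[ord])
}

#' Materialise a dependent scan from ground truth
#'
#' Builds the spectrum the instrument would have produced had it inserted a
#' scan of the given level at the given retention time, deterministically
#' from the run's ground truth and seed: trigger/target MS2 fragment spectra
#' (shared relative fragmentation pattern, since trigger and target are the
#' same chemistry; plus injected interference peaks), reporter prescans, and
#' impurity-mixed SPS-MS3 reporter spectra.
#'
#' @param run A `"sim_run"`.
#' @param peptide_id Which monitored peptide the scan is for.
#' @param level `"TRIGGER_MS2"`, `"TARGET_MS2"`, `"PRESCAN"` or `"MS3"`.
#' @param rt_min Retention time of the request.
#' @return List with `peaks` (tibble `mz`, `intensity`), `noise` (scan noise
#'   floor) and `rt_min`.
#' @export
materialize_scan <- function(run, peptide_id,
                             level = c("TRIGGER_MS2", "TARGET_MS2",
                                       "PRESCAN", "MS3"),
                             rt_min) {
  level <- match.arg(level)
  truth <- run$truth
  p <- truth$params
  i <- match(peptide_id, truth$peptide$peptide_id)
  if (is.na(i)) stop("unknown peptide_id: ", peptide_id, call. = FALSE)
  pep <- truth$peptide[i, ]
  g <- gauss_profile(rt_min, pep$apex_rt, pep$sigma_rt)
  tag <- paste(level, peptide_id, format(rt_min, digits = 12), sep = ":")

  if (level %in% c("TRIGGER_MS2", "TARGET_MS2")) {
    lab <- if (level == "TRIGGER_MS2") "tmtsh" else pep$label
    amol <- if (level == "TRIGGER_MS2") {
      pep$trigger_amol
    } else {
      sum(truth$abundance$amol[truth$abundance$peptide_id == peptide_id])
    }
    frags <- fragments_cached(pep$sequence, lab, truth$mods)
    rel <- fragment_pattern(pep$sequence, nrow(frags))
    base <- amol * p$precursor_ion_factor * p$ms2_yield * g
    pk <- tibble::tibble(mz = frags$mz, intensity = rel * base)
    pk <- pk[pk$intensity > 0, ]
    withr::with_seed(substream_seed(truth$seed, tag), {
      if (p$interference_density > 0 && base > 0) {
        n_int <- stats::rpois(1, p$interference_density)
        if (n_int > 0) {
          lo <- min(frags$mz) - 5; hi <- max(frags$mz) + 5
          pk <- dplyr::bind_rows(pk, tibble::tibble(
            mz = stats::runif(n_int, lo, hi),
            intensity = stats::runif(n_int, 0, p$interference_rel_max) * base))
        }
      }
      if (nrow(pk) > 0 && p$noise_cv > 0) {
        pk$intensity <- apply_scan_noise(pk$intensity, p$noise_cv,
                                         p$noise_floor_ms2)
        pk <- pk[pk$intensity > 0, ]
      }
    })
    return(list(peaks = dplyr::arrange(pk, .data$mz),
                noise = p$noise_floor_ms2, rt_min = rt_min))
  }

  # reporter-bearing scans: impurity-mixed channel abundances
  ab <- truth$abundance[truth$abundance$peptide_id == peptide_id, ]
  ab <- ab[match(truth$channels$channel_id, ab$channel_id), ]
  mixed <- drop(truth$impurity %*% (ab$amol * p$reporter_ion_factor * g))
  pk <- tibble::tibble(mz = truth$channels$reporter_mz, intensity = mixed)
  pk <- pk[pk$intensity > 0, ]
  noise <- if (level == "PRESCAN") p$noise_floor_ms2 else p$noise_floor_ms3
  withr::with_seed(substream_seed(truth$seed, tag), {
    if (nrow(pk) > 0 && p$noise_cv > 0) {
      pk$intensity <- apply_scan_noise(pk$intensity, p$noise_cv, noise)
      pk <- pk[pk$intensity > 0, ]
    }
  })
  list(peaks = pk, noise = noise, rt_min = rt_min)
}

#' @export
print.sim_run <- function(x, ...) {
  cat("<sim_run> mode:", x$mode, "| scans:", nrow(x$scans),
      "| peptides:", nrow(x$truth$peptide),
      "| channels:", nrow(x$truth$channels), "| seed:", x$seed, "\n")
  invisible(x)
}
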