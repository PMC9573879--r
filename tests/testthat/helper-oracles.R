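# Independent brute-force oracles, kept deliberately naive: plain loops,
# no indexing, no reuse of package internals beyond shared constants.

AA_ORACLE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_O <- 18.010565
PROTON_O <- 1.007276

oracle_peptide_mass <- function(seq) {
  sum(AA_ORACLE[strsplit(seq, "")[[1]]]) + WATER_O
}

# brute-force fragment calculator: explicit substring sums
oracle_fragments <- function(seq, charge = 1, cam = 57.021) {
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  AA_ORACLE <- AA_ORACLE
  AA_ORACLE["C"] <- AA_ORACLE["C"] + cam   # static alkylation
  out <- list()
  for (i in seq_len(L - 1)) {
    b <- sum(AA_ORACLE[aa[1:i]])
    y <- sum(AA_ORACLE[aa[(L - i + 1):L]]) + WATER_O
    out[[length(out) + 1]] <- data.frame(
      series = c("b", "y"), index = i,
      mz = c((b + charge * PROTON_O) / charge,
             (y + charge * PROTON_O) / charge))
  }
  do.call(rbind, out)
}

random_peptide <- function(len, with_k = FALSE) {
  letters20 <- names(AA_ORACLE)
  s <- paste(sample(letters20, len, replace = TRUE), collapse = "")
  if (with_k && !grepl("K", s)) {
    substr(s, len, len) <- "K"
  }
  s
}

# --- engine decision oracle: exhaustive re-implementation ------------------

oracle_ppm_ok <- function(obs, ref, ppm) abs(obs - ref) / ref * 1e6 <= ppm

oracle_monitor_ms1 <- function(peaks, triggers, cfg) {
  hits <- character(0); ints <- numeric(0)
  for (i in seq_len(nrow(triggers))) {
    best <- NA_real_
    for (j in seq_len(nrow(peaks))) {
      if (oracle_ppm_ok(peaks$mz[j], triggers$trigger_mz[i], cfg$ms1_match_ppm) &&
          peaks$intensity[j] >= cfg$trigger_min_intensity &&
          (!"charge" %in% names(peaks) || is.na(peaks$charge[j]) ||
             peaks$charge[j] == triggers$charge[i])) {
        if (is.na(best) || peaks$intensity[j] > best) best <- peaks$intensity[j]
      }
    }
    if (!is.na(best)) { hits <- c(hits, triggers$peptide_id[i]); ints <- c(ints, best) }
  }
  hits[order(-ints)]
}

oracle_rtpm_count <- function(peaks, lib_mz, ppm) {
  n <- 0
  for (m in lib_mz) {
    found <- FALSE
    for (j in seq_len(nrow(peaks))) {
      if (oracle_ppm_ok(peaks$mz[j], m, ppm)) found <- TRUE
    }
    if (found) n <- n + 1
  }
  n
}

# full cascade oracle over a simulated run; returns per-MS1 list of emitted
# MS3 peptide ids in service order, plus the total MS3 count
oracle_run_engine <- function(run, cfg) {
  truth <- run$truth
  trig <- truth$peptide
  emitted <- character(0)
  events <- character(0)
  for (k in which(run$scans$level == "MS1")) {
    rt <- run$scans$rt_min[k]
    peaks <- run$peaks[[k]]
    if (nrow(peaks) == 0) next
    hits <- oracle_monitor_ms1(
      peaks, data.frame(peptide_id = trig$peptide_id,
                        trigger_mz = trig$trigger_mz, charge = trig$charge),
      cfg)
    for (pid in hits) {
      i <- which(trig$peptide_id == pid)
      events <- c(events, paste0("MATCH:", pid))
      trig_frags <- tomahaqr::fragment_ions(trig$sequence[i], 1L, "tmtsh",
                                            truth$mods)
      tms2 <- tomahaqr::materialize_scan(run, pid, "TRIGGER_MS2", rt)
      if (oracle_rtpm_count(tms2$peaks, trig_frags$mz, cfg$rtpm_ppm) <
          cfg$rtpm_min_peaks) next
      # library: theoretical trigger fragments matched in the trigger MS2
      lib <- list()
      for (f in seq_len(nrow(trig_frags))) {
        best <- NA_real_
        for (j in seq_len(nrow(tms2$peaks))) {
          if (oracle_ppm_ok(tms2$peaks$mz[j], trig_frags$mz[f], cfg$rtpm_ppm)) {
            if (is.na(best) || tms2$peaks$intensity[j] > best)
              best <- tms2$peaks$intensity[j]
          }
        }
        if (!is.na(best)) {
          lib[[length(lib) + 1]] <- data.frame(
            series = trig_frags$series[f], index = trig_frags$index[f],
            carries_label = trig_frags$carries_label[f], intensity = best)
        }
      }
      if (length(lib) == 0) next
      lib <- do.call(rbind, lib)
      lib$rel <- lib$intensity / max(lib$intensity)
      tgt_frags <- tomahaqr::fragment_ions(trig$sequence[i], 1L,
                                           trig$label[i], truth$mods)
      gms2 <- tomahaqr::materialize_scan(run, pid, "TARGET_MS2", rt)
      # target confirmation at the target's own fragment m/z
      lib_t_mz <- numeric(0); lib_t_rel <- numeric(0); obs_int <- numeric(0)
      for (r in seq_len(nrow(lib))) {
        f <- which(tgt_frags$series == lib$series[r] &
                     tgt_frags$index == lib$index[r])
        lib_t_mz <- c(lib_t_mz, tgt_frags$mz[f])
        lib_t_rel <- c(lib_t_rel, lib$rel[r])
      }
      matched <- rep(FALSE, length(lib_t_mz))
      obs_at <- rep(NA_real_, length(lib_t_mz))
      for (r in seq_along(lib_t_mz)) {
        for (j in seq_len(nrow(gms2$peaks))) {
          if (oracle_ppm_ok(gms2$peaks$mz[j], lib_t_mz[r], cfg$rtpm_ppm)) {
            matched[r] <- TRUE
            if (is.na(obs_at[r]) || gms2$peaks$intensity[j] > obs_at[r])
              obs_at[r] <- gms2$peaks$intensity[j]
          }
        }
      }
      ok <- TRUE
      if (cfg$target_check_count) ok <- sum(matched) >= cfg$rtpm_min_peaks
      if (ok && cfg$target_check_rank && sum(matched) >= 2) {
        a <- obs_at[matched]; b <- lib_t_rel[matched]
        # naive rank correlation: count, for each element, how many are
        # smaller, then Pearson on those ranks
        rk <- function(v) vapply(v, function(x) {
          1 + sum(v < x) + (sum(v == x) - 1) / 2
        }, 0)
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          ra <- rk(a); rb <- rk(b)
          rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
            sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
          ok <- rho >= cfg$rtpm_rank_min_cor
        }
      }
      if (!ok) next
      # SPS selection
      base_peak <- max(gms2$peaks$intensity)
      n_sps <- 0
      for (r in seq_len(nrow(lib))) {
        if (!lib$carries_label[r]) next
        f <- which(tgt_frags$series == lib$series[r] &
                     tgt_frags$index == lib$index[r])
        if (!tgt_frags$carries_label[f]) next
        best <- NA_real_
        for (j in seq_len(nrow(gms2$peaks))) {
          if (oracle_ppm_ok(gms2$peaks$mz[j], tgt_frags$mz[f], cfg$rtpm_ppm)) {
            if (is.na(best) || gms2$peaks$intensity[j] > best)
              best <- gms2$peaks$intensity[j]
          }
        }
        if (is.na(best)) next
        if (abs(best / base_peak - lib$rel[r]) / lib$rel[r] >
            cfg$sps_ratio_tolerance) next
        win <- abs(gms2$peaks$mz - tgt_frags$mz[f]) <= cfg$sps_purity_window / 2
        if (best / sum(gms2$peaks$intensity[win]) < cfg$sps_purity_min) next
        n_sps <- n_sps + 1
      }
      if (n_sps == 0) next
      emitted <- c(emitted, pid)
      events <- c(events, paste0("MS3:", pid))
    }
  }
  list(emitted = emitted, events = events)
}

# small random run builder shared by engine tests
random_small_run <- function(seed, n_peptides = 2, noise_cv = 0.1,
                             interference = 3) {
  withr::with_seed(seed, {
    seqs <- unique(vapply(seq_len(n_peptides), function(i)
      random_peptide(sample(7:11, 1), with_k = TRUE), ""))
    des <- dplyr::bind_rows(lapply(seq_along(seqs), function(i) {
      tibble::tibble(
        peptide_id = paste0("pep", i), pair_id = paste0("pep", i),
        sequence = seqs[i], termini = "full_tryptic",
        sim_group = "other", label = c("tmtsh", "tmt"),
        n_label_sites = tomahaqr::n_label_sites(seqs[i]),
        charge = 2L, scheduled_rt_min = 10 + i,
        role = c("TRIGGER", "TARGET"),
        amount_amol = c(100, stats::runif(1, 50, 400)))
    }))
    ch <- tomahaqr::channel_design(c("DMSO", "DMSO", "BSI", "KO"))
    tomahaqr::simulate_run(
      des, ch, seed = seed,
      params = tomahaqr::sim_params(noise_cv = noise_cv,
                                    interference_density = interference,
                                    ms1_interval_min = 0.08))
  })
}
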