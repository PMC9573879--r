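cfg <- engine_config()

test_that("MS1 monitoring enforces ppm, charge and intensity thresholds", {
  trig <- tibble::tibble(peptide_id = "p1", trigger_mz = 800, charge = 2L)
  expect_equal(nrow(monitor_ms1(tibble::tibble(mz = numeric(0),
                                               intensity = numeric(0)),
                                trig, cfg)), 0)
  pk <- tibble::tibble(mz = 800 * (1 + 9e-6), intensity = 1e5, charge = 2L)
  expect_equal(monitor_ms1(pk, trig, cfg)$peptide_id, "p1")
  # 11 ppm away: no match
  pk$mz <- 800 * (1 + 11e-6)
  expect_equal(nrow(monitor_ms1(pk, trig, cfg)), 0)
  # below the intensity minimum: no match
  pk <- tibble::tibble(mz = 800, intensity = 4e4, charge = 2L)
  expect_equal(nrow(monitor_ms1(pk, trig, cfg)), 0)
  # wrong charge: no match
  pk <- tibble::tibble(mz = 800, intensity = 1e5, charge = 3L)
  expect_equal(nrow(monitor_ms1(pk, trig, cfg)), 0)
  # multiple matches serviced in descending intensity
  trig2 <- tibble::tibble(peptide_id = c("a", "b"),
                          trigger_mz = c(800, 900), charge = 2L)
  pk2 <- tibble::tibble(mz = c(800, 900), intensity = c(1e5, 5e5),
                        charge = 2L)
  expect_equal(monitor_ms1(pk2, trig2, cfg)$peptide_id, c("b", "a"))
})

test_that("RTPM passes at 7 matched peaks and fails at 6", {
  lib <- tibble::tibble(mz = seq(300, 1200, length.out = 10),
                        rel_intensity = NA_real_)
  full <- tibble::tibble(mz = lib$mz, intensity = 10:1)
  expect_true(rtpm_match(full, lib, cfg)$pass)
  six <- full[1:6, ]
  seven <- full[1:7, ]
  expect_false(rtpm_match(six, lib, cfg)$pass)
  expect_equal(rtpm_match(six, lib, cfg)$matched_count, 6)
  expect_true(rtpm_match(seven, lib, cfg)$pass)
  # a uniform +25 ppm shift defeats matching
  shifted <- dplyr::mutate(full, mz = mz * (1 + 25e-6))
  expect_false(rtpm_match(shifted, lib, cfg)$pass)
  expect_error(rtpm_match(full, lib[0, ], cfg), "empty library")
})

test_that("RTPM rank-order check compares against the stored library", {
  lib <- tibble::tibble(mz = c(300, 400, 500, 600, 700, 800, 900),
                        rel_intensity = c(1, .9, .8, .7, .6, .5, .4))
  good <- tibble::tibble(mz = lib$mz, intensity = c(70, 60, 50, 40, 30, 20, 10))
  expect_true(rtpm_match(good, lib, cfg, check_rank = TRUE)$pass)
  bad <- tibble::tibble(mz = lib$mz, intensity = c(10, 60, 50, 40, 30, 20, 70))
  expect_false(rtpm_match(bad, lib, cfg, check_rank = TRUE)$pass)
})

test_that("SPS selection applies label, ratio and purity filters", {
  frag <- tibble::tibble(series = c("b", "b", "y"), index = c(1L, 2L, 1L),
                         mz = c(300, 400, 500),
                         carries_label = c(TRUE, TRUE, FALSE))
  lib <- tibble::tibble(mz = c(300, 400, 500),
                        rel_intensity = c(0.5, 1, 0.9),
                        series = c("b", "b", "y"), index = c(1L, 2L, 1L),
                        carries_label = c(TRUE, TRUE, FALSE))
  # observed rel 0.8 vs library 0.5: |0.8-0.5|/0.5 = 0.6 > 0.5 -> rejected
  pk <- tibble::tibble(mz = c(300, 400), intensity = c(80, 100))
  out <- select_sps_ions(pk, lib, frag, cfg)
  expect_equal(out$mz, 400)
  # within ratio tolerance -> kept, most intense first
  pk2 <- tibble::tibble(mz = c(300, 400), intensity = c(60, 100))
  out2 <- select_sps_ions(pk2, lib, frag, cfg)
  expect_equal(out2$mz, c(400, 300))
  # purity: 60 signal + 40 interference inside 3 Th window -> 0.6, kept
  pk3 <- tibble::tibble(mz = c(300, 301, 400), intensity = c(60, 40, 120))
  out3 <- select_sps_ions(pk3, lib, frag, cfg)
  expect_equal(out3$purity[out3$mz == 300], 0.6, tolerance = 1e-12)
  # purity below 0.5 -> dropped
  pk4 <- tibble::tibble(mz = c(300, 301, 400), intensity = c(49, 51, 100))
  expect_false(300 %in% select_sps_ions(pk4, lib, frag, cfg)$mz)
  # purity just above 0.5 -> kept
  pk5 <- tibble::tibble(mz = c(300, 301, 400), intensity = c(51, 49, 100))
  expect_true(300 %in% select_sps_ions(pk5, lib, frag, cfg)$mz)
  # unlabeled y1 never selected, however intense
  pk6 <- tibble::tibble(mz = c(400, 500), intensity = c(100, 1e6))
  expect_false(500 %in% select_sps_ions(pk6, lib, frag, cfg)$mz)
  # sps_max_ions caps the list
  cfg1 <- engine_config(sps_max_ions = 1L)
  expect_equal(nrow(select_sps_ions(pk2, lib, frag, cfg1)), 1)
})

test_that("prescan scaling sets injection time with a hard cap", {
  expect_equal(prescan_injection_time(cfg$target_agc_ms3, cfg),
               cfg$prescan_inject_ms)
  expect_equal(prescan_injection_time(0, cfg), cfg$ms3_max_inject_ms)
  t1 <- prescan_injection_time(cfg$target_agc_ms3 * 2, cfg)
  t2 <- prescan_injection_time(cfg$target_agc_ms3 * 4, cfg)
  expect_equal(t1 / t2, 2, tolerance = 1e-12)
  sig <- c(10, 100, 1000) * cfg$target_agc_ms3
  expect_true(all(diff(prescan_injection_time(sig, cfg)) <= 0))
  expect_error(prescan_injection_time(-1, cfg), "negative")
})

test_that("a clean run emits one MS3 per trigger per qualifying MS1 cycle", {
  run <- random_small_run(5, n_peptides = 1, noise_cv = 0, interference = 0)
  acq <- run_engine(run, cfg)
  n_match <- sum(acq$log$event == "MS1_MATCH")
  expect_gt(n_match, 0)
  expect_equal(nrow(acq$ms3), n_match)   # no filter should fire
  # all MS3 near the elution apex
  apex <- run$truth$peptide$apex_rt[1]
  expect_true(all(abs(acq$ms3$rt_min - apex) < 0.3))
})

test_that("no trigger peaks means no cascade", {
  run <- random_small_run(6, n_peptides = 1, noise_cv = 0, interference = 0)
  foreign <- dplyr::mutate(run$truth$peptide, trigger_mz = trigger_mz + 50)
  acq <- run_engine(run, cfg, triggers = foreign)
  expect_equal(nrow(acq$ms3), 0)
  expect_false(any(acq$log$event == "MS1_MATCH"))
})

test_that("an unsatisfiable purity filter suppresses every MS3", {
  run <- random_small_run(7, n_peptides = 1, noise_cv = 0, interference = 0)
  acq <- run_engine(run, engine_config(sps_purity_min = 1.01))
  expect_equal(nrow(acq$ms3), 0)
  expect_true(any(acq$log$event == "TARGET_CONFIRM"))
})

test_that("no MS3 is emitted for a target whose trigger failed RTPM", {
  n_ms3_total <- 0
  for (s in 1:10) {
    run <- random_small_run(100 + s, n_peptides = 2, noise_cv = 0.3,
                            interference = 8)
    acq <- run_engine(run, cfg)
    lg <- acq$log
    n_ms3_total <- n_ms3_total + sum(lg$event == "MS3")
    for (i in which(lg$event == "MS3")) {
      prior <- lg[seq_len(i - 1), ]
      prior <- prior[prior$peptide_id == lg$peptide_id[i], ]
      expect_true(any(prior$event == "RTPM_PASS"))
      expect_true(any(prior$event == "PRESCAN"))
      expect_true(any(prior$event == "TARGET_MS2"))
    }
  }
  # noise and interference must not silence the cascade entirely
  expect_gt(n_ms3_total, 0)
})

test_that("tightening any threshold never increases emitted MS3 scans", {
  run <- random_small_run(55, n_peptides = 2, noise_cv = 0.25,
                          interference = 6)
  base_n <- nrow(run_engine(run, cfg)$ms3)
  tighter <- list(
    engine_config(rtpm_min_peaks = 9L),
    engine_config(sps_purity_min = 0.8),
    engine_config(sps_ratio_tolerance = 0.2),
    engine_config(trigger_min_intensity = 5e5),
    engine_config(ms1_match_ppm = 2)
  )
  for (cf in tighter) {
    expect_lte(nrow(run_engine(run, cf)$ms3), base_n)
  }
})

test_that("malformed (unordered) scan streams are rejected with the scan index", {
  run <- random_small_run(8, n_peptides = 1)
  run$scans$rt_min <- rev(run$scans$rt_min)
  expect_error(run_engine(run), "scan index")
})

test_that("engine decisions agree with the exhaustive oracle on random runs", {
  for (s in 1:15) {
    run <- random_small_run(200 + s, n_peptides = 2,
                            noise_cv = stats::runif(1, 0, 0.3),
                            interference = sample(0:8, 1))
    acq <- run_engine(run, cfg)
    orc <- oracle_run_engine(run, cfg)
    expect_identical(acq$ms3$peptide_id, orc$emitted)
  }
})
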