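test_that("reporter extraction respects the integration window and sums", {
  mzs <- c(`126` = 126.127726, `127N` = 127.124761)
  empty <- extract_reporters(NULL, mzs)
  expect_equal(empty$intensity, c(0, 0))
  pk <- tibble::tibble(mz = 126.127726 + 0.002, intensity = 10)
  expect_equal(extract_reporters(pk, mzs)$intensity, c(10, 0))
  pk$mz <- 126.127726 + 0.004
  expect_equal(extract_reporters(pk, mzs)$intensity, c(0, 0))
  two <- tibble::tibble(mz = 126.127726 + c(-0.002, 0.002),
                        intensity = c(10, 5))
  out <- extract_reporters(two, mzs, noise = 3)
  expect_equal(out$intensity[1], 15)
  expect_equal(out$sn[1], 5)
  # adjacent N/C channels are 0.0063 Th apart: 0.004 Da tolerance overlaps
  expect_error(extract_reporters(pk, c(a = 127.124761, b = 127.131081),
                                 tolerance_da = 0.004), "overlap")
})

test_that("impurity correction inverts the mixing model", {
  expect_equal(impurity_correct(c(9, 4), diag(2)), c(9, 4))
  M <- matrix(c(0.95, 0.05, 0.05, 0.95), 2)
  expect_equal(impurity_correct(c(95, 5), M), c(100, 0), tolerance = 1e-12)
  withr::with_seed(9, {
    for (i in 1:20) {
      n <- sample(3:11, 1)
      M <- impurity_matrix(n, minus = stats::runif(1, 0, 0.05),
                           plus = stats::runif(1, 0, 0.05))
      x <- stats::runif(n, 0, 1000)
      expect_equal(impurity_correct(mix_reporters(x, M), M), x,
                   tolerance = 1e-9)
    }
  })
  expect_error(impurity_correct(c(1, 1), matrix(c(1, 1e-13, 1e-13, 1e-13), 2)),
               "dominant|singular")
  # negatives clamp to zero
  M2 <- impurity_matrix(2, minus = 0.1, plus = 0.1)
  expect_true(all(impurity_correct(c(0.05, 1), M2) >= 0))
})

make_qt <- function(mat, conditions, ko = grepl("KO", conditions)) {
  ch <- channel_design(conditions)
  sn <- tibble::tibble(
    peptide_id = rep(rownames(mat), each = ncol(mat)),
    channel_id = rep(ch$channel_id, nrow(mat)),
    condition = rep(ch$condition, nrow(mat)),
    is_ko = rep(ch$is_ko, nrow(mat)),
    sn_raw = as.vector(t(mat)), sn = as.vector(t(mat)))
  structure(list(sn = sn, channels = ch,
                 n_scans = tibble::tibble(peptide_id = rownames(mat),
                                          n_scans = 1L),
                 impurity = diag(ncol(mat)), normalized = FALSE),
            class = "quant_table")
}

test_that("total-reporter normalisation equalises channel sums, idempotently", {
  m <- rbind(p1 = c(10, 20, 10), p2 = c(30, 60, 30))
  qt <- make_qt(m, c("DMSO", "DMSO", "KO"))
  qn <- normalize_total(qt)
  sums <- tapply(qn$sn$sn, qn$sn$channel_id, sum)
  expect_true(max(sums) - min(sums) < 1e-9)
  # a uniformly doubled channel is scaled straight back
  expect_equal(qn$sn$sn[qn$sn$channel_id == "127N"],
               qn$sn$sn[qn$sn$channel_id == "126"])
  # already-equal columns unchanged
  m2 <- rbind(p1 = c(10, 10, 10), p2 = c(30, 30, 30))
  qt2 <- make_qt(m2, c("DMSO", "DMSO", "KO"))
  expect_equal(normalize_total(qt2)$sn$sn, qt2$sn$sn)
  # idempotent and ratio-preserving
  qnn <- normalize_total(qn)
  expect_equal(qnn$sn$sn, qn$sn$sn, tolerance = 1e-12)
  r <- function(x) x$sn$sn[x$sn$peptide_id == "p2"] /
    x$sn$sn[x$sn$peptide_id == "p1"]
  expect_equal(r(qn), r(qt), tolerance = 1e-12)
})

test_that("knockout background subtraction clamps at zero", {
  m <- rbind(p1 = c(10, 3, 4, 4), p2 = c(5, 5, 0, 0))
  qt <- make_qt(m, c("DMSO", "DMSO", "KO", "KO"))
  qs <- background_subtract(qt)
  p1 <- qs$sn[qs$sn$peptide_id == "p1", ]
  expect_equal(unique(p1$background), 4)
  expect_equal(p1$sn_adj[p1$condition == "DMSO"], c(6, 0))  # 3 - 4 clamps
  p2 <- qs$sn[qs$sn$peptide_id == "p2", ]
  expect_equal(p2$sn_adj[p2$condition == "DMSO"], c(5, 5))  # KO = 0: identity
  qt_noko <- make_qt(m[, 1:2, drop = FALSE], c("DMSO", "DMSO"))
  expect_error(background_subtract(qt_noko), "background")
})

test_that("condition tests match the reference t-test", {
  m <- rbind(p1 = c(5, 6, 7, 5.5, 6.5, 7.5),
             p2 = c(1, 1.1, 0.9, 3, 3.2, 2.8))
  qt <- make_qt(m, c(rep("DMSO", 3), rep("BSI", 3)))
  out <- condition_test(qt, "DMSO", "BSI")
  for (pid in c("p1", "p2")) {
    x <- m[pid, 1:3]; y <- m[pid, 4:6]
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(out$t[out$peptide_id == pid], unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(out$p[out$peptide_id == pid], ref$p.value, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  mi <- rbind(p1 = c(2, 3, 4, 2, 3, 4))
  qi <- make_qt(mi, c(rep("DMSO", 3), rep("BSI", 3)))
  oi <- condition_test(qi, "DMSO", "BSI")
  expect_equal(oi$t, 0); expect_equal(oi$p, 1)
  # swapping groups negates t, keeps p
  sw <- condition_test(qt, "BSI", "DMSO")
  expect_equal(sw$t, -out$t, tolerance = 1e-12)
  expect_equal(sw$p, out$p, tolerance = 1e-12)
  # fewer than two replicates per side is an error
  q1 <- make_qt(rbind(p1 = c(1, 2, 3)), c("DMSO", "DMSO", "BSI"))
  expect_error(condition_test(q1, "DMSO", "BSI"), "2 replicates")
  expect_equal(p_stars(c(0.2, 0.04, 0.009, 1e-4)),
               c("n.s.", "*", "**", "***"))
})

test_that("SIM absolute quantification follows the spike-ratio rule", {
  m <- tibble::tibble(peptide_id = c("a", "b", "c"),
                      target_area = c(1e6, 2e6, 5e5),
                      trigger_area = c(1e6, 1e6, 1e6),
                      trigger_amol = c(100, 100, 0))
  out <- sim_absolute(m)
  expect_equal(out$total_amol, c(100, 200, 0))
  m$trigger_area[1] <- 0
  expect_error(sim_absolute(m), "zero")
})

test_that("per-channel apportionment conserves the SIM total", {
  m11 <- matrix(10, 1, 11, dimnames = list("p1", NULL))
  qt <- make_qt(m11, c(rep("DMSO", 3), rep("BSI", 3), rep("GSI", 3),
                       rep("KO", 2)))
  sim_abs <- tibble::tibble(peptide_id = "p1", total_amol = 110)
  out <- per_channel_absolute(sim_abs, qt)
  expect_equal(out$amol, rep(10, 11))
  # single nonzero channel receives everything
  m2 <- matrix(c(7, 0, 0), 1, 3, dimnames = list("p1", NULL))
  qt2 <- make_qt(m2, c("DMSO", "DMSO", "KO"))
  out2 <- per_channel_absolute(tibble::tibble(peptide_id = "p1",
                                              total_amol = 55), qt2)
  expect_equal(out2$amol, c(55, 0, 0))
  expect_equal(sum(out2$amol), 55, tolerance = 1e-12)
})

test_that("SIM peak areas integrate the co-eluting trigger/target traces", {
  d <- build_design(demo_substrate(), sites = demo_sites()[6, ],
                    base_amount_amol = 300)
  ch <- channel_design(c("DMSO", "DMSO", "KO"))
  run <- simulate_run(d, ch, engine_mode = "sim", seed = 2)
  ar <- sim_peak_areas(run)
  tot <- sum(run$truth$abundance$amol)
  expect_equal(sim_absolute(ar)$total_amol, tot, tolerance = 1e-9)
})
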