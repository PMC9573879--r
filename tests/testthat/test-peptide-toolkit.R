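ABETA42 <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
ABETA43 <- paste0(ABETA42, "T")

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_equal(digest(protein_sequence("p", "AKRG"))$sequence,
               c("AK", "R", "G"))
  expect_equal(digest(protein_sequence("p", "AKPR"))$sequence, "AKPR")
  expect_equal(digest(protein_sequence("p", "AKRG"), "lysc")$sequence,
               c("AK", "RG"))
  expect_error(protein_sequence("p", ""), "empty")
})

test_that("digesting the amyloid-beta region yields the known C-terminal product", {
  peps <- digest(protein_sequence("abeta42", ABETA42))
  expect_true("GAIIGLMVGGVVIA" %in% peps$sequence)
  expect_equal(peps$sequence[which.max(peps$start)], "GAIIGLMVGGVVIA")
})

test_that("missed cleavages add concatenated neighbours", {
  peps <- digest(protein_sequence("p", "AKRG"), missed_cleavages = 1)
  expect_setequal(peps$sequence, c("AK", "AKR", "R", "RG", "G"))
  expect_true(all(peps$missed <= 1))
})

test_that("zero-missed-cleavage digestion partitions random sequences", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      s <- random_peptide(sample(10:60, 1))
      for (prot in c("trypsin", "lysc")) {
        peps <- digest(protein_sequence("r", s), prot)
        expect_identical(paste(peps$sequence, collapse = ""), s)
        expect_identical(peps$start[1], 1L)
        expect_identical(peps$end[nrow(peps)], nchar(s))
      }
    }
  })
})

test_that("half-tryptic products concatenate to their parent", {
  p <- demo_substrate()   # carries the A-beta region in its tryptic context
  # gamma cleavage one residue past the A-beta-42 end gives the 43-form
  out43 <- half_tryptic_products(p, 59)
  expect_equal(out43$sequence[out43$role == "n_half"], "GAIIGLMVGGVVIAT")
  out42 <- half_tryptic_products(p, 58)
  expect_equal(out42$sequence[out42$role == "n_half"], "GAIIGLMVGGVVIA")
  expect_identical(paste(out42$sequence[2:3], collapse = ""),
                   out42$sequence[1])

  toy <- half_tryptic_products(protein_sequence("toy", "AACDK"), 2)
  expect_equal(toy$sequence, c("AACDK", "AA", "CDK"))
  expect_equal(toy$termini,
               c("full_tryptic", "half_tryptic_c", "half_tryptic_n"))

  # a site on a tryptic boundary generates no half-tryptic species
  expect_error(half_tryptic_products(protein_sequence("p", "AKRG"), 2),
               "boundary")
})

test_that("half masses are additive: parent = n + c - water", {
  withr::with_seed(21, {
    for (i in 1:50) {
      s <- random_peptide(sample(8:20, 1))
      prot <- protein_sequence("r", s)
      peps <- digest(prot)
      long <- peps[nchar(peps$sequence) >= 3, ]
      if (nrow(long) == 0) next
      parent <- long[1, ]
      cut <- parent$start + 1L
      halves <- half_tryptic_products(prot, cut)
      expect_identical(paste(halves$sequence[2:3], collapse = ""),
                       halves$sequence[1])
      m <- peptide_mass(halves$sequence, cys_cam = FALSE)
      expect_equal(m[1], m[2] + m[3] - 18.010565, tolerance = 1e-9)
    }
  })
})

test_that("peptide masses match independent residue-table arithmetic", {
  expect_equal(peptide_mass("GR"), 231.1332, tolerance = 2e-4)
  withr::with_seed(5, {
    for (i in 1:30) {
      s <- random_peptide(sample(5:15, 1))
      expect_equal(peptide_mass(s, cys_cam = FALSE), oracle_peptide_mass(s),
                   tolerance = 1e-9)
    }
  })
  expect_error(peptide_mass(character(0)), "non-empty")
  expect_error(peptide_mass("GZ"), "unknown residue")
})

test_that("isobaric labelling adds one label mass per site", {
  d <- peptide_mass("K", label = "tmt") - peptide_mass("K")
  expect_equal(d, 2 * 229.162, tolerance = 1e-9)   # N-terminus + lysine
  d1 <- peptide_mass("GR", label = "tmtpro",
                     mods = mod_table(tmtsh_mass = 235)) - peptide_mass("GR")
  expect_equal(d1, 304.207, tolerance = 1e-9)
  expect_error(peptide_mass("GR", label = "tmtsh"), "not configured")
})

test_that("fragment ions enumerate b/y per charge with label flags", {
  f <- fragment_ions("GGR", charges = 1)
  expect_equal(nrow(f), 4)           # b1, b2, y1, y2
  expect_setequal(paste0(f$series, f$index), c("b1", "b2", "y1", "y2"))
  b2 <- f$mz[f$series == "b" & f$index == 2]
  expect_equal(b2, peptide_mass("GG") - 18.010565 + 1.007276,
               tolerance = 1e-9)

  mods <- mod_table(tmtsh_mass = 235)
  fl <- fragment_ions("GGR", charges = 1, label = "tmt", mods = mods)
  expect_true(all(fl$carries_label[fl$series == "b"]))   # N-terminal label
  expect_false(any(fl$carries_label[fl$series == "y"]))  # no lysine
  fk <- fragment_ions("GKR", charges = 1, label = "tmt", mods = mods)
  expect_false(fk$carries_label[fk$series == "y" & fk$index == 1])
  expect_true(fk$carries_label[fk$series == "y" & fk$index == 2])

  expect_equal(nrow(fragment_ions("GGR", charges = c(1, 2))), 8)
  expect_error(fragment_ions("GGR", charges = 0), "positive")
})

test_that("fragments match a brute-force calculator and are complementary", {
  withr::with_seed(31, {
    for (i in 1:25) {
      s <- random_peptide(sample(4:12, 1))
      got <- fragment_ions(s, charges = 1)
      want <- oracle_fragments(s)
      got <- got[order(got$series, got$index), ]
      want <- want[order(want$series, want$index), ]
      expect_equal(got$mz, want$mz, tolerance = 1e-9)
      # series complementarity: b_i + y_(L-i) = neutral mass + 2 protons
      L <- nchar(s)
      M <- oracle_peptide_mass(s) +
        57.021 * lengths(regmatches(s, gregexpr("C", s)))
      for (j in seq_len(L - 1)) {
        b <- got$mz[got$series == "b" & got$index == j]
        y <- got$mz[got$series == "y" & got$index == L - j]
        expect_equal(b + y, M + 2 * 1.007276, tolerance = 1e-9)
      }
    }
  })
})

test_that("trigger/target mass offset bookkeeping round-trips", {
  mods <- mod_table(tmtsh_mass = 235.5)
  expect_equal(trigger_target_offset(n_sites = 0, mods = mods), 0)
  delta <- 235.5 - 229.162
  expect_equal(trigger_target_offset("AKR", mods = mods), 2 * delta,
               tolerance = 1e-9)
  # round trip through precursor m/z at charge 2
  z <- 2
  tgt <- precursor_mz(peptide_mass("AKR", "tmt", mods), z)
  trg <- precursor_mz(peptide_mass("AKR", "tmtsh", mods), z)
  off <- trigger_target_offset("AKR", mods = mods)
  expect_equal(tgt + off / z, trg, tolerance = 1e-6)
  expect_error(trigger_target_offset("AKR"), "not configured")
})
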