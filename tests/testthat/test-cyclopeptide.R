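test_that("residue alphabet is consistent with formula masses", {
  alpha <- default_alphabet()
  expect_identical(nrow(alpha), 21L)
  for (i in seq_len(nrow(alpha))) {
    expect_equal(alpha$mass[i], monoisotopic_mass(alpha$formula[i]),
                 tolerance = 1e-12)
  }
  expect_equal(alpha$mass[alpha$name == "NMePhe"], 161.08406,
               tolerance = 5e-6)
  expect_equal(alpha$mass[alpha$name == "Pro"], 97.05276, tolerance = 5e-6)
  # NMePhe composition = Phe + CH2
  expect_equal(alpha$mass[alpha$name == "NMePhe"] -
                 alpha$mass[alpha$name == "Phe"],
               monoisotopic_mass("CH2"), tolerance = 1e-9)
  # Leu/Ile isobaric, Gly smallest
  expect_equal(alpha$mass[alpha$name == "Leu"],
               alpha$mass[alpha$name == "Ile"], tolerance = 0)
  expect_identical(unique(alpha$iso_class[alpha$name %in% c("Leu", "Ile")]),
                   "Xle")
  expect_true(all(alpha$mass[alpha$name != "Gly"] >
                    alpha$mass[alpha$name == "Gly"]))
})

test_that("precursor m/z and neutral formula reproduce the pentapeptides", {
  expect_equal(round_half_up(precursor_mz(ellisiiamide_a()), 4), 556.3493)
  expect_equal(round_half_up(precursor_mz(ellisiiamide_b()), 4), 570.3650)
  expect_equal(round_half_up(precursor_mz(ellisiiamide_c()), 4), 598.3963)
  expect_equal(round_half_up(precursor_mz(cyclic_peptide(c("Gly", "Gly"))), 4),
               115.0502)
  expect_equal(format(peptide_formula(ellisiiamide_a())), "C30H45N5O5")
  expect_equal(format(peptide_formula(ellisiiamide_c())), "C33H51N5O5")
  expect_equal(format(peptide_formula(cyclic_peptide(c("Gly", "Gly")))),
               "C4H6N2O2")
  # consistency with the formula route
  for (p in list(ellisiiamide_a(), ellisiiamide_b(), ellisiiamide_c())) {
    expect_equal(precursor_mz(p), ion_mz(peptide_formula(p), "[M+H]+"),
                 tolerance = 1e-6)
  }
})

test_that("ring openings enumerate all rotations with labelled sites", {
  p3 <- cyclic_peptide(c("Ala", "Gly", "Pro"))
  op <- ring_openings(p3)
  expect_length(op, 3L)
  expect_identical(lapply(op, `[[`, "residues"),
                   list(c("Ala", "Gly", "Pro"), c("Gly", "Pro", "Ala"),
                        c("Pro", "Ala", "Gly")))
  expect_identical(op[[1]]$site, "Pro->Ala")
  expect_length(ring_openings(ellisiiamide_a()), 5L)
  # opening the Pro->NMePhe bond linearizes in input order
  op_a <- ring_openings(ellisiiamide_a())
  expect_identical(op_a[[1]]$site, "Pro->NMePhe")
  expect_identical(op_a[[1]]$residues,
                   c("NMePhe", "Ala", "Ile", "Leu", "Pro"))
})

test_that("b-ion series is the proton-capped prefix sum and telescopes", {
  b <- b_series(c("NMePhe", "Ala", "Ile", "Leu", "Pro"))
  expect_equal(round_half_up(b, 1), c(b1 = 162.1, b2 = 233.1, b3 = 346.2,
                                      b4 = 459.3, b5 = 556.3))
  expect_true(all(diff(b) > 0))
  expect_equal(unname(b[5]), precursor_mz(ellisiiamide_a()),
               tolerance = 1e-12)
  expect_equal(unname(b_series("Gly")), 58.0287, tolerance = 5e-5)
  # telescoping: b_k plus the remaining residue masses equals b_n
  alpha <- default_alphabet()
  set.seed(5)
  for (i in 1:10) {
    nm <- sample(alpha$name, 5, replace = TRUE)
    b <- b_series(nm)
    ms <- residues(nm)$mass
    for (k in 1:4) {
      expect_equal(unname(b[k]) + sum(ms[(k + 1):5]), unname(b[5]),
                   tolerance = 1e-9)
    }
  }
})

test_that("cyclospectrum has n(n-1)+1 ions and is rotation invariant", {
  pA <- ellisiiamide_a()
  cs <- cyclospectrum(pA)
  expect_length(cs, 21L)
  expect_equal(max(cs), precursor_mz(pA), tolerance = 1e-12)
  expect_equal(round_half_up(cyclospectrum(cyclic_peptide(rep("Gly", 3)),
                                           dedup = TRUE), 4),
               c(58.0287, 115.0502, 172.0717))
  alpha <- default_alphabet()
  set.seed(9)
  for (i in 1:10) {
    nm <- sample(alpha$name, sample(3:6, 1), replace = TRUE)
    p <- cyclic_peptide(nm)
    rot <- cyclic_peptide(c(nm[-1], nm[1]))
    expect_equal(cyclospectrum(p, dedup = TRUE),
                 cyclospectrum(rot, dedup = TRUE), tolerance = 1e-9)
    expect_equal(precursor_mz(p), precursor_mz(rot), tolerance = 1e-9)
    expect_identical(format(peptide_formula(p)), format(peptide_formula(rot)))
  }
})

test_that("rotation keys identify rotation classes and merge reflections", {
  nm <- c("NMePhe", "Ala", "Ile", "Leu", "Pro")
  k1 <- rotation_key(nm)
  for (i in 2:5) {
    expect_identical(rotation_key(c(nm[i:5], nm[seq_len(i - 1)])), k1)
  }
  expect_identical(rotation_key(nm, collapse_xle = TRUE),
                   "Ala-Xle-Xle-Pro-NMePhe")
  # the reversed ring shares the merged key but not the plain key
  expect_false(rotation_key(rev(nm)) == k1)
  expect_identical(rotation_key(rev(nm), merge_reflections = TRUE),
                   rotation_key(nm, merge_reflections = TRUE))
})

test_that("spectrum annotation finds the diagnostic ladder of the right
           opening and degrades gracefully", {
  pA <- ellisiiamide_a()
  # self-annotation at tight tolerance: full coverage for every opening
  self <- annotate_spectrum(pA, msms_spectrum(precursor_mz(pA),
                                              cyclospectrum(pA, dedup = TRUE)),
                            tol = 0.02)
  expect_true(all(self$coverage$coverage == 1))
  # printed diagnostic ladder picks out the Pro->NMePhe opening
  obs <- msms_spectrum(556.35, c(459.30, 346.21, 233.13, 162.09))
  ann <- annotate_spectrum(pA, obs, tol = 0.05)
  expect_identical(ann$coverage$site[1], "Pro->NMePhe")
  expect_identical(ann$coverage$coverage[1], 1)
  # sequential-loss labels on that opening
  lad <- ann$annotations[ann$annotations$site == "Pro->NMePhe" &
                           ann$annotations$matched, ]
  expect_identical(lad$lost_residue[match(c("b1", "b2", "b3", "b4"), lad$ion)],
                   c("Ala", "Ile", "Leu", "Pro"))
  # off-ladder peak matches nothing; empty spectrum gives zero coverage
  none <- annotate_spectrum(pA, msms_spectrum(556.35, 500.0), tol = 0.05)
  expect_false(any(none$annotations$matched))
  empty <- annotate_spectrum(pA, msms_spectrum(556.35, numeric(0)), tol = 0.05)
  expect_true(all(empty$coverage$coverage == 0))
})

test_that("MGF and two-column peak lists round-trip", {
  pA <- ellisiiamide_a()
  s <- simulate_msms(pA, mz_noise_sd = 0.005, n_contaminants = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(s, path, titles = "synthetic pentapeptide spectrum")
  back <- read_mgf(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$precursor_mz, s$precursor_mz, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$mz, s$peaks$mz, tolerance = 1e-5)
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fragment list", "162.0913 100", "233.1285 40"), txt)
  s2 <- read_peaks(txt, precursor_mz = 556.3493)
  expect_identical(nrow(s2$peaks), 2L)
  expect_equal(s2$peaks$intensity, c(100, 40))
})
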