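test_that("formula parsing handles counts, repeats and Hill rendering", {
  f <- parse_formula("C17H18ClO6")
  expect_equal(unclass(f)[c("C", "H", "Cl", "O")],
               c(C = 17L, H = 18L, Cl = 1L, O = 6L))
  expect_equal(format(f), "C17H18ClO6")
  expect_equal(unclass(parse_formula("H2O")), c(H = 2L, O = 1L))
  # repeated symbols accumulate; rendering canonicalizes
  expect_equal(format(parse_formula("CH3CH3")), "C2H6")
  # Hill order puts C, H first, then alphabetical symbols
  expect_equal(format(parse_formula("C11H18O4Na")), "C11H18NaO4")
  # canonical rendering is a fixed point of parse/format
  for (txt in c("C30H45N5O5", "C11H18O4Na", "C3H5NOS", "O2S")) {
    canon <- format(parse_formula(txt))
    expect_equal(format(parse_formula(canon)), canon)
  }
})

test_that("formula parsing rejects unknown symbols and zero counts", {
  expect_error(parse_formula("C17Xq3"), "Xq")
  expect_error(parse_formula("C0H4"), "zero count")
  expect_error(parse_formula("c6h6"), "parse error")
})

test_that("monoisotopic mass is correct and additive", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C30H45N5O5"), 555.34205, tolerance = 1e-5)
  expect_identical(monoisotopic_mass(new_mol_formula(integer(0))), 0)
  set.seed(11)
  syms <- names(element_masses())
  for (i in 1:25) {
    f1 <- new_mol_formula(setNames(sample(1:30, 3), sample(syms, 3)))
    f2 <- new_mol_formula(setNames(sample(1:30, 3), sample(syms, 3)))
    expect_equal(monoisotopic_mass(formula_add(f1, f2)),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 tolerance = 1e-9)
  }
})

test_that("adduct m/z matches printed values and the electron route", {
  expect_equal(round_half_up(ion_mz("C30H45N5O5", "[M+H]+"), 4), 556.3493)
  expect_equal(round_half_up(ion_mz("C11H18O4", "[M+Na]+"), 4), 237.1097)
  expect_equal(ion_mz(new_mol_formula(integer(0)), "[M+H]+"), 1.007276)
  expect_error(ion_mz("H2O", "[M+K]+"))
  # neutral + adduct must agree with ion-formula minus electron
  lib <- compound_library()
  for (i in seq_len(nrow(lib))) {
    via_adduct <- ion_mz(lib$neutral_formula[i], lib$adduct[i])
    via_electron <- monoisotopic_mass(lib$ion_formula[i]) - ELECTRON_MASS
    expect_equal(via_adduct, via_electron, tolerance = 1e-6)
  }
})

test_that("ring-plus-double-bond equivalents follow the formula", {
  expect_identical(rdbe("C30H45N5O5"), 11)
  expect_identical(rdbe("C6H6"), 4)
  expect_identical(rdbe("C17H17ClO6"), 9)  # neutral griseofulvin
  expect_identical(rdbe("CH4"), 0)
  # ion (even-electron) formulas give half-integers
  expect_identical(rdbe("C17H18ClO6"), 8.5)
})

test_that("ppm error sign convention and antisymmetry hold", {
  expect_equal(round_half_up(ppm_error(353.0793, 353.0786), 2), -1.98)
  expect_equal(round_half_up(ppm_error(319.1173, 319.1176), 2), 0.94)
  expect_identical(ppm_error(500, 500), 0)
  expect_error(ppm_error(-1, 500), "positive")
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, 100, 1000); b <- a + rnorm(1, 0, 0.01)
    expect_equal(ppm_error(a, b), -ppm_error(b, a) * (b / a),
                 tolerance = 1e-9)
  }
})

test_that("bundled library recomputes all printed masses except the one
           internally inconsistent row", {
  lib <- compound_library()
  expect_identical(nrow(lib), 19L)
  dev <- abs(lib$recomputed_mz - lib$calc_mz)
  # epoxycytochalasin D prints a calculated mass 1.8 mDa away from its own
  # printed ion formula; every other row agrees to the printed precision
  inconsistent <- lib$name == "Epoxycytochalasin D"
  expect_true(all(dev[!inconsistent] <= 5e-4))
  expect_true(dev[inconsistent] > 5e-4 && dev[inconsistent] < 2e-3)
  # adducts: exactly one sodiated entry
  expect_identical(sum(lib$adduct == "[M+Na]+"), 1L)
  expect_identical(lib$name[lib$adduct == "[M+Na]+"], "Piliformic acid")
})

test_that("dereplication matches by ppm and RT windows with stable ordering", {
  hits <- dereplicate(550.3973, 15.97, tol_ppm = 5, tol_rt = 0.5)
  expect_identical(hits$name, "Xylarotide A")
  expect_lt(abs(hits$ppm), 5)
  # tighter ppm window excludes the printed |ppm| of 1.8
  expect_identical(nrow(dereplicate(550.3973, 15.97, tol_ppm = 0.5,
                                    tol_rt = 0.5)), 0L)
  # below all library masses
  expect_identical(nrow(dereplicate(100, 1, tol_ppm = 5, tol_rt = 0.5)), 0L)
  # wide windows return several hits sorted by |ppm|
  wide <- dereplicate(556.35, 15, tol_ppm = 30000, tol_rt = 31)
  expect_gt(nrow(wide), 1)
  expect_true(!is.unsorted(abs(wide$ppm)))
})
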