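test_that("Hill-notation parsing recovers counts and charge", {
  f <- parse_formula("C27H49N6O3+")
  expect_identical(f$counts, c(C = 27L, H = 49L, N = 6L, O = 3L))
  expect_identical(f$charge, 1L)

  expect_identical(parse_formula("H2O")$counts, c(H = 2L, O = 1L))
  expect_identical(parse_formula("H2O")$charge, 0L)

  # zero-count normalization
  expect_identical(parse_formula("C0H2O")$counts, c(H = 2L, O = 1L))

  expect_identical(parse_formula("[C27H50N6O3]2+")$charge, 2L)
  expect_identical(parse_formula("[C27H50N6O3]2+")$counts[["H"]], 50L)
  expect_error(parse_formula("[C2H6O]x"), "malformed")
  expect_identical(parse_formula("")$counts, setNames(integer(), character()))

  expect_error(parse_formula("C2Xy3"), "unknown element")
  expect_error(parse_formula("C2h3"), "position")
})

test_that("formula serialization is Hill-ordered and round-trips", {
  expect_identical(format_formula(parse_formula("O3N6C27H49+")), "C27H49N6O3+")
  expect_identical(format_formula(parse_formula("C29H50F3N6O5+")),
                   "C29H50F3N6O5+")
  for (s in c("C23H40N6O", "H2O", "[C27H50N6O3]2+", "CH4N3"))
    expect_identical(format_formula(parse_formula(s)), s)
})

test_that("formula combination adds, subtracts, and guards underflow", {
  a <- parse_formula("C27H49N6O3")
  b <- parse_formula("C24H40N5O3")
  expect_identical(format_formula(formula_combine(a, b, -1L)), "C3H9N")
  # identity with the empty formula
  expect_true(formula_combine(a, chem_formula(), 1L) == a)
  expect_error(formula_combine(parse_formula("C2H7N"),
                               parse_formula("C3H9N"), -1L),
               "underflow.*C")
})

test_that("monoisotopic masses match the per-atom summation oracle", {
  expect_equal(monoisotopic_mass(parse_formula("C2H7N")), 45.05785,
               tolerance = 1e-5)
  expect_equal(monoisotopic_mass(parse_formula("C3H7N")), 57.05785,
               tolerance = 1e-5)
  expect_identical(monoisotopic_mass(chem_formula()), 0.0)
  # random formulas against the independent oracle, to 1e-9 Da
  set.seed(11)
  for (i in 1:50) {
    counts <- c(C = sample(0:40, 1), H = sample(0:80, 1), N = sample(0:10, 1),
                O = sample(0:10, 1), S = sample(0:2, 1))
    counts <- counts[counts > 0]
    f <- chem_formula(counts)
    expect_equal(monoisotopic_mass(f), oracle_mass(counts), tolerance = 1e-9)
  }
})

test_that("mass additivity holds to 1e-9 Da", {
  set.seed(12)
  for (i in 1:50) {
    a <- chem_formula(c(C = sample(1:30, 1), H = sample(1:60, 1),
                        N = sample(0:8, 1), O = sample(0:6, 1)))
    b <- chem_formula(c(C = sample(1:10, 1), H = sample(1:20, 1),
                        F = sample(0:3, 1)))
    expect_equal(monoisotopic_mass(formula_combine(a, b, 1L)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-9)
  }
})

test_that("ion m/z applies proton addition and electron-mass correction", {
  # intrinsic cation, no added proton
  expect_equal(ion_mz(parse_formula("C27H49N6O3"), 0L, 1L), 505.38607,
               tolerance = 1e-5)
  # protonated neutral
  expect_equal(ion_mz(parse_formula("C23H40N6O"), 1L, 1L), 417.33364,
               tolerance = 1e-5)
  # doubly charged: cation plus one proton
  expect_equal(ion_mz(parse_formula("C27H49N6O3"), 1L, 2L), 253.19667,
               tolerance = 1e-5)
  expect_error(ion_mz(parse_formula("H2O"), 0L, 0L), "charge")
})

test_that("doubly protonated m/z relates algebraically to the singly charged case", {
  k <- mass_constants()
  set.seed(13)
  for (i in 1:20) {
    f <- chem_formula(c(C = sample(10:30, 1), H = sample(20:60, 1),
                        N = sample(1:8, 1), O = sample(0:5, 1)))
    m <- monoisotopic_mass(f)
    expect_equal(ion_mz(f, 2L, 2L),
                 (m + 2 * (k$atomic[["H"]] - k$electron)) / 2,
                 tolerance = 1e-10)
    expect_equal(2 * ion_mz(f, 2L, 2L) - ion_mz(f, 1L, 1L),
                 k$atomic[["H"]] - k$electron, tolerance = 1e-9)
  }
})

test_that("ppm error uses the theoretical value as reference with exact sign", {
  expect_equal(round(ppm_error(146.06041, 146.06004), 2), 2.53)
  expect_equal(ppm_error(100, 100), 0)
  expect_equal(round(ppm_error(45.05836, 45.05785), 2), 11.32)
  # sign convention: measured above theoretical is positive
  expect_gt(ppm_error(100.001, 100), 0)
  expect_lt(ppm_error(99.999, 100), 0)
  # antisymmetry only holds to first order
  expect_false(isTRUE(all.equal(ppm_error(100.1, 100),
                                -ppm_error(100, 100.1), tolerance = 1e-12)))
  expect_equal(ppm_error(100.1, 100), -ppm_error(100, 100.1),
               tolerance = 1e-2)
  expect_error(ppm_error(100, 0), "theoretical")
})
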