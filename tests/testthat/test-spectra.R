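make_mgf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".mgf", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("MGF blocks parse with metadata and sorted peaks", {
  path <- make_mgf(c(
    "BEGIN IONS",
    "TITLE=demo",
    "PEPMASS=417.33334 12345.0",
    "CHARGE=1+",
    "RTINSECONDS=533.4",
    "229.13354 500",
    "130.06513 1000",
    "343.24924 200",
    "END IONS"))
  sps <- read_peaklist(path)
  expect_length(sps, 1L)
  sp <- sps[[1L]]
  expect_identical(nrow(sp$peaks), 3L)
  expect_identical(sp$peaks$mz, sort(sp$peaks$mz))
  expect_equal(sp$precursor_mz, 417.33334)
  expect_identical(sp$precursor_charge, 1L)
  expect_equal(sp$rt_min, 8.89)
  expect_identical(sp$title, "demo")
})

test_that("TSV peak lists parse with and without a header", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity", "146.06041\t1200"), path)
  sp <- read_peaklist(path)[[1L]]
  expect_identical(nrow(sp$peaks), 1L)
  expect_equal(sp$peaks$mz, 146.06041)

  writeLines("146.06041\t1200", path)
  expect_equal(read_peaklist(path)[[1L]]$peaks$intensity, 1200)
})

test_that("malformed peak lists raise errors naming the line", {
  p1 <- make_mgf(c("BEGIN IONS", "PEPMASS=100", "110.1 5"))
  expect_error(read_peaklist(p1), "line 1.*END IONS|no matching END IONS")
  p2 <- make_mgf(c("BEGIN IONS", "110.1 bogus extra", "END IONS"))
  expect_error(read_peaklist(p2), "line 2")
  p3 <- withr::local_tempfile(fileext = ".mgf")
  file.create(p3)
  expect_identical(read_peaklist(p3), list())
  expect_error(read_peaklist("/nonexistent/x.mgf"), "no such file")
})

test_that("MGF write/read round-trips peaks to 1e-5 m/z", {
  sp <- synth_spectrum("IndAc4333")
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  sp2 <- read_peaklist(path)[[1L]]
  expect_identical(nrow(sp2$peaks), nrow(sp$peaks))
  expect_true(max(abs(sp2$peaks$mz - sp$peaks$mz)) <= 1e-5)
  expect_identical(sp2$precursor_charge, 1L)
})

test_that("annotation links each peak to its best prediction within tolerance", {
  s <- parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+")
  pred <- fragment_ions(s)
  # the five printed fragment peaks of the reference measurement
  sp <- new_spectrum(c(146.06041, 231.11341, 304.16639, 361.22422, 446.31402),
                     c(900, 800, 700, 600, 500))
  ann <- annotate_spectrum(sp, pred, tol_ppm = 5)
  expect_identical(nrow(ann$annotations), 5L)
  expect_identical(ann$annotations$ion_type, c("a'", "a", "a", "a", "a"))
  expect_equal(round(ann$annotations$ppm, 2), c(2.53, 2.62, 2.70, 2.22, 3.26))
  # intensity invariance
  sp10 <- new_spectrum(sp$peaks$mz, sp$peaks$intensity * 10)
  ann10 <- annotate_spectrum(sp10, pred, tol_ppm = 5)
  expect_identical(ann$annotations[, c("peak", "ion_type", "index", "ppm")],
                   ann10$annotations[, c("peak", "ion_type", "index", "ppm")])
})

test_that("annotation of an empty spectrum leaves all predictions unmatched", {
  pred <- fragment_ions(parse_generic_name("IndAc4333"))
  ann <- annotate_spectrum(new_spectrum(numeric(), numeric()), pred)
  expect_identical(nrow(ann$annotations), 0L)
  expect_identical(nrow(ann$unmatched_predicted), nrow(pred))
})

test_that("similarity is bounded, symmetric, and separates jitter from mismatch", {
  sp <- synth_spectrum("IndAc4333")
  expect_equal(spectrum_similarity(sp, sp)$score, 1.0)
  expect_equal(spectrum_similarity(sp, sp)$matched_fraction, 1.0)

  # disjoint m/z sets
  a <- new_spectrum(c(100, 200), c(1, 1))
  b <- new_spectrum(c(300, 400), c(1, 1))
  expect_identical(spectrum_similarity(a, b)$score, 0.0)

  # seeded 2-ppm jitter barely perturbs the score
  spj <- synth_spectrum("IndAc4333", jitter_ppm = 2, seed = 101)
  sim <- spectrum_similarity(spj, sp, tol_ppm = 5)
  expect_gte(sim$score, 0.99)

  # symmetry
  s1 <- spectrum_similarity(spj, sp)
  s2 <- spectrum_similarity(sp, spj)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)

  expect_error(spectrum_similarity(a, new_spectrum(numeric(), numeric())),
               "non-empty")
})
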