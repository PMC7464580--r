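reg <- build_fixture_registry()

test_that("head detection ranks heads by diagnostic-ion evidence", {
  # the two printed head-diagnostic peaks of the unknown-compound example
  sp <- new_spectrum(c(146.06014, 231.11307), c(1000, 800))
  hd <- detect_head(sp)
  expect_gt(nrow(hd), 0L)
  expect_identical(hd$head[1L], "4-OH-IndAc")
  expect_identical(hd$a1_chain[1L], 3L)  # linked to a propylamine unit

  expect_identical(nrow(detect_head(new_spectrum(c(500.1), 1))), 0L)

  # self-consistency on a generated spectrum of another head
  sp2 <- synth_spectrum("4-OH-Bz3(OH)334")
  expect_identical(detect_head(sp2)$head[1L], "4-OH-Bz")
})

test_that("a known compound with a reference spectrum is identified via Q1-Q3", {
  sp <- synth_spectrum("IndAc4333", jitter_ppm = 1, seed = 42)
  r <- identify_compound(sp, precursor_mz = 417.33334, precursor_charge = 1,
                         rt = 8.89, formula = "C23H40N6O", registry = reg)
  expect_identical(r$verdict, "identified_by_reference")
  expect_identical(r$best_candidate, "IndAc4333")
  expect_identical(r$decision_trace$question, c("Q1", "Q2", "Q3"))
  expect_match(r$decision_trace$answer[1], "4 candidate")
  expect_match(r$decision_trace$evidence[2], "IndAc3334: excluded")
})

test_that("a known cation without reference spectrum is supported via Q5-Q7", {
  sp <- synth_spectrum("4-OH-IndAc3(OH)335(NMe3)+", jitter_ppm = 2, seed = 7)
  r <- identify_compound(sp, precursor_mz = 505.38687, precursor_charge = 1,
                         rt = 8.10, hdx_shift = 6, registry = reg)
  expect_identical(r$verdict, "supported_by_prediction")
  expect_identical(r$best_candidate, "4-OH-IndAc3(OH)335(NMe3)+")
  expect_identical(r$decision_trace$question,
                   c("Q1", "Q2", "Q3", "Q4", "Q5", "Q6", "Q7"))
  # Q2 finds no comparable Rt, Q6 finds the backbone sibling without spectrum
  expect_match(r$decision_trace$evidence[2], "not comparable")
  expect_match(r$decision_trace$evidence[6], "IndAc3\\(OH\\)335\\(NMe3\\)\\+")
  expect_identical(r$hdx_check$expected, 6L)
})

test_that("an unknown is elucidated via head detection and assembly (Q8-Q10)", {
  sp <- synth_spectrum("4-OH-IndAc3(OH)335(NMe2)", jitter_ppm = 2, seed = 9)
  r <- identify_compound(sp, precursor_mz = 491.37039, precursor_charge = 1,
                         rt = 8.32, hdx_shift = 7, formula = "C26H47N6O3+",
                         registry = reg)
  expect_identical(r$verdict, "proposed_new_structure")
  expect_identical(r$best_candidate, "4-OH-IndAc3(OH)335(NMe2)")
  expect_identical(r$decision_trace$question,
                   c("Q1", "Q8", "Q9", "Q10", "Q5", "Q6", "Q7"))
  # the floor-491 registry hit is excluded by the accurate-mass guard
  expect_match(r$decision_trace$evidence[1], "excluded by accurate mass")
  expect_match(r$decision_trace$evidence[1], "Gu")
  expect_identical(r$hdx_check, list(expected = 7L, observed = 7L))
})

test_that("decision traces are total: each executed question appears once", {
  sp <- synth_spectrum("4-OH-IndAc3(OH)335(NMe2)", jitter_ppm = 2, seed = 9)
  for (args in list(
    list(precursor_mz = 417.33364, rt = 8.89),
    list(precursor_mz = 491.37042, hdx_shift = 7),
    list(precursor_mz = 1234.5))) {
    r <- do.call(identify_compound,
                 c(list(spectrum = sp, registry = reg), args))
    q <- r$decision_trace$question
    expect_identical(anyDuplicated(q), 0L)
  }
})

test_that("dead ends yield an unresolved verdict, not an error", {
  noise <- new_spectrum(c(101.1, 202.2, 303.3), c(1, 1, 1))
  r <- identify_compound(noise, precursor_mz = 999.9, registry = reg)
  expect_identical(r$verdict, "unresolved")
  expect_true(is.na(r$best_candidate))
  # implausible formula stops at Q8
  r2 <- identify_compound(noise, precursor_mz = 999.9, formula = "C40H80O2",
                          registry = reg)
  expect_identical(r2$verdict, "unresolved")
  expect_match(r2$decision_trace$answer[r2$decision_trace$question == "Q8"],
               "inconsistent")
})

test_that("mass-isomeric backbones are reported as ties without an HDX shift", {
  sp <- synth_spectrum("4-OH-IndAc3(OH)335(NMe2)",
                       ion_types = c("a", "a0", "a'"))
  r <- identify_compound(sp, precursor_mz = 491.37042, precursor_charge = 1,
                         registry = reg)
  expect_identical(r$verdict, "proposed_new_structure")
  # with only a-type evidence, N-Me vs +CH2 placements are indistinguishable
  expect_gt(length(r$ties), 0L)
})
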