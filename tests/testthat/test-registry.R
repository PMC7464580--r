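reg <- build_fixture_registry()

test_that("the fixture registry validates and round-trips through JSON", {
  expect_gte(length(reg), 11L)
  path <- withr::local_tempfile(fileext = ".json")
  write_compound_registry(reg, path)
  reg2 <- load_compound_registry(path)
  expect_identical(length(reg2), length(reg))
  n1 <- vapply(reg$records, `[[`, "", "generic_name")
  n2 <- vapply(reg2$records, `[[`, "", "generic_name")
  expect_identical(n1, n2)
  # the C-1 record keeps its reference spectrum through the round-trip
  r4 <- Filter(function(r) r$c_level == "C-1", reg2$records)
  expect_length(r4, 1L)
  expect_gt(nrow(r4[[1L]]$reference_spectrum$peaks), 0L)
  # trivial-name aliases survive
  atx <- Filter(function(r) "argiotoxin 636" %in% r$trivial_names,
                reg2$records)
  expect_length(atx, 1L)
  expect_identical(atx[[1L]]$generic_name, "2,4-(OH)2-PhAcAsn533Arg")
})

test_that("record validation enforces level vocabularies and requirements", {
  expect_error(compound_record("X", formula = "C2H6O", s_level = "S-6",
                               c_level = "C-3"), "S-6")
  expect_error(compound_record("X", formula = "C2H6O", s_level = "S-1",
                               c_level = "C-9"), "C-9")
  expect_error(compound_record("X", formula = "C2H6O", s_level = "S-1",
                               c_level = "C-1"), "reference spectrum")
  # S-5 permits a missing formula, lower levels do not
  expect_silent(compound_record("X", s_level = "S-5", c_level = "C-4"))
  expect_error(compound_record("X", s_level = "S-3", c_level = "C-4"),
               "formula is required")
  expect_error(compound_registry(list(
    compound_record("A", s_level = "S-5", c_level = "C-4"),
    compound_record("A", s_level = "S-5", c_level = "C-4"))), "duplicate")
  expect_identical(length(compound_registry(list())), 0L)
})

test_that("malformed registry files report the record index", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(generic_name = "ok", formula = "C2H6O", s_level = "S-1",
         c_level = "C-3"),
    list(generic_name = "bad", formula = "C2H6O", s_level = "S-6",
         c_level = "C-3")), path, auto_unbox = TRUE)
  expect_error(load_compound_registry(path), "record 2")
})

test_that("formula search is exact on counts and charge", {
  hits <- search_by_formula(reg, "C23H40N6O")
  expect_setequal(vapply(hits, `[[`, "", "generic_name"),
                  c("IndAc3334", "IndAc3343", "IndAc3433", "IndAc4333"))
  # the quaternary toxin is indexed under its cation formula only
  expect_length(search_by_formula(reg, "C27H48N6O3"), 0L)
  expect_length(search_by_formula(reg, "C27H49N6O3+"), 1L)
  expect_length(search_by_formula(reg, "C26H46N6O3"), 0L)
  expect_length(search_by_formula(reg, "CH"), 0L)
})

test_that("precursor search floors the stored ion masses", {
  h505 <- search_by_precursor(reg, 505)
  expect_identical(vapply(h505, `[[`, "", "generic_name"),
                   "4-OH-IndAc3(OH)335(NMe3)+")
  h491 <- search_by_precursor(reg, 491)
  expect_identical(vapply(h491, `[[`, "", "generic_name"),
                   "4-OH-IndAc3(OH)334Gu")
  expect_length(search_by_precursor(reg, 100), 0L)
  expect_error(search_by_precursor(reg, 0), "mz_floor")
})

test_that("the retention-time filter applies a 2% window of the observed value", {
  cands <- search_by_formula(reg, "C23H40N6O")
  kept <- rt_filter(cands, 8.89)
  expect_identical(attr(kept, "window"), 0.18)
  st <- attr(kept, "status")
  expect_identical(unname(st[c("IndAc3334", "IndAc3343", "IndAc3433")]),
                   rep("excluded", 3))
  expect_identical(unname(st[["IndAc4333"]]), "kept")
  expect_identical(vapply(kept, `[[`, "", "generic_name"), "IndAc4333")

  # an exact match is kept; records without Rt pass through flagged
  one <- rt_filter(cands[4], 9.00)
  expect_identical(attr(one, "status")[["IndAc4333"]], "kept")
  nme3 <- search_by_precursor(reg, 505)
  fl <- rt_filter(nme3, 8.10)
  expect_identical(unname(attr(fl, "status")), "not comparable")
  expect_length(fl, 1L)

  expect_error(rt_filter(cands, -1), "observed_rt")
})
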