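test_that("molecular formulas of the reference compounds are exact", {
  expect_identical(format_formula(molecular_formula(
    parse_generic_name("IndAc4333"))), "C23H40N6O")
  expect_identical(format_formula(molecular_formula(
    parse_generic_name("4-OH-IndAc3(OH)335(NMe2)"))), "C26H46N6O3")
  expect_identical(format_formula(molecular_formula(
    parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+"))), "C27H49N6O3+")
  expect_identical(format_formula(molecular_formula(
    parse_generic_name("4-OH-Bz3(OH)334"))), "C20H37N5O3")
})

test_that("precursor ion sets cover protonation states and TFA adducts", {
  p <- precursor_ion_set(parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+"))
  expect_identical(p$label, c("M+", "[M+H]2+", "[(M+H)+CF3CO2]+"))
  expect_equal(p$mz, c(505.38607, 253.19667, 619.37893), tolerance = 1e-5)
  expect_identical(p$formula[2], "[C27H50N6O3]2+")
  expect_identical(p$formula[3], "C29H50F3N6O5+")

  p2 <- precursor_ion_set(parse_generic_name("IndAc4333"))
  expect_identical(p2$label, c("[M+H]+", "[M+2H]2+", "[M+H+TFA]+"))
  expect_equal(p2$mz[1:2], c(417.33364, 209.17046), tolerance = 1e-5)
  expect_identical(p2$formula[1], "C23H41N6O+")
})

test_that("the a-series reproduces the validated fragment ladder", {
  s <- parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+")
  fr <- fragment_ions(s)
  a <- fr[fr$ion_type == "a", ]
  expect_equal(a$mz[order(a$index)],
               c(231.11280, 304.16557, 361.22342, 446.31257),
               tolerance = 1e-5)
  expect_equal(fr$mz[fr$ion_type == "a'"], 146.06004, tolerance = 1e-5)
  expect_equal(fr$mz[fr$ion_type == "a0"], 174.05495, tolerance = 1e-5)
  # neutral loss precursor minus a4 is the trimethylamine tail
  M <- molecular_formula(s)
  a4 <- parse_formula(a$formula[a$index == 4])
  loss <- formula_combine(chem_formula(M$counts), chem_formula(a4$counts), -1L)
  expect_identical(format_formula(loss), "C3H9N")
})

test_that("a-series increments telescope to the unit masses", {
  set.seed(21)
  for (i in 1:25) {
    s <- random_structure()
    fr <- fragment_ions(s)
    a <- fr[fr$ion_type == "a", ]
    a <- a[order(a$index), ]
    diffs <- diff(a$mz)
    expected <- vapply(seq_along(diffs) + 1L, function(k)
      monoisotopic_mass(polyfrag:::unit_atoms(s$units[[k]]$chain,
                                              s$units[[k]]$nsub)), 0.0)
    expect_equal(diffs, expected, tolerance = 1e-9)
  }
})

test_that("a/y pairs are complementary on neutral structures", {
  set.seed(22)
  for (i in 1:25) {
    s <- random_structure(tails = c("NH2", "NMe2", "Arg", "Gu"))
    n <- length(s$units)
    fr <- fragment_ions(s)
    a <- fr[fr$ion_type == "a", ]
    y <- fr[fr$ion_type == "y", ]
    p <- precursor_ion_set(s)
    mh <- p$mz[p$label == "[M+H]+"]
    for (k in seq_len(n - 1L)) {
      amz <- a$mz[a$index == k]
      ymz <- y$mz[y$index == n - k]
      expect_equal(amz + ymz, mh + 1.00728, tolerance = 1e-5)
    }
  }
})

test_that("fragment formulas equal a brute-force recount of their substructure", {
  set.seed(23)
  for (i in 1:20) {
    s <- random_structure()
    fr <- fragment_ions(s, fragment_rules(b = FALSE, c = FALSE, z = FALSE,
                                          t = FALSE))
    a <- fr[fr$ion_type == "a", ]
    for (k in a$index) {
      sub <- s
      sub$units <- s$units[seq_len(k)]
      # recount head(+linker)+units 1..k independently (drop the tail term)
      v <- oracle_structure_counts(sub)
      tailc <- oracle_counts(format_formula(s$tail$atoms))
      for (sym in names(tailc)) v[sym] <- v[[sym]] - tailc[[sym]]
      expect_identical(formula_key(parse_formula(a$formula[a$index == k])),
                       oracle_key(v))
    }
  }
})

test_that("fragment types are individually switchable", {
  s <- parse_generic_name("IndAc4333")
  fr <- fragment_ions(s, fragment_rules(b = FALSE, z = FALSE))
  expect_false(any(fr$ion_type %in% c("b", "z")))
  expect_true(all(c("a", "a0", "a'", "c", "y") %in% fr$ion_type))
  fr2 <- fragment_ions(s, fragment_rules(a = FALSE, a_head = FALSE, y = FALSE,
                                         b = FALSE, c = FALSE, z = FALSE))
  expect_identical(nrow(fr2), 0L)
})

test_that("tail diagnostic ions are emitted from the block table", {
  reg <- default_block_registry()
  register_block(reg, "tail", "NMe3x", "C3H9N", intrinsic_charge = 1L,
                 style = "bracketed",
                 diagnostic_ions = list(t1 = "C3H8N"))
  s <- parse_generic_name("IndAc333(NMe3x)+", reg)
  fr <- fragment_ions(s)
  expect_true("t_z" %in% fr$ion_type)
  expect_equal(fr$mz[fr$ion_type == "t_z"],
               ion_mz(parse_formula("C3H8N"), 0L, 1L), tolerance = 1e-9)
})

test_that("exchangeable-proton counts follow the labile-site rules", {
  expect_identical(exchangeable_protons(
    parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+")), 6L)
  expect_identical(exchangeable_protons(
    parse_generic_name("4-OH-IndAc3(OH)335(NMe2)")), 6L)
  expect_identical(exchangeable_protons(parse_generic_name("IndAc4333")), 7L)
})

test_that("observed HDX shifts add the ionizing protons", {
  nme2 <- parse_generic_name("4-OH-IndAc3(OH)335(NMe2)")
  nme3 <- parse_generic_name("4-OH-IndAc3(OH)335(NMe3)+")
  expect_identical(hdx_observed_shift(nme2, "[M+H]+"), 7L)
  expect_identical(hdx_observed_shift(nme3, "M+"), 6L)
  expect_identical(hdx_observed_shift(nme3, "[M+H]2+"), 7L)
  expect_identical(hdx_observed_shift(nme2, "[M+2H]2+"), 8L)
  expect_error(hdx_observed_shift(nme3, "[M+H]+"), "not valid")
  # a neutral protonated species always shifts one more than the same
  # atom count carried as a fixed cation
  expect_identical(hdx_observed_shift(nme2, "[M+H]+") -
                     exchangeable_protons(nme2), 1L)
})

test_that("neutral-loss tail inference enumerates and ranks amine isomers", {
  partial <- parse_generic_name("4-OH-IndAc3(OH)335")
  res <- infer_tail_from_neutral_loss("C2H7N", partial,
                                      observed_hdx_shift = 7)
  expect_setequal(res$tail, c("NMe2", "NHEt"))
  expect_identical(res$tail[res$hdx_consistent], "NMe2")
  expect_identical(res$predicted_shift[res$tail == "NHEt"], 8L)

  # on a fixed-cation compound the loss equals the tail atoms directly
  res2 <- infer_tail_from_neutral_loss("C3H9N", partial)
  expect_true("NMe3" %in% res2$tail)

  expect_error(infer_tail_from_neutral_loss("CH4", partial), "no terminal")
})
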