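test_that("formula parsing reads Hill tokens and round-trips", {
  expect_identical(unclass(parse_formula("H2O"))[c("H", "O")],
                   c(H = 2L, O = 1L))
  g <- parse_formula("C5H5N5O")
  expect_identical(unclass(g)[c("C", "H", "N", "O")],
                   c(C = 5L, H = 5L, N = 5L, O = 1L))
  expect_identical(unclass(parse_formula("C5H8O3"))[c("C", "H", "O")],
                   c(C = 5L, H = 8L, O = 3L))
  # counts default to 1; repeated symbols accumulate
  expect_true(parse_formula("CH3COOH") == parse_formula("C2H4O2"))
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("Xx5"), "unknown element")
  expect_error(parse_formula("C5h2"), "malformed")
  set.seed(11)
  for (i in 1:50) {
    f <- parse_formula(rand_formula_string())
    expect_true(parse_formula(format_formula(f)) == f)
  }
})

test_that("formula arithmetic is element-wise and guards negatives", {
  expect_true(parse_formula("C5H5N5O") + parse_formula("C5H8O3") ==
                parse_formula("C10H13N5O4"))
  expect_true(parse_formula("C10H13N5O4") - parse_formula("C5H5N5O") ==
                parse_formula("C5H8O3"))
  expect_error(parse_formula("CH4") - parse_formula("H2O"),
               "negative count")
  # round trip of add/subtract
  a <- parse_formula("C17H12O6"); b <- parse_formula("H2O")
  expect_true((a + b) - b == a)
})

test_that("monoisotopic masses and [M+H]+ m/z match the printed values", {
  expect_identical(sprintf("%.4f", monoisotopic_mass("C5H8O3")), "116.0473")
  expect_identical(sprintf("%.4f", monoisotopic_mass("H2O")), "18.0106")
  empty <- formula_subtract("H2O", "H2O")
  expect_identical(monoisotopic_mass(empty), 0)
  expect_identical(format_formula(empty), "")
  expect_identical(sprintf("%.4f", protonated_mz("C5H5N5O")), "152.0567")
  expect_identical(sprintf("%.4f", protonated_mz("C5H5N5")), "136.0618")
  expect_identical(sprintf("%.4f", protonated_mz("C10H13N5O3")), "252.1091")
})

test_that("mass computation agrees with an independent per-atom oracle", {
  set.seed(21)
  for (i in 1:20) {
    f <- parse_formula(rand_formula_string())
    expect_equal(monoisotopic_mass(f), oracle_mass(f), tolerance = 1e-6)
  }
})

test_that("protonated m/z is strictly monotone under adding any element", {
  f <- parse_formula("C10H13N5O3")
  for (el in c("C", "H", "N", "O", "S", "P", "Cl"))
    expect_gt(protonated_mz(formula_add(f, el)), protonated_mz(f))
})

test_that("biotransformation chains apply in order and are revertible", {
  steps <- biotransformations()
  expect_true(apply_chain("C12H16O3", list(steps$epoxidation)) ==
                parse_formula("C12H16O4"))
  expect_identical(
    sprintf("%.4f", protonated_mz(apply_chain("C12H16O3",
                                              list(steps$epoxidation)))),
    "225.1121")
  bap <- apply_chain("C20H12", list(steps$epoxidation, steps$hydration,
                                    steps$epoxidation))
  expect_true(bap == parse_formula("C20H14O3"))
  # the intact nucleoside adduct lands within 5 ppm of the observed feature
  expect_lt(abs(ppm_error(570.1980,
                          protonated_mz(bap + parse_formula("C10H13N5O4")))),
            5)
  expect_true(apply_chain("C20H12", list()) == parse_formula("C20H12"))
  expect_error(apply_chain("C2H6", list(steps$dehydration)),
               "negative count")
  expect_error(apply_chain("C2H6", rep(list(steps$hydration), 4)),
               "max_chain")
  f <- parse_formula("C12H16O3")
  expect_true(revert_step(apply_chain(f, list(steps$dehydration)),
                          steps$dehydration) == f)
})

test_that("hypothesis enumeration covers the subunit combinatorics", {
  h <- enumerate_hypotheses("C3H6O2", steps = list(), targets = "Gua",
                            max_chain = 0, binding_losses = "none",
                            parent_name = "glycidol")
  expect_equal(nrow(h), 1L)
  expect_identical(sprintf("%.4f", h$expected_mz), "226.0935")

  h2 <- enumerate_hypotheses("C12H16O3", targets = "dA", max_chain = 1,
                             parent_name = "AS")
  as_da <- h2[h2$chain == "epoxidation" & h2$binding_loss == "none", ]
  expect_equal(nrow(as_da), 1L)
  expect_identical(sprintf("%.4f", as_da$expected_mz), "476.2140")

  # enumeration is deduplicated by adduct formula and sorted by m/z;
  # cross-target isomers (dG adduct vs oxidized dA adduct) collapse to the
  # fewer-step variant
  h3 <- enumerate_hypotheses("C12H16O3", targets = c("dA", "dG"),
                             max_chain = 1, parent_name = "AS")
  expect_false(any(duplicated(h3$adduct_formula)))
  expect_false(is.unsorted(h3$expected_mz))
  iso <- h3[h3$adduct_formula == "C22H29N5O7", ]
  expect_identical(iso$name, "AS-dG")
  expect_equal(iso$n_steps, 0L)
  expect_error(enumerate_hypotheses("C3H6O2", targets = dna_targets()[0, ]),
               "empty target")
})

test_that("base and nucleoside variants differ by the deoxyribose mass", {
  dr <- monoisotopic_mass("C5H8O3")
  pairs <- list(c("Gua", "dG"), c("Ade", "dA"), c("Cyt", "dC"),
                c("Thy", "dT"))
  tg <- dna_targets()
  for (p in pairs) {
    base <- parse_formula(tg$formula[tg$name == p[1]])
    nucl <- parse_formula(tg$formula[tg$name == p[2]])
    expect_true(nucl - base == parse_formula("C5H8O3"))
    for (chain in list(list(), list(biotransformations()$epoxidation))) {
      hb <- adduct_hypothesis("C12H16O3", chain, p[1])
      hn <- adduct_hypothesis("C12H16O3", chain, p[2])
      expect_equal(hn$expected_mz - hb$expected_mz, dr, tolerance = 1e-10)
    }
  }
})

test_that("hypothesis tables export to CSV with the documented columns", {
  h <- enumerate_hypotheses("C3H6O2", targets = c("Gua", "dG"),
                            max_chain = 1, parent_name = "glycidol")
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypotheses(h, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("name", "parent_formula", "chain", "target",
                     "binding_loss", "adduct_formula", "expected_mz"))
  expect_equal(back$expected_mz, h$expected_mz, tolerance = 1e-6)
})
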