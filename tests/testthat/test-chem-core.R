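# Formula parsing, monoisotopic masses, adduct m/z and mass-error arithmetic.

test_that("formula parsing is canonical, order-independent and round-trips", {
  f <- parse_formula("C15H22O5")
  expect_equal(unclass(f), c(C = 15L, H = 22L, O = 5L),
               ignore_attr = "class")
  expect_equal(parse_formula("H22C15O5"), f)
  expect_equal(parse_formula("C_15_H_22_O_5_"), f)
  expect_length(parse_formula(""), 0)
  # round-trip through the writer for every fixture formula
  for (s in unique(read_metabolite_fixture()$formula)) {
    expect_equal(parse_formula(write_formula(parse_formula(s))),
                 parse_formula(s))
  }
  expect_error(parse_formula("C15X2"), "unknown element symbol 'X'")
  expect_error(parse_formula("C15h22"), "position 4")
})

test_that("monoisotopic masses match an element-by-element oracle", {
  expect_equal(formula_mass("C15H22O5"), oracle_mass(C = 15, H = 22, O = 5),
               tolerance = 1e-12)
  expect_equal(round(formula_mass("C15H22O5"), 4), 282.1467)
  expect_equal(round(formula_mass("H2O"), 4), 18.0106)
  expect_equal(formula_mass(chem_formula()), 0)
  expect_error(formula_mass(chem_formula(c(Xx = 1))), "Xx")
})

test_that("formula mass is additive over formula union", {
  set.seed(42)
  syms <- c("C", "H", "N", "O", "Na", "K")
  for (i in 1:50) {
    a <- chem_formula(stats::setNames(sample(0:20, 6, TRUE), syms))
    b <- chem_formula(stats::setNames(sample(0:20, 6, TRUE), syms))
    merged <- apply_formula_delta(a, unclass(b))
    expect_equal(formula_mass(merged), formula_mass(a) + formula_mass(b),
                 tolerance = 1e-9)
  }
})

test_that("adduct m/z reproduces the derived reference values", {
  expect_equal(round(ion_mz("C15H22O5", "M+H"), 4), 283.1540)
  expect_equal(round(ion_mz("C15H22O4", "M+Na"), 4), 289.1410)
  expect_equal(round(ion_mz("C15H24O5", "M+K"), 4), 323.1255)
  expect_error(ion_mz("C15H22O5", "M+NH4"), "unsupported adduct")
})

test_that("adduct m/z is ordered M+H < M+Na < M+K and increases with mass", {
  set.seed(1)
  for (i in 1:25) {
    f <- chem_formula(c(C = sample(1:30, 1), H = sample(1:40, 1),
                        O = sample(0:10, 1)))
    expect_lt(ion_mz(f, "M+H"), ion_mz(f, "M+Na"))
    expect_lt(ion_mz(f, "M+Na"), ion_mz(f, "M+K"))
    g <- apply_formula_delta(f, c(O = 1))
    expect_lt(ion_mz(f, "M+H"), ion_mz(g, "M+H"))
  }
})

test_that("reference-compound adduct ions lie within 2 mDa, except the known DHA [M+H]+", {
  refs <- read_reference_compounds()
  ions <- c(mz_mh = "M+H", mz_mna = "M+Na", mz_mk = "M+K")
  for (i in seq_len(nrow(refs))) {
    for (col in names(ions)) {
      err <- mass_error_mda(refs[[col]][i], ion_mz(refs$formula[i], ions[[col]]))
      if (refs$alias[i] == "DHA" && col == "mz_mh") {
        expect_gt(abs(err), 2)  # flagged typo, not reconciled
      } else {
        expect_lte(abs(err), 2)
      }
    }
  }
})

test_that("mass errors reproduce printed table cells and are antisymmetric", {
  expect_equal(round_mda(mass_error_mda(267.1586, ion_mz("C15H22O4", "M+H"))),
               -0.5)
  expect_equal(round_mda(mass_error_mda(307.1505, ion_mz("C15H24O5", "M+Na"))),
               -1.1)
  expect_equal(mass_error_mda(283.1540, 283.1540), 0)
  x <- c(283.1537, 305.1354, 321.1092)
  y <- c(283.1540, 305.1359, 321.1099)
  expect_equal(mass_error_mda(x, y), -mass_error_mda(y, x))
})

test_that("reported mDa rounding is half-away-from-zero", {
  expect_equal(round_mda(c(-0.45, 0.45, -0.44, 1.25)), c(-0.5, 0.5, -0.4, 1.3))
})

test_that("formula deltas apply element-wise and reject negative counts", {
  expect_equal(apply_formula_delta("C15H22O5", c(O = 1)),
               parse_formula("C15H22O6"))
  expect_equal(apply_formula_delta("C15H22O5", c(O = -1)),
               parse_formula("C15H22O4"))
  expect_error(apply_formula_delta("C15H22O5", c(O = -6)),
               "infeasible transformation")
})

test_that("formula + adduct notation from the summary table splits correctly", {
  p <- parse_ion_notation("C_15_H_22_O_6_ + Na^+^")
  expect_equal(write_formula(p$formula), "C15H22O6")
  expect_equal(p$ion, "M+Na")
  expect_error(parse_ion_notation("C15H22O5"), "cannot split")
})
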