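# Neutral-loss path search, the exhaustive oracle, and coverage scoring.

test_that("loss registry masses equal the masses of their formulas", {
  reg <- default_loss_registry()
  expect_setequal(reg$label, c("H2O", "HCOOH", "CH3COOH", "CO", "C2H4"))
  expect_equal(reg$mass, vapply(reg$formula, formula_mass, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(round(reg$mass[reg$label == "H2O"], 4), 18.0106)
  expect_equal(round(reg$mass[reg$label == "CH3COOH"], 4), 60.0211)
})

test_that("single and composed losses explain the reference fragments", {
  p <- ion_mz("C15H22O5", "M+H")  # protonated artemisinin, 283.1540
  expect_equal(explain_fragment(p, 265)$path, "H2O")
  expect_equal(explain_fragment(p, 247)$path, "H2O;H2O")
  expect_equal(explain_fragment(p, 205)$path, "H2O;CH3COOH")
  # hydrogenated ladder: loss of water with addition of H2
  hit <- explain_fragment(ion_mz("C15H24O6", "M+H"), 285)
  expect_equal(hit$path, "H2O")
  expect_equal(hit$adjustment, "+H2")
  # identity: zero-loss path
  same <- explain_fragment(p, p)
  expect_equal(same$n_losses, 0L)
  expect_equal(same$adjustment, "none")
  expect_null(explain_fragment(p, 100, max_depth = 2))
})

test_that("mass bookkeeping is exact along every assignment", {
  reg <- default_loss_registry()
  p <- ion_mz("C15H22O4", "M+H")
  for (fmz in c(249, 231, 239, 221, 203)) {
    hit <- explain_fragment(p, fmz)
    labels <- strsplit(hit$path, ";", fixed = TRUE)[[1]]
    adj <- switch(hit$adjustment, none = 0, `+H2` = 2 * 1.007825,
                  `-H2` = -2 * 1.007825)
    expect_equal(hit$theoretical_mz + sum(reg$mass[match(labels, reg$label)]) -
                   adj, p, tolerance = 1e-12)
  }
})

test_that("the search agrees with the exhaustive oracle on random instances", {
  set.seed(17)
  reg <- default_loss_registry()
  n_nonempty <- 0
  for (i in 1:200) {
    p <- stats::runif(1, 150, 500)
    f <- p - stats::runif(1, -1, 4 * 60 + 4)
    depth <- sample(0:4, 1)
    h2 <- sample(c(TRUE, FALSE), 1)
    all_paths <- explain_fragment_oracle(p, f, reg, depth, h2, tol = 0.3)
    found <- if (f <= p + 0.3 + 2 * 1.007825) {
      explain_fragment(p, f, reg, depth, h2, tol = 0.3)
    } else {
      NULL
    }
    if (nrow(all_paths) == 0) {
      expect_null(found)
    } else {
      n_nonempty <- n_nonempty + 1
      expect_false(is.null(found))
      expect_true(any(all_paths$path == found$path &
                        all_paths$adjustment == found$adjustment))
      # minimal-cardinality preference
      expect_equal(found$n_losses, min(all_paths$n_losses))
    }
  }
  expect_gt(n_nonempty, 20)  # the property was exercised, not vacuous
})

test_that("oracle enumerations contain the derived reference solutions", {
  p <- ion_mz("C15H22O5", "M+H")
  o247 <- explain_fragment_oracle(p, 247)
  expect_true("H2O;H2O" %in% o247$path[o247$adjustment == "none"])
  o191 <- explain_fragment_oracle(p, 191)
  expect_true(any(o191$path == "H2O;HCOOH;C2H4"))
  expect_equal(nrow(explain_fragment_oracle(100, 99.9, tol = 0.01)), 0L)
})

test_that("raising max_depth never unexplains a fragment", {
  set.seed(23)
  p <- ion_mz("C15H22O5", "M+H")
  frags <- p - stats::runif(30, 0, 150)
  for (i in seq_along(frags)) {
    explained_at <- vapply(1:4, function(d)
      !is.null(explain_fragment(p, frags[i], max_depth = d)), logical(1))
    expect_true(all(diff(explained_at) >= 0))
  }
})

test_that("each reference compound's printed fragment list is fully covered", {
  refs <- read_reference_compounds()
  for (i in seq_len(nrow(refs))) {
    ann <- annotate_spectrum(refs$formula[i], refs$fragments[[i]],
                             max_depth = 4, allow_h2 = TRUE, tol = 0.5)
    expect_equal(ann$coverage, 1.0)
    expect_equal(ann$n_considered, length(refs$fragments[[i]]))
  }
  # the de-ART 239 fragment is the carbon monoxide loss
  d239 <- annotate_spectrum("C15H22O4", 239)$assignments
  expect_equal(d239$path, "CO")
})

test_that("coverage distinguishes unexplainable, empty and capped spectra", {
  p_formula <- "C15H22O5"
  # nothing reachable: all fragments far below any depth-4 loss combination
  low <- annotate_spectrum(p_formula, c(30.1, 35.2), tol = 0.3)
  expect_equal(low$coverage, 0)
  # empty fragment list is not-evaluable, distinct from zero coverage
  none <- annotate_spectrum(p_formula, numeric(0))
  expect_true(is.na(none$coverage))
  expect_false(none$evaluable)
  # the cap keeps only the top-N most intense fragments
  frags <- data.frame(mz = seq(150, 281, length.out = 15),
                      intensity = 1:15)
  capped <- annotate_spectrum(p_formula, frags, max_fragments = 10)
  expect_equal(capped$n_considered, 10L)
  expect_true(all(capped$assignments$fragment_mz %in% frags$mz[6:15]))
})
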