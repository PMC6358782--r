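# Cross-system comparison, class tallies, Rt windows and fixture auditing.

test_that("the fixture replay reproduces the headline comparison", {
  rep <- replay_fixture()
  expect_equal(unname(rep$n), c(23L, 32L, 16L))
  expect_equal(length(rep$common), 16L)
  expect_true(all(rep$common %in% intersect(rep$in_vivo, rep$in_vitro)))
  expect_lte(length(rep$common), min(rep$n[["in_vivo"]], rep$n[["in_vitro"]]))
})

test_that("class tallies reproduce the printed hydroxylation counts", {
  fx <- read_metabolite_fixture()
  all_counts <- class_counts(fx, "all")
  expect_equal(all_counts[["ART + O"]], 13L)
  expect_equal(all_counts[["ART + O2"]], 9L)
  expect_equal(all_counts[["ART + O"]] + all_counts[["ART + O2"]], 22L)
  common <- class_counts(fx, "common")
  expected <- c("ART + O" = 7L, "ART + O2" = 2L, "de-ART" = 1L,
                "de-ART + O" = 4L, "DHA + O" = 1L, "DHA-O + O" = 1L)
  expect_setequal(names(common), names(expected))
  expect_equal(common[names(expected)], expected)
  # tallies sum to set size for every selector
  for (set in c("all", "in_vivo", "in_vitro", "common", "in_vivo_only",
                "in_vitro_only")) {
    expect_equal(sum(class_counts(fx, set)),
                 sum(switch(set, all = TRUE, in_vivo = fx$in_vivo,
                            in_vitro = fx$in_vitro,
                            common = fx$in_vivo & fx$in_vitro,
                            in_vivo_only = fx$in_vivo & !fx$in_vitro,
                            in_vitro_only = fx$in_vitro & !fx$in_vivo) *
                       rep(1L, nrow(fx))))
  }
})

test_that("retention-time windows match the elution ranges", {
  fx <- read_metabolite_fixture()
  expect_equal(rt_range(fx, "ART + O"), c(2.6, 5.8))
  expect_equal(rt_range(fx, "ART + O2"), c(2.0, 3.8))
  expect_equal(rt_range(fx, "DHA"), c(7.0, 7.0))  # single-record class
  expect_error(rt_range(fx, "no-such-class"), "no-such-class")
})

test_that("comparison is permutation-invariant and rejects duplicate ids", {
  fx <- read_metabolite_fixture()
  set.seed(4)
  shuffled <- fx[sample(nrow(fx)), ]
  expect_equal(compare_systems(shuffled)$n, compare_systems(fx)$n)
  expect_equal(compare_systems(shuffled)$common, compare_systems(fx)$common)
  dup <- rbind(fx, fx[1, ])
  expect_error(compare_systems(dup), "duplicate metabolite id")
})

test_that("empty record sets compare to zero counts", {
  empty <- read_metabolite_fixture()[0, ]
  rep <- compare_systems(empty)
  expect_equal(unname(rep$n), c(0L, 0L, 0L))
})

test_that("synthetic membership is recovered exactly by set arithmetic", {
  set.seed(8)
  n <- 40
  truth_vivo <- sample(c(TRUE, FALSE), n, replace = TRUE)
  truth_vitro <- ifelse(truth_vivo, sample(c(TRUE, FALSE), n, TRUE), TRUE)
  recs <- data.frame(id = sprintf("S%02d", 1:n),
                     class = sample(c("ART + O", "de-ART"), n, TRUE),
                     rt_min = stats::runif(n, 1, 10),
                     in_vivo = truth_vivo, in_vitro = truth_vitro,
                     stringsAsFactors = FALSE)
  rep <- compare_systems(recs)
  expect_equal(rep$n[["in_vivo"]], sum(truth_vivo))
  expect_equal(rep$n[["in_vitro"]], sum(truth_vitro))
  expect_equal(rep$n[["common"]], sum(truth_vivo & truth_vitro))
  expect_setequal(rep$common, recs$id[truth_vivo & truth_vitro])
})

test_that("the validator passes self-consistent rows and flags known typos", {
  fx <- read_metabolite_fixture()
  audit <- validate_fixture(fx)
  grade_of <- function(id, system) {
    audit$grade[audit$id == id & audit$system == system]
  }
  expect_equal(grade_of("M23", "in_vivo"), "pass")
  expect_equal(round_mda(audit$recomputed_err[audit$id == "M23" &
                                                audit$system == "in_vivo"]),
               -0.5)
  expect_equal(grade_of("M32", "in_vivo"), "pass")
  expect_equal(grade_of("M28", "in_vitro"), "pass")
  # observed m/z inconsistent with the printed formula + adduct
  expect_equal(grade_of("M11", "in_vivo"), "fail")
  expect_equal(grade_of("M21", "in_vitro"), "fail")
  expect_equal(grade_of("M38", "in_vitro"), "fail")
  # every per-system observation is audited
  expect_equal(nrow(audit), sum(fx$in_vivo) + sum(fx$in_vitro))
})
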