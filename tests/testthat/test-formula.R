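# Formula arithmetic, adduct rules, enumeration, compound matching and
# consensus classification.

test_that("monoisotopic masses match reference isotope sums", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C15H14O6"), 290.079038, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(c(C = 1, O = 2)), 43.989829,
               tolerance = 1e-6)
  expect_error(monoisotopic_mass(""), "non-empty")
  expect_error(monoisotopic_mass("Xx2"), "unknown element")
})

test_that("adduct applicability enforces element and mobile-phase rules", {
  rules <- default_adduct_rules()
  nh3_loss <- rules[rules$name == "[M+H-NH3]+", ]
  expect_false(rule_applicable("C15H14O6", nh3_loss))  # no N, no NH3 loss
  expect_true(rule_applicable("C8H10N4O2", nh3_loss))
  nh4 <- rules[rules$name == "[M+NH4]+", ]
  expect_false(rule_applicable("C15H14O6", nh4))  # mobile phase lacks NH4+
  expect_true(rule_applicable("C15H14O6", nh4,
                              context = list(mobile_phase_ions = "NH4+")))
  deprot <- rules[rules$name == "[M-H]-", ]
  expect_true(rule_applicable("C15H14O6", deprot))
})

test_that("ion m/z follows (n*M + delta)/z", {
  rules <- default_adduct_rules()
  m <- monoisotopic_mass("C15H14O6")
  expect_equal(ion_mz("C15H14O6", rules[rules$name == "[M-H]-", ]),
               289.071762, tolerance = 1e-6)
  expect_equal(ion_mz("C15H14O6", rules[rules$name == "[M+H]+", ]),
               291.086314, tolerance = 1e-6)
  expect_equal(ion_mz("C15H14O6", rules[rules$name == "[2M+H]+", ]),
               2 * m + 1.007276, tolerance = 1e-9)
  expect_error(ion_mz("C15H14O6", rules[rules$name == "[M+H-NH3]+", ]),
               "not applicable")
})

test_that("rule files round-trip through TSV", {
  rules <- default_adduct_rules()
  path <- tempfile(fileext = ".tsv")
  write_adduct_rules(rules, path)
  back <- read_adduct_rules(path)
  expect_equal(back$name, rules$name)
  expect_equal(back$mass_delta, rules$mass_delta, tolerance = 1e-9)
})

test_that("enumeration finds known formulas and respects boundaries", {
  hits <- enumerate_formulas(290.079038, 3)
  expect_true("C15H14O6" %in% hits$formula)
  expect_true(all(abs(hits$ppm) <= 3))
  expect_true(all(diff(abs(hits$ppm)) >= -1e-12))  # sorted by |ppm|

  exact <- enumerate_formulas(monoisotopic_mass("C6H12O6"), 0)
  expect_true(all(abs(exact$ppm) < 1e-9))
  expect_true("C6H12O6" %in% exact$formula)

  expect_equal(nrow(enumerate_formulas(10.0, 3)), 0)
})

test_that("enumeration matches the nested-loop oracle on small ranges", {
  ranges <- list(C = c(0, 10), H = c(0, 20), N = c(0, 2), O = c(0, 5),
                 P = c(0, 1), S = c(0, 1))
  set.seed(5)
  for (mass in runif(8, 60, 250)) {
    mine <- sort(enumerate_formulas(mass, 10, ranges)$formula)
    expect_equal(mine, oracle_enumerate(mass, 10, ranges))
  }
})

test_that("raising ppm tolerance never removes candidates", {
  f2 <- enumerate_formulas(290.079, 2)$formula
  f4 <- enumerate_formulas(290.079, 4)$formula
  expect_true(all(f2 %in% f4))
})

test_that("feature assignment inverts adduct rules and gates polarity", {
  cand <- assign_feature(289.0718, "negative", ppm_tol = 3)
  hit <- cand[cand$formula == "C15H14O6" & cand$adduct == "[M-H]-", ]
  expect_equal(nrow(hit), 1)
  expect_lte(abs(hit$ppm), 3)
  expect_true(all(cand$adduct %in% c("[M-H]-", "[M+Cl]-", "[M+HCOO]-",
                                     "[2M-H]-")))
  expect_equal(order(abs(cand$ppm)), seq_len(nrow(cand)))

  # round trip across all applicable default rules
  rules <- default_adduct_rules()
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (nzchar(r$requires_ion)) next
    if (!rule_applicable("C9H11NO2", r)) next
    mz <- ion_mz("C9H11NO2", r)
    cand <- assign_feature(mz, r$polarity, ppm_tol = 3)
    expect_true("C9H11NO2" %in%
                  cand$formula[cand$adduct == r$name],
                info = r$name)
  }
})

test_that("compound matching prefers the primary tier", {
  snap <- data.frame(
    compound_id = paste0("C", 1:6),
    formula = c("C6H12O6", "C6H12O6", "C6H12O6", "C5H5N5", "C5H5N5", "CH4"),
    tier = c("primary", "primary", "fallback", "fallback", "fallback",
             "fallback"),
    taxonomy_path = "A/B/C", stringsAsFactors = FALSE)
  hit <- match_compounds("C6H12O6", snap)
  expect_equal(hit$compound_id, c("C1", "C2"))
  fb <- match_compounds("C5H5N5", snap)
  expect_equal(fb$compound_id, c("C4", "C5"))
  expect_equal(nrow(match_compounds("C2H6O", snap)), 0)
})

test_that("consensus classification descends to the agreed depth", {
  cons <- consensus_classification(c("A/B/C", "A/B/D", "A/E/F"), 0.66)
  expect_equal(cons$path, c("A", "B"))
  expect_equal(cons$depth, 2)
  single <- consensus_classification("A/B/C/D")
  expect_equal(single$path, c("A", "B", "C", "D"))
  none <- consensus_classification(c("A/B", "C/D"), 0.66)
  expect_equal(none$depth, 0)
  expect_error(consensus_classification(character()), "no taxonomy")
  # order invariance, unanimity at threshold 1
  p <- c("A/B/C", "A/B/D", "A/B/C", "A/E/F")
  expect_equal(consensus_classification(p, 0.66),
               consensus_classification(rev(p), 0.66))
  expect_equal(consensus_classification(p, 1.0)$path, "A")
  # modal ties break the descent
  tie <- consensus_classification(c("A/B", "A/C"), 0.4)
  expect_equal(tie$path, "A")
})

test_that("class frequency counts are monotone across levels", {
  asg <- data.frame(
    feature_id = paste0("f", 1:4),
    consensus_path = c("K/S1/C1", "K/S1", "K/S2", ""),
    stringsAsFactors = FALSE)
  tab <- class_frequency_table(asg)
  expect_equal(tab$count[tab$level == 1 & tab$label == "K"], 3)
  expect_equal(sum(tab$count[tab$level == 2]), 3)
  expect_equal(sum(tab$count[tab$level == 3]), 1)
  totals <- tapply(tab$count, tab$level, sum)
  expect_true(all(diff(totals) <= 0))
})
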