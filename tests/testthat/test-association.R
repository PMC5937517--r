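test_that("chi_square shortcut equals the expected-count form", {
  # worked 2x2 table with strong positive association
  t <- contingency_table(1767, 1109, 4659, 8992)
  oracle <- chisq_expected_form(1767, 1109, 4659, 8992)
  expect_equal(chi_square(t), oracle, tolerance = 1e-12)
  expect_equal(chi_square(t), 745.5725, tolerance = 1e-4)
  # and agrees with the uncorrected Pearson test
  ref <- stats::chisq.test(matrix(c(1767, 4659, 1109, 8992), 2),
                           correct = FALSE)
  expect_equal(chi_square(t), unname(ref$statistic), tolerance = 1e-9)
})

test_that("chi_square is zero under perfect independence and symmetric", {
  t <- contingency_table(10, 10, 10, 10)
  expect_equal(chi_square(t), 0)
  t1 <- contingency_table(30, 12, 7, 41)
  # swapping rows and columns simultaneously leaves chi-square unchanged
  t2 <- contingency_table(41, 7, 12, 30)
  expect_equal(chi_square(t1), chi_square(t2))
  expect_error(chi_square(contingency_table(0, 0, 5, 5)), "margin")
})

test_that("statistical identities hold on random valid tables", {
  set.seed(404)
  for (i in 1:300) {
    t <- random_valid_table()
    chi <- chi_square(t)
    expect_equal(chi, chisq_expected_form(t$a, t$b, t$c, t$d),
                 tolerance = 1e-9)
    cmp <- comp_stat(t)
    expect_equal(cmp^2, chi, tolerance = 1e-9)
    delta <- t$a * t$d - t$b * t$c
    expect_equal(sign(cmp), sign(delta))
    # comp sign tracks the odds-ratio side of 1
    or <- (t$a * t$d) / (t$b * t$c)
    if (or > 1) expect_gt(cmp, 0)
    if (or < 1) expect_lt(cmp, 0)
    # comp = sqrt(n) * phi coefficient
    phi <- delta / sqrt(prod(adrmine:::margins_of(t)))
    expect_equal(cmp, sqrt(t$n) * phi, tolerance = 1e-9)
  }
})

test_that("min_tev gives the chi-square critical value or its root", {
  expect_equal(min_tev(0.05, "paper"), 3.841, tolerance = 1e-3)
  expect_equal(min_tev(0.05, "sqrt_scale"), 1.95996, tolerance = 1e-5)
  expect_equal(min_tev(0.05, "sqrt_scale")^2, min_tev(0.05, "paper"))
  expect_lt(min_tev(0.999, "paper"), 1e-4)  # alpha -> 1 limit
  expect_error(min_tev(0), "alpha")
  expect_error(min_tev(1.5), "alpha")
})

test_that("comp_stat reproduces the published worked example", {
  t <- contingency_table(1767, 1109, 4659, 8992)
  expect_equal(comp_stat(t), 27.305, tolerance = 1e-3)
  # within 5% relative of the reported 26.897 for this reconstruction
  expect_lt(abs(comp_stat(t) - 26.897) / 26.897, 0.05)
  expect_equal(comp_stat(contingency_table(10, 10, 10, 10)), 0)
})

test_that("validity_check needs n > 40 and expected counts >= 5", {
  expect_false(validity_check(contingency_table(10, 10, 10, 10)))  # n = 40
  expect_true(validity_check(contingency_table(100, 100, 100, 100)))
  expect_false(validity_check(contingency_table(1, 99, 1, 99)))
})

test_that("build_table counts set inclusion over the cohort", {
  db <- db_from_sets(list(P1 = "a", P2 = "a", P3 = character(0)),
                     ae_sets = list(P1 = "X", P3 = "X"))
  t <- build_table(db, "a", "X")
  expect_equal(c(t$a, t$b, t$c, t$d), c(1, 1, 1, 0))
  # absent antecedent -> empty exposed margin
  t0 <- build_table(db, "zzz", "X")
  expect_equal(t0$a + t0$b, 0)
  expect_error(chi_square(t0), "margin")
  # two-drug antecedent requires both drugs
  db2 <- db_from_sets(list(P1 = c("a", "b"), P2 = "a", P3 = "b", P4 = "c"),
                      ae_sets = list(P1 = "X"))
  t2 <- build_table(db2, c("a", "b"), "X")
  expect_equal(t2$a + t2$b, 1)
  expect_error(build_table(db2, character(0), "X"), "non-empty")
})

test_that("mine_rules recovers a planted harmful association", {
  spec <- synthetic_spec(
    5000,
    drugs = data.frame(drug_code = c("druga", "drugb", "drugc"),
                       prevalence = 0.2, stringsAsFactors = FALSE),
    aes = data.frame(ae_term = c("aex", "aey"), base_rate = 0.2,
                     stringsAsFactors = FALSE),
    effects = data.frame(drug_code = "druga", ae_term = "aex",
                         odds_ratio = 5, stringsAsFactors = FALSE),
    seed = 11)
  db <- cohort_db(generate_cohort(spec))
  rules <- mine_rules(db, mining_params(min_sup = 0.01))
  hit <- rules[rules$antecedent == "druga" & rules$consequent == "aex", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "positive")
  expect_gt(hit$comp, min_tev(0.05, "paper"))
})

test_that("mine_rules recovers a planted protective association", {
  spec <- synthetic_spec(
    5000,
    drugs = data.frame(drug_code = c("druga", "drugb"),
                       prevalence = 0.2, stringsAsFactors = FALSE),
    aes = data.frame(ae_term = "aex", base_rate = 0.4,
                     stringsAsFactors = FALSE),
    effects = data.frame(drug_code = "druga", ae_term = "aex",
                         odds_ratio = 0.2, stringsAsFactors = FALSE),
    seed = 12)
  db <- cohort_db(generate_cohort(spec))
  rules <- mine_rules(db, mining_params(min_sup = 0.01, min_cof = 5))
  hit <- rules[rules$antecedent == "druga" & rules$consequent == "aex", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "negative")
  expect_lt(hit$comp, -min_tev(0.05, "paper"))
})

test_that("raising thresholds only ever shrinks the rule set", {
  spec <- null_spec(2000, 8, 4, seed = 13)
  db <- cohort_db(generate_cohort(spec))
  key <- function(r) paste(r$antecedent, r$consequent)
  base <- mine_rules(db, mining_params(min_sup = 0.01, min_cof = 1,
                                       alpha = 0.5, threshold_mode = "sqrt_scale"))
  for (min_cof in c(5, 15, 30)) {
    shrunk <- mine_rules(db, mining_params(min_sup = 0.01, min_cof = min_cof,
                                           alpha = 0.5,
                                           threshold_mode = "sqrt_scale"))
    expect_true(all(key(shrunk) %in% key(base)))
  }
  for (alpha in c(0.2, 0.05, 0.01)) {  # smaller alpha -> larger min_tev
    shrunk <- mine_rules(db, mining_params(min_sup = 0.01, min_cof = 1,
                                           alpha = alpha,
                                           threshold_mode = "sqrt_scale"))
    expect_true(all(key(shrunk) %in% key(base)))
  }
})

test_that("rule_strength_rank orders by |comp| with lexicographic ties", {
  rules <- data.frame(
    antecedent = c("b", "a", "c", "a"), consequent = c("x", "x", "x", "y"),
    comp = c(5, -7, 2, -7), stringsAsFactors = FALSE)
  ranked <- rule_strength_rank(rules)
  expect_equal(ranked$comp, c(-7, -7, 5, 2))
  expect_equal(ranked$antecedent[1:2], c("a", "a"))
  expect_equal(ranked$consequent[1:2], c("x", "y"))
  expect_equal(nrow(rule_strength_rank(rules[0, ])), 0L)
})

test_that("mining_params validates its ranges", {
  expect_error(mining_params(alpha = 0), "alpha")
  expect_error(mining_params(min_cof = 0), "min_cof")
  expect_error(mining_params(min_cof = 101), "min_cof")
  expect_error(mining_params(max_antecedent = 0), "max_antecedent")
})
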