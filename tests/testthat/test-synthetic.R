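test_that("synthetic_spec validates fields by name", {
  drugs <- data.frame(drug_code = "a", prevalence = 0.2)
  aes <- data.frame(ae_term = "x", base_rate = 0.2)
  expect_error(synthetic_spec(-1, drugs, aes), "n_patients")
  expect_error(
    synthetic_spec(10, data.frame(drug_code = "a", prevalence = 1.2), aes),
    "prevalence")
  expect_error(synthetic_spec(10, drugs, data.frame(ae_term = "x", base_rate = 0)),
               "base_rate")
  expect_error(
    synthetic_spec(10, drugs, aes,
                   effects = data.frame(drug_code = "a", ae_term = "x",
                                        odds_ratio = -2)),
    "odds_ratio")
  expect_error(
    synthetic_spec(10, drugs, aes,
                   effects = data.frame(drug_code = "zz", ae_term = "x",
                                        odds_ratio = 2)),
    "unknown drug")
  expect_error(synthetic_spec(10, drugs, aes, grade_probs = c(0.5, 0.5)),
               "grade_probs")
})

test_that("the same seed reproduces the cohort byte-for-byte", {
  spec <- null_spec(500, 5, 3, seed = 41)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$exposures, c2$exposures)
  expect_identical(c1$ae_records, c2$ae_records)
  spec2 <- null_spec(500, 5, 3, seed = 42)
  c3 <- generate_cohort(spec2)
  expect_false(identical(c1$exposures, c3$exposures))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_cohort(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null-cohort marginals match the generative rates within 3 s.e.", {
  n <- 10000
  spec <- null_spec(n, 6, 4, seed = 43, prevalence = 0.2, base_rate = 0.15)
  coh <- generate_cohort(spec)
  db <- cohort_db(coh)
  mats <- adrmine:::db_matrices(db)
  se_drug <- sqrt(0.2 * 0.8 / n)
  for (rate in colMeans(mats$drugs))
    expect_lt(abs(rate - 0.2), 3 * se_drug)
  se_ae <- sqrt(0.15 * 0.85 / n)
  for (rate in colMeans(mats$aes))
    expect_lt(abs(rate - 0.15), 3 * se_ae)
})

test_that("a planted odds ratio shifts the conditional AE rate", {
  spec <- synthetic_spec(
    5000,
    drugs = data.frame(drug_code = c("druga", "drugb"), prevalence = 0.2,
                       stringsAsFactors = FALSE),
    aes = data.frame(ae_term = "aex", base_rate = 0.2,
                     stringsAsFactors = FALSE),
    effects = data.frame(drug_code = "druga", ae_term = "aex",
                         odds_ratio = 5, stringsAsFactors = FALSE),
    seed = 44)
  t <- build_table(cohort_db(generate_cohort(spec)), "druga", "aex")
  expect_gt(t$a / (t$a + t$b), t$c / (t$c + t$d))
})

test_that("planting is sign-faithful across seeded replicates", {
  hits <- vapply(1:20, function(s) {
    spec <- synthetic_spec(
      2000,
      drugs = data.frame(drug_code = "druga", prevalence = 0.2,
                         stringsAsFactors = FALSE),
      aes = data.frame(ae_term = "aex", base_rate = 0.2,
                       stringsAsFactors = FALSE),
      effects = data.frame(drug_code = "druga", ae_term = "aex",
                           odds_ratio = 3, stringsAsFactors = FALSE),
      seed = 4000 + s)
    t <- build_table(cohort_db(generate_cohort(spec)), "druga", "aex")
    (t$a * t$d) > (t$b * t$c)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("co-prescription boost raises joint exposure", {
  spec <- synthetic_spec(
    8000,
    drugs = data.frame(drug_code = c("druga", "drugb"), prevalence = 0.2,
                       stringsAsFactors = FALSE),
    aes = data.frame(ae_term = "aex", base_rate = 0.2,
                     stringsAsFactors = FALSE),
    co_rx = data.frame(drug_i = "druga", drug_j = "drugb", boost = 3,
                       stringsAsFactors = FALSE),
    seed = 45)
  db <- cohort_db(generate_cohort(spec))
  joint <- sum(vapply(db$drug_sets, function(s) all(c("druga", "drugb") %in% s),
                      logical(1))) / db$n
  expect_gt(joint, 2 * 0.2 * 0.2)  # well above the independent 4%
})

test_that("an empty cohort produces empty tables and truth", {
  spec <- null_spec(0, 2, 2, seed = 46)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$exposures), 0L)
  expect_equal(nrow(coh$ae_records), 0L)
  expect_equal(coh$truth$n_patients, 0L)
  expect_length(coh$truth$effects, 0L)
})

test_that("generate_cohort writes loadable files", {
  dir <- withr::local_tempdir()
  spec <- null_spec(50, 3, 2, seed = 47)
  coh <- generate_cohort(spec, dir = dir)
  expo <- suppressMessages(read_exposures(file.path(dir, "exposures.csv")))
  expect_identical(expo$patient_id, coh$exposures$patient_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$n_patients, 50)
})

test_that("evaluate_against_truth scores matches, signs, and degeneracies", {
  truth <- list(effects = data.frame(
    drug_code = c("druga", "drugb"), ae_term = c("aex", "aey"),
    odds_ratio = c(5, 0.2), stringsAsFactors = FALSE))
  rules <- data.frame(
    antecedent = c("druga", "drugb", "drugc"),
    consequent = c("aex", "aey", "aex"),
    direction = c("positive", "negative", "positive"),
    stringsAsFactors = FALSE)
  res <- evaluate_against_truth(rules, truth)
  expect_equal(res$recall, 1)
  expect_equal(res$precision, 2 / 3)
  expect_equal(res$sign_accuracy, 1)
  # wrong sign does not count as recovery
  rules$direction[2] <- "positive"
  res2 <- evaluate_against_truth(rules, truth)
  expect_equal(res2$recall, 0.5)
  expect_equal(res2$sign_accuracy, 0.5)
  # empty rule set: recall 0, precision 1 by convention with flag
  res3 <- evaluate_against_truth(rules[0, ], truth)
  expect_equal(res3$recall, 0)
  expect_equal(res3$precision, 1)
  expect_false(res3$precision_defined)
  # strict matching requires every antecedent drug to carry an effect
  two <- data.frame(antecedent = "druga;drugc", consequent = "aex",
                    direction = "positive", stringsAsFactors = FALSE)
  expect_equal(evaluate_against_truth(two, truth, match = "single")$recall, 0.5)
  expect_equal(evaluate_against_truth(two, truth, match = "strict")$recall, 0)
})
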