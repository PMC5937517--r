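#' Specify a synthetic pharmacovigilance cohort
#'
#' Defines the generative model for a cohort with known ground truth:
#' independent Bernoulli drug exposures (optionally boosted into
#' regimen-like co-prescription pairs), and adverse events drawn per
#' patient from a logistic model whose log-odds are the AE's baseline
#' log-odds plus the sum of log odds ratios of the drugs the patient is
#' exposed to. Odds ratios above 1 plant positive drug-AE associations,
#' below 1 protective (negative) ones; 1 is the null. Grades are drawn
#' from a per-AE distribution over 1..4 given occurrence.
#'
#' @param n_patients Cohort size (>= 0).
#' @param drugs Data.frame with columns `drug_code`, `prevalence`
#'   (exposure probability in (0, 1)).
#' @param aes Data.frame with columns `ae_term`, `base_rate` (baseline
#'   occurrence probability in (0, 1)); optional `soc` column.
#' @param effects Data.frame with columns `drug_code`, `ae_term`,
#'   `odds_ratio` (> 0); pairs not listed have odds ratio 1. May be
#'   `NULL` for a fully null cohort.
#' @param co_rx Data.frame with columns `drug_i`, `drug_j`, `boost`
#'   (>= 1): the target joint-exposure probability of the pair is
#'   `boost` times the product of the marginals (capped at the smaller
#'   marginal), creating regimen-like co-prescription. `NULL` for none.
#' @param grade_probs Probability vector of length 4 (grades 1..4 given
#'   occurrence), or a named list of such vectors per AE term. Default
#'   `c(0.60, 0.25, 0.10, 0.05)`, the mild-skewed severity profile
#'   typical of laboratory AEs.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_patients, drugs, aes, effects = NULL,
                           co_rx = NULL,
                           grade_probs = c(0.60, 0.25, 0.10, 0.05),
                           seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 0)
    stop("invalid field n_patients: must be a non-negative count", call. = FALSE)
  check_frame(drugs, c("drug_code", "prevalence"), "drugs")
  if (any(drugs$prevalence <= 0 | drugs$prevalence >= 1))
    stop("invalid field drugs$prevalence: must lie in (0, 1)", call. = FALSE)
  if (anyDuplicated(drugs$drug_code))
    stop("invalid field drugs$drug_code: duplicates", call. = FALSE)
  check_frame(aes, c("ae_term", "base_rate"), "aes")
  if (any(aes$base_rate <= 0 | aes$base_rate >= 1))
    stop("invalid field aes$base_rate: must lie in (0, 1)", call. = FALSE)
  if (is.null(aes$soc)) aes$soc <- "Investigations"
  if (!is.null(effects)) {
    check_frame(effects, c("drug_code", "ae_term", "odds_ratio"), "effects")
    if (any(effects$odds_ratio <= 0))
      stop("invalid field effects$odds_ratio: must be > 0", call. = FALSE)
    if (!all(effects$drug_code %in% drugs$drug_code))
      stop("invalid field effects$drug_code: unknown drug", call. = FALSE)
    if (!all(effects$ae_term %in% aes$ae_term))
      stop("invalid field effects$ae_term: unknown AE term", call. = FALSE)
  }
  if (!is.null(co_rx)) {
    check_frame(co_rx, c("drug_i", "drug_j", "boost"), "co_rx")
    if (any(co_rx$boost < 1))
      stop("invalid field co_rx$boost: must be >= 1", call. = FALSE)
  }
  gp_check <- function(p, where) {
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("invalid field grade_probs", if (nzchar(where)) paste0(" (", where, ")"),
           ": must be 4 probabilities summing to 1", call. = FALSE)
  }
  if (is.list(grade_probs)) {
    for (term in names(grade_probs)) gp_check(grade_probs[[term]], term)
  } else gp_check(grade_probs, "")
  structure(list(n_patients = as.integer(n_patients), drugs = drugs,
                 aes = aes, effects = effects, co_rx = co_rx,
                 grade_probs = grade_probs, seed = as.integer(seed)),
            class = "synthetic_spec")
}

check_frame <- function(df, cols, name) {
  if (!is.data.frame(df) || !all(cols %in% names(df)))
    stop("invalid field ", name, ": needs columns ",
         paste(cols, collapse = ", "), call. = FALSE)
}

#' Generate a synthetic cohort with known planted effects
#'
#' Draws the cohort defined by a [synthetic_spec()]. Exposures are
#' independent Bernoulli draws per drug; each co-prescription pair then
#' has additional patients set to joint exposure so the pair's joint
#' probability approaches `boost` times the product of marginals. AE
#' occurrence follows the logistic model (effects combine additively on
#' the log-odds scale across exposures); grades are drawn from the AE's
#' grade distribution. The caller's RNG state is preserved; everything is
#' reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory: when given, writes `patients.csv` (the
#'   cohort roster, so downstream mining can use the full denominator),
#'   `exposures.csv`, `adverse_events.csv` and `truth.json` there.
#' @return List with `exposures` (patient_id, drug_code), `ae_records`
#'   (patient_id, ae_term, soc, grade), and `truth` (list with the
#'   planted non-unit odds ratios and the generative parameters).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_patients
  drugs <- spec$drugs$drug_code
  pats <- if (n > 0) sprintf("P%05d", seq_len(n)) else character(0)
  expo <- matrix(FALSE, nrow = n, ncol = length(drugs),
                 dimnames = list(pats, drugs))
  for (j in seq_along(drugs))
    expo[, j] <- stats::runif(n) < spec$drugs$prevalence[j]
  if (!is.null(spec$co_rx) && n > 0) {
    for (r in seq_len(nrow(spec$co_rx))) {
      di <- spec$co_rx$drug_i[r]; dj <- spec$co_rx$drug_j[r]
      pi <- spec$drugs$prevalence[match(di, drugs)]
      pj <- spec$drugs$prevalence[match(dj, drugs)]
      target <- min(spec$co_rx$boost[r] * pi * pj, min(pi, pj))
      # promote non-joint patients to joint exposure with the probability
      # that lifts P(joint) from pi*pj toward the target
      q <- (target - pi * pj) / (1 - pi * pj)
      if (q > 0) {
        notjoint <- !(expo[, di] & expo[, dj])
        promote <- notjoint & (stats::runif(n) < q)
        expo[promote, c(di, dj)] <- TRUE
      }
    }
  }

  terms <- spec$aes$ae_term
  log_or <- matrix(0, nrow = length(drugs), ncol = length(terms),
                   dimnames = list(drugs, terms))
  if (!is.null(spec$effects) && nrow(spec$effects) > 0) {
    for (r in seq_len(nrow(spec$effects)))
      log_or[spec$effects$drug_code[r], spec$effects$ae_term[r]] <-
        log(spec$effects$odds_ratio[r])
  }
  # n x terms matrix of per-patient log-odds
  lp <- matrix(rep(stats::qlogis(spec$aes$base_rate), each = max(n, 1L)),
               nrow = max(n, 1L))
  if (n > 0 && length(drugs) > 0) lp <- lp + (expo %*% log_or)
  occur <- if (n > 0) matrix(stats::runif(n * length(terms)) < stats::plogis(lp),
                             nrow = n, dimnames = list(pats, terms))
           else matrix(FALSE, 0, length(terms), dimnames = list(NULL, terms))

  hits <- which(expo, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  exposures <- data.frame(patient_id = pats[hits[, 1L]],
                          drug_code = drugs[hits[, 2L]],
                          stringsAsFactors = FALSE)
  grade_for <- function(term, k) {
    p <- if (is.list(spec$grade_probs)) spec$grade_probs[[term]] else spec$grade_probs
    sample(1:4, k, replace = TRUE, prob = p)
  }
  ae_pieces <- lapply(seq_along(terms), function(j) {
    who <- which(occur[, j])
    if (!length(who)) return(NULL)
    data.frame(patient_id = pats[who], ae_term = terms[j],
               soc = spec$aes$soc[j], grade = grade_for(terms[j], length(who)),
               stringsAsFactors = FALSE)
  })
  ae_records <- do.call(rbind, ae_pieces)
  if (is.null(ae_records))
    ae_records <- data.frame(patient_id = character(0), ae_term = character(0),
                             soc = character(0), grade = integer(0),
                             stringsAsFactors = FALSE)

  planted <- spec$effects
  if (!is.null(planted)) planted <- planted[planted$odds_ratio != 1, , drop = FALSE]
  truth <- list(
    n_patients = n, seed = spec$seed,
    effects = if (is.null(planted) || nrow(planted) == 0L) list() else planted,
    drugs = spec$drugs, aes = spec$aes[, c("ae_term", "base_rate")])

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(data.frame(patient_id = pats), file.path(dir, "patients.csv"),
                     row.names = FALSE, quote = FALSE)
    write_exposures(exposures, file.path(dir, "exposures.csv"))
    write_ae_records(ae_records, file.path(dir, "adverse_events.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(exposures = exposures, ae_records = ae_records, truth = truth)
}

#' Transaction database over the full simulated cohort
#'
#' Builds the [build_itemset_db()] database for a generated cohort with
#' the complete patient universe, so patients with neither exposures nor
#' AEs still count in contingency-table denominators (the generator's ids
#' are `P00001..P<n>`).
#'
#' @param cohort List returned by [generate_cohort()].
#' @return An `itemset_db` with `n == truth$n_patients`.
#' @export
cohort_db <- function(cohort) {
  n <- cohort$truth$n_patients
  build_itemset_db(cohort$exposures, cohort$ae_records,
                   patients = if (n > 0) sprintf("P%05d", seq_len(n)))
}

#' Score mined rules against the planted ground truth
#'
#' A mined rule matches a truth effect when its antecedent contains the
#' effect's drug and the consequents agree; its sign is correct when the
#' rule direction matches the side of 1 the planted odds ratio lies on.
#' With `match = "strict"`, a multi-drug rule only counts toward recall
#' of an effect if every antecedent drug carries a non-unit odds ratio
#' for that AE.
#'
#' @param rules Rule data.frame from [mine_rules()].
#' @param truth `truth` element from [generate_cohort()].
#' @param match `"single"` (default) or `"strict"`.
#' @return List with `recall`, `precision`, `sign_accuracy`,
#'   `n_truth`, `n_rules`, and `precision_defined` (`FALSE` when there
#'   are no rules, in which case precision is reported as 1 by
#'   convention).
#' @export
evaluate_against_truth <- function(rules, truth, match = c("single", "strict")) {
  match <- match.arg(match)
  eff <- truth$effects
  eff <- if (is.data.frame(eff) && nrow(eff)) eff else
    data.frame(drug_code = character(0), ae_term = character(0),
               odds_ratio = numeric(0), stringsAsFactors = FALSE)
  n_truth <- nrow(eff)
  if (nrow(rules) == 0L)
    return(list(recall = if (n_truth) 0 else NA_real_, precision = 1,
                sign_accuracy = NA_real_, n_truth = n_truth, n_rules = 0L,
                precision_defined = FALSE))
  ante <- strsplit(rules$antecedent, ";", fixed = TRUE)
  truth_key <- paste(eff$drug_code, eff$ae_term)
  nonunit <- function(drug, term) paste(drug, term) %in% truth_key
  rule_hits <- lapply(seq_len(nrow(rules)), function(i) {
    drugs_in <- ante[[i]][nonunit(ante[[i]], rules$consequent[i])]
    if (length(drugs_in) == 0L) return(character(0))
    if (match == "strict" && length(drugs_in) < length(ante[[i]]))
      return(character(0))
    paste(drugs_in, rules$consequent[i])
  })
  matched_rule <- lengths(rule_hits) > 0L
  precision <- mean(matched_rule)
  recovered <- logical(n_truth)
  sign_ok <- logical(0)
  for (i in which(matched_rule)) {
    hit_idx <- match(rule_hits[[i]], truth_key)
    planted_pos <- eff$odds_ratio[hit_idx] > 1
    ok <- (rules$direction[i] == "positive") == planted_pos
    recovered[hit_idx[ok]] <- TRUE
    sign_ok <- c(sign_ok, ok)
  }
  list(recall = if (n_truth) mean(recovered) else NA_real_,
       precision = precision,
       sign_accuracy = if (length(sign_ok)) mean(sign_ok) else NA_real_,
       n_truth = n_truth, n_rules = nrow(rules), precision_defined = TRUE)
}
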