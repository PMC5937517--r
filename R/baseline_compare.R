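#' Mine rules with the conventional support/confidence Apriori
#'
#' The baseline miner: identical Step 1 (frequent itemsets), but Step 2
#' retains every (itemset, AE) pair whose confidence meets `min_cof`, with
#' no chi-square screen. The signed statistic is still computed and
#' attached for reporting, and `direction` is labeled post hoc by its sign
#' (`"none"` when undefined or exactly zero) so the two miners' outputs
#' are comparable. Because its filter is strictly weaker, the screened
#' miner's rule set is always a subset of this one at equal thresholds.
#'
#' @param db An [build_itemset_db()] database.
#' @param min_sup Minimum support (count or fraction).
#' @param min_cof Minimum confidence in percent.
#' @param max_antecedent Largest antecedent size.
#' @param support_def `"antecedent"` or `"joint"`, as in [mining_params()].
#' @return Rule data.frame in the same layout as [mine_rules()].
#' @export
mine_rules_conventional <- function(db, min_sup = 165, min_cof = 10,
                                    max_antecedent = 2L,
                                    support_def = "antecedent") {
  params <- mining_params(min_sup = min_sup, min_cof = min_cof,
                          max_antecedent = max_antecedent,
                          support_def = support_def)
  itemsets <- mine_frequent_itemsets(db, params$min_sup, params$max_antecedent)
  cand <- evaluate_candidates(db, itemsets, params)
  if (nrow(cand) == 0L) return(empty_rules())
  keep <- !is.na(cand$confidence) & cand$confidence >= min_cof
  out <- cand[keep, , drop = FALSE]
  out$direction <- ifelse(is.na(out$comp) | out$comp == 0, "none",
                          ifelse(out$comp > 0, "positive", "negative"))
  out <- rule_strength_rank(out)
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "params") <- params
  out
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two samples: exact enumeration when
#' the combined sample size is at most 12 and there are no ties, and the
#' normal approximation with tie and continuity correction otherwise
#' (via [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (the Mann-Whitney U for `x`), `p_value`,
#'   and `method` (`"exact"` or `"normal approximation"`).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Compare the screened and conventional miners on one database
#'
#' Runs both miners at the same support/confidence thresholds, stratifies
#' the retained rules by antecedent size (single drug vs. two drugs) and
#' direction, and reports per-stratum rule counts, mean `comp`, mean
#' support and mean confidence for each algorithm, plus a rank-sum
#' p-value comparing the two algorithms' `comp` distributions within the
#' stratum (`NA` when either side is empty). Wall-clock mining times are
#' recorded for information only -- they are hardware-dependent.
#'
#' @param db An [build_itemset_db()] database.
#' @param params A [mining_params()] bundle (used by the screened miner;
#'   the baseline reuses its support/confidence thresholds).
#' @return Object of class `ade_comparison`: a list with `summary` (the
#'   stratified data.frame), `totals`, `rules_modified`,
#'   `rules_conventional` and `timings`.
#' @export
compare_algorithms <- function(db, params = mining_params()) {
  t0 <- proc.time()[["elapsed"]]
  conv <- mine_rules_conventional(db, params$min_sup, params$min_cof,
                                  params$max_antecedent, params$support_def)
  t1 <- proc.time()[["elapsed"]]
  mod <- mine_rules(db, params)
  t2 <- proc.time()[["elapsed"]]

  strata <- expand.grid(size = c(1L, 2L), direction = c("positive", "negative"),
                        stringsAsFactors = FALSE)
  strata <- strata[order(strata$size, strata$direction != "positive"), ]
  stat_row <- function(rules, size, direction) {
    sub <- rules[rules$antecedent_size == size & rules$direction == direction, ,
                 drop = FALSE]
    list(n = nrow(sub),
         comp_mean = if (nrow(sub)) mean(sub$comp) else NA_real_,
         support_mean = if (nrow(sub)) mean(sub$support) else NA_real_,
         confidence_mean = if (nrow(sub)) mean(sub$confidence) else NA_real_,
         comp = sub$comp)
  }
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sz <- strata$size[i]; dir <- strata$direction[i]
    cv <- stat_row(conv, sz, dir)
    md <- stat_row(mod, sz, dir)
    p <- if (cv$n >= 1L && md$n >= 1L)
      rank_sum_test(md$comp, cv$comp)$p_value else NA_real_
    data.frame(antecedent_size = sz, direction = dir,
               conventional_n = cv$n, conventional_comp = cv$comp_mean,
               conventional_support = cv$support_mean,
               conventional_confidence = cv$confidence_mean,
               modified_n = md$n, modified_comp = md$comp_mean,
               modified_support = md$support_mean,
               modified_confidence = md$confidence_mean,
               rank_sum_p = p, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(
    summary = summary,
    totals = data.frame(
      algorithm = c("conventional", "modified"),
      n_rules = c(nrow(conv), nrow(mod)),
      n_single = c(sum(conv$antecedent_size == 1L), sum(mod$antecedent_size == 1L)),
      n_two = c(sum(conv$antecedent_size == 2L), sum(mod$antecedent_size == 2L)),
      n_positive = c(sum(conv$direction == "positive"), sum(mod$direction == "positive")),
      n_negative = c(sum(conv$direction == "negative"), sum(mod$direction == "negative")),
      elapsed_s = c(t1 - t0, t2 - t1),
      stringsAsFactors = FALSE),
    rules_modified = mod, rules_conventional = conv),
    class = "ade_comparison")
}

#' @export
print.ade_comparison <- function(x, ...) {
  cat("Algorithm comparison (screened vs conventional Apriori)\n\n")
  print(x$totals, row.names = FALSE)
  cat("\nPer-stratum summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a comparison report
#'
#' @param report An `ade_comparison` from [compare_algorithms()].
#' @param path Output path; `.json` selects JSON, anything else a TSV of
#'   the per-stratum summary.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(totals = report$totals, summary = report$summary),
                         path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(report$summary, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
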