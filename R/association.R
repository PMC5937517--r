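#' A 2x2 exposure-by-event contingency table
#'
#' The atom of all screening statistics: counts of patients
#' cross-classified by antecedent exposure (all drugs of the itemset) and
#' adverse-event occurrence (any grade >= 1).
#'
#' @param a Exposed with the event.
#' @param b Exposed without the event.
#' @param c Unexposed with the event.
#' @param d Unexposed without the event.
#' @return Object of class `contab` with fields `a`, `b`, `c`, `d`, `n`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contab")
}

#' @export
print.contab <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("exposed", "unexposed"), c("event", "no event")))
  print(m)
  invisible(x)
}

margins_of <- function(t) {
  c(row1 = t$a + t$b, row2 = t$c + t$d, col1 = t$a + t$c, col2 = t$b + t$d)
}

#' Pearson chi-square of a 2x2 table (shortcut form)
#'
#' Computes \eqn{\chi^2 = n(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]} with one
#' degree of freedom -- algebraically identical to the expected-count form
#' \eqn{\sum (O - E)^2 / E}. No continuity correction is applied.
#'
#' @param t A [contingency_table()].
#' @return Non-negative chi-square value.
#' @export
chi_square <- function(t) {
  m <- margins_of(t)
  if (any(m == 0))
    stop("chi-square undefined: a table margin is zero", call. = FALSE)
  t$n * (t$a * t$d - t$b * t$c)^2 / prod(m)
}

#' Minimum test value: the screening threshold for `comp`
#'
#' The threshold that the screening statistic must exceed in magnitude for
#' a rule to be called. Two conventions are offered:
#' \describe{
#'   \item{`paper`}{the chi-square(df = 1) upper-`alpha` critical value
#'     itself (3.841 at `alpha = 0.05`), the threshold the method was
#'     originally stated with.}
#'   \item{`sqrt_scale`}{its square root (1.960 at 0.05) -- consistent with
#'     `comp` living on the root (signed-z) scale, and the choice that
#'     makes the screen an exact-level two-sided test.}
#' }
#'
#' @param alpha Two-sided significance level in (0, 1).
#' @param mode `"paper"` or `"sqrt_scale"`.
#' @return The threshold value.
#' @export
min_tev <- function(alpha = 0.05, mode = c("paper", "sqrt_scale")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  crit <- stats::qchisq(1 - alpha, df = 1)
  if (mode == "paper") crit else sqrt(crit)
}

#' Signed chi-square screening statistic
#'
#' The signed square root of the Pearson chi-square:
#' \eqn{\mathrm{comp} = \mathrm{sign}(ad - bc)\,\sqrt{\chi^2}
#' = \sqrt{n}\,\phi}, where \eqn{\phi} is the phi coefficient of the 2x2
#' table. Positive values mean the exposure raises the event frequency,
#' negative values that it lowers it; the magnitude measures rule
#' strength. Zero exactly when `ad = bc` (sample independence).
#'
#' @param t A [contingency_table()].
#' @return Signed real value with `comp_stat(t)^2 == chi_square(t)`.
#' @export
comp_stat <- function(t) {
  sign(t$a * t$d - t$b * t$c) * sqrt(chi_square(t))
}

#' Chi-square applicability check
#'
#' The classical validity condition for the chi-square approximation on a
#' 2x2 table: total sample size greater than 40 and all four expected
#' counts (row margin x column margin / n) at least 5.
#'
#' @param t A [contingency_table()].
#' @return `TRUE` if the approximation is considered applicable.
#' @export
validity_check <- function(t) {
  if (t$n <= 40) return(FALSE)
  m <- margins_of(t)
  expected <- c(m["row1"] * m["col1"], m["row1"] * m["col2"],
                m["row2"] * m["col1"], m["row2"] * m["col2"]) / t$n
  all(expected >= 5)
}

#' Build the 2x2 table for one (drug itemset, AE term) pair
#'
#' A patient is exposed when their drug set contains every antecedent
#' drug; the event is present when the AE term appears in their AE set at
#' any grade. The denominator is the full cohort: patients with no
#' recorded AEs count as event-absent.
#'
#' @param db An [build_itemset_db()] database.
#' @param antecedent Character vector of drug codes (non-empty).
#' @param consequent AE term.
#' @return A [contingency_table()].
#' @export
build_table <- function(db, antecedent, consequent) {
  if (length(antecedent) == 0L) stop("antecedent must be non-empty", call. = FALSE)
  exposed <- vapply(db$drug_sets, function(s) all(antecedent %in% s), logical(1))
  event <- vapply(db$ae_sets, function(s) consequent %in% s, logical(1))
  contingency_table(sum(exposed & event), sum(exposed & !event),
                    sum(!exposed & event), sum(!exposed & !event))
}

#' Mining parameters
#'
#' Bundles the thresholds of the rule miner. Defaults follow the
#' motivating study design: `min_sup = 165` (1% of a 16,527-patient
#' cohort; pass a fraction < 1 to scale with cohort size), `min_cof = 10`
#' (percent), `alpha = 0.05` compared on the `"paper"` threshold scale,
#' and antecedents of at most two drugs.
#'
#' @param min_sup Minimum support: absolute count, or fraction in (0, 1).
#' @param min_cof Minimum confidence, in percent, in (0, 100].
#' @param alpha Significance level for the screen.
#' @param threshold_mode `"paper"` (compare `|comp|` to the chi-square
#'   critical value, 3.841 at 0.05) or `"sqrt_scale"` (compare to its
#'   root, 1.960 -- the calibrated two-sided test).
#' @param max_antecedent Largest antecedent itemset size.
#' @param support_def `"antecedent"` (rule support = antecedent support /
#'   n, the reading consistent with published worked examples) or
#'   `"joint"` (= a / n).
#' @param p_adjust `"none"` (default) or `"BH"`: optionally attach
#'   Benjamini-Hochberg adjusted two-sided p-values and screen on them.
#' @return Object of class `mining_params`.
#' @export
mining_params <- function(min_sup = 165, min_cof = 10, alpha = 0.05,
                          threshold_mode = c("paper", "sqrt_scale"),
                          max_antecedent = 2L,
                          support_def = c("antecedent", "joint"),
                          p_adjust = c("none", "BH")) {
  threshold_mode <- match.arg(threshold_mode)
  support_def <- match.arg(support_def)
  p_adjust <- match.arg(p_adjust)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(min_cof) || min_cof <= 0 || min_cof > 100)
    stop("min_cof must lie in (0, 100]", call. = FALSE)
  if (max_antecedent < 1L) stop("max_antecedent must be >= 1", call. = FALSE)
  structure(list(min_sup = min_sup, min_cof = min_cof, alpha = alpha,
                 threshold_mode = threshold_mode,
                 max_antecedent = as.integer(max_antecedent),
                 support_def = support_def, p_adjust = p_adjust),
            class = "mining_params")
}

# Shared candidate evaluation: one row per (frequent itemset, AE term)
# with every statistic attached. Vectorized over patients via incidence
# matrices; pairs with a zero margin get NA statistics.
evaluate_candidates <- function(db, itemsets, params) {
  mats <- db_matrices(db)
  terms <- colnames(mats$aes)
  if (nrow(itemsets) == 0L || length(terms) == 0L) return(empty_rules())
  item_list <- strsplit(itemsets$items, ";", fixed = TRUE)
  rows <- vector("list", nrow(itemsets) * length(terms))
  idx <- 0L
  threshold <- min_tev(params$alpha, params$threshold_mode)
  for (i in seq_len(nrow(itemsets))) {
    items <- item_list[[i]]
    exposed <- rowSums(mats$drugs[, items, drop = FALSE]) == length(items)
    n_exp <- sum(exposed)
    for (term in terms) {
      event <- mats$aes[, term]
      a <- sum(exposed & event)
      b <- n_exp - a
      c_ <- sum(event) - a
      d <- db$n - n_exp - c_
      degenerate <- (a + b) == 0L || (c_ + d) == 0L ||
        (a + c_) == 0L || (b + d) == 0L
      if (degenerate) {
        chi2 <- NA_real_; comp <- NA_real_; valid <- FALSE
      } else {
        t <- contingency_table(a, b, c_, d)
        chi2 <- chi_square(t)
        comp <- sign(a * d - b * c_) * sqrt(chi2)
        valid <- validity_check(t)
      }
      support <- if (params$support_def == "antecedent")
        itemsets$support_count[i] / db$n else a / db$n
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        antecedent = itemsets$items[i], antecedent_size = itemsets$size[i],
        consequent = term, a = a, b = b, c = c_, d = d, n = db$n,
        support = support,
        confidence = if (n_exp > 0) 100 * a / n_exp else NA_real_,
        chi2 = chi2, comp = comp, valid = valid,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(idx)])
  out$p_value <- ifelse(is.na(out$chi2), NA_real_,
                        stats::pchisq(out$chi2, df = 1, lower.tail = FALSE))
  attr(out, "min_tev") <- threshold
  out
}

empty_rules <- function() {
  out <- data.frame(antecedent = character(0), antecedent_size = integer(0),
                    consequent = character(0), a = integer(0), b = integer(0),
                    c = integer(0), d = integer(0), n = integer(0),
                    support = numeric(0), confidence = numeric(0),
                    chi2 = numeric(0), comp = numeric(0), valid = logical(0),
                    p_value = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "n_candidates") <- 0L
  out
}

#' Mine positive and negative association rules (chi-square screened)
#'
#' The full two-step miner. Step 1 finds all frequent drug itemsets up to
#' `max_antecedent` drugs. Step 2 crosses every frequent itemset with
#' every AE term, computes support, confidence and the signed chi-square
#' statistic, and retains the pairs with `confidence >= min_cof` and
#' `|comp|` above the screening threshold [min_tev()]. The sign of `comp`
#' classifies each retained rule as a positive association (the exposure
#' raises the AE frequency) or a negative one (it lowers it).
#'
#' @param db An [build_itemset_db()] database.
#' @param params A [mining_params()] bundle.
#' @return Data.frame of retained rules sorted by `|comp|` descending
#'   (ties broken by antecedent, then consequent), with columns
#'   `antecedent` (semicolon-joined drugs), `antecedent_size`,
#'   `consequent`, `a`, `b`, `c`, `d`, `n`, `support`, `confidence` (%),
#'   `chi2`, `comp`, `valid`, `p_value`, `direction`. The number of
#'   candidate (itemset, AE) pairs evaluated and pairs screened by the
#'   statistic alone are attached as attributes `n_candidates` and
#'   `n_flagged`; the threshold used as `min_tev`.
#' @export
mine_rules <- function(db, params = mining_params()) {
  itemsets <- mine_frequent_itemsets(db, params$min_sup, params$max_antecedent)
  cand <- evaluate_candidates(db, itemsets, params)
  if (nrow(cand) == 0L) return(empty_rules())
  threshold <- attr(cand, "min_tev")
  flagged <- !is.na(cand$comp) & abs(cand$comp) > threshold
  if (params$p_adjust == "BH") {
    padj <- stats::p.adjust(cand$p_value, method = "BH")
    cand$p_adjusted <- padj
    flagged <- flagged & !is.na(padj) & padj <= params$alpha
  }
  keep <- flagged & !is.na(cand$confidence) & cand$confidence >= params$min_cof
  out <- cand[keep, , drop = FALSE]
  out$direction <- ifelse(out$comp > 0, "positive", "negative")
  out <- rule_strength_rank(out)
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "n_flagged") <- sum(flagged)
  attr(out, "min_tev") <- threshold
  attr(out, "params") <- params
  out
}

#' Order rules by association strength
#'
#' Stable descending sort by `|comp|`; ties broken lexicographically by
#' antecedent, then consequent. Rules with undefined `comp` sink to the
#' bottom.
#'
#' @param rules Rule data.frame with columns `comp`, `antecedent`,
#'   `consequent`.
#' @return The reordered data.frame.
#' @export
rule_strength_rank <- function(rules) {
  if (nrow(rules) == 0L) return(rules)
  key <- abs(rules$comp)
  key[is.na(key)] <- -Inf
  out <- rules[order(-key, rules$antecedent, rules$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write mined rules as TSV or JSON
#'
#' @param rules Rule data.frame from [mine_rules()] or
#'   [mine_rules_conventional()].
#' @param path Output path; a `.json` extension selects JSON, anything
#'   else TSV.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rules, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    utils::write.table(rules, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
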