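# Independent oracles and fixture builders shared across tests.
# These deliberately avoid the code paths they check.

# Exhaustive frequent-itemset enumeration over every non-empty item
# subset, via a superset-sum (zeta) transform on transaction bitmasks --
# a different algorithm from the miner's level-wise join/prune/count
# path. Feasible for <= 16 distinct items.
brute_force_itemsets <- function(db, min_sup, max_k = Inf) {
  empty <- data.frame(items = character(0), size = integer(0),
                      support_count = integer(0), stringsAsFactors = FALSE)
  items <- sort(unique(unlist(db$drug_sets)))
  K <- length(items)
  if (K == 0L) return(empty)
  stopifnot(K <= 16L)
  bits <- 2L^(seq_len(K) - 1L)
  masks <- vapply(db$drug_sets,
                  function(s) sum(bits[match(s, items)]), numeric(1))
  f <- tabulate(masks + 1L, nbins = 2L^K)  # transactions per exact mask
  # after the transform, f[m + 1] = #transactions whose mask contains m
  all_masks <- 0:(2L^K - 1L)
  for (b in bits) {
    lacks <- which(bitwAnd(all_masks, b) == 0L)
    f[lacks] <- f[lacks] + f[lacks + b]
  }
  sizes <- vapply(all_masks, function(m) sum(bitwAnd(m, bits) > 0L), integer(1))
  keep <- which(all_masks > 0L & f >= min_sup & sizes <= max_k)
  if (!length(keep)) return(empty)
  out <- data.frame(
    items = vapply(all_masks[keep], function(m)
      paste(items[bitwAnd(m, bits) > 0L], collapse = ";"), character(1)),
    size = sizes[keep], support_count = f[keep], stringsAsFactors = FALSE)
  out <- out[order(out$size, out$items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Expected-count chi-square: sum (O - E)^2 / E with E from the margins.
chisq_expected_form <- function(a, b, c, d) {
  O <- matrix(c(a, c, b, d), nrow = 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Build an itemset_db directly from a named list of drug sets (and
# optionally AE sets), every patient kept.
db_from_sets <- function(drug_sets, ae_sets = NULL) {
  pats <- union(names(drug_sets), names(ae_sets))
  expo <- data.frame(
    patient_id = rep(names(drug_sets), lengths(drug_sets)),
    drug_code = unlist(drug_sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  ae <- if (is.null(ae_sets)) NULL else data.frame(
    patient_id = rep(names(ae_sets), lengths(ae_sets)),
    ae_term = unlist(ae_sets, use.names = FALSE),
    soc = "Investigations", grade = 1L, stringsAsFactors = FALSE)
  build_itemset_db(expo, ae, patients = pats)
}

# Random transaction database over lowercase-letter items.
random_db <- function(n_items, n_trans, p = 0.35) {
  items <- letters[seq_len(n_items)]
  pats <- sprintf("T%04d", seq_len(n_trans))
  sets <- lapply(seq_len(n_trans), function(i) items[stats::runif(n_items) < p])
  names(sets) <- pats
  expo <- data.frame(patient_id = rep(pats, lengths(sets)),
                     drug_code = unlist(sets, use.names = FALSE),
                     stringsAsFactors = FALSE)
  build_itemset_db(expo, NULL, patients = pats)
}

# Random 2x2 table with all cells >= 1 (so every margin is positive).
random_valid_table <- function(max_cell = 200L) {
  contingency_table(sample(max_cell, 1), sample(max_cell, 1),
                    sample(max_cell, 1), sample(max_cell, 1))
}

# Small null synthetic spec shared by calibration tests.
null_spec <- function(n, n_drugs, n_aes, seed, prevalence = 0.2,
                      base_rate = 0.2) {
  synthetic_spec(
    n_patients = n,
    drugs = data.frame(drug_code = sprintf("drug%02d", seq_len(n_drugs)),
                       prevalence = prevalence, stringsAsFactors = FALSE),
    aes = data.frame(ae_term = sprintf("ae%02d", seq_len(n_aes)),
                     base_rate = base_rate, stringsAsFactors = FALSE),
    seed = seed)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
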