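#' Frequent single items (first Apriori pass)
#'
#' Counts each drug's per-patient support (a patient contributes at most
#' once however often the drug was prescribed) and keeps those meeting the
#' minimum support count.
#'
#' @param db An [build_itemset_db()] database.
#' @param min_sup Minimum support as an absolute patient count (>= 1), or
#'   a fraction in (0, 1) converted via `floor(min_sup * n)`.
#' @return Data.frame of frequent 1-itemsets with columns `items`, `size`,
#'   `support_count`, `support`, sorted lexicographically.
#' @export
find_frequent_1_itemsets <- function(db, min_sup) {
  min_sup <- resolve_min_sup(min_sup, db$n)
  counts <- table(unlist(db$drug_sets))
  if (length(counts) == 0L)
    return(itemset_frame(list(), integer(0), db$n))
  keep <- counts[counts >= min_sup]
  keep <- keep[order(names(keep))]
  itemset_frame(as.list(names(keep)), as.integer(keep), db$n)
}

#' Candidate generation by prefix join
#'
#' Joins every pair of frequent (k-1)-itemsets agreeing on their first
#' k-2 items into a k-candidate (the Agrawal-Srikant join).
#'
#' @param L_prev List of character vectors, each a sorted (k-1)-itemset,
#'   all the same size.
#' @return Sorted, duplicate-free list of k-item character vectors.
#' @export
apriori_join <- function(L_prev) {
  if (length(L_prev) < 2L) return(list())
  sizes <- lengths(L_prev)
  if (length(unique(sizes)) != 1L)
    stop("all itemsets in L_prev must have equal size", call. = FALSE)
  k1 <- sizes[[1L]]
  L_prev <- lapply(L_prev, sort)
  prefixes <- vapply(L_prev, function(x) paste(x[seq_len(k1 - 1L)], collapse = "\r"),
                     character(1))
  lasts <- vapply(L_prev, function(x) x[k1], character(1))
  out <- list()
  groups <- split(seq_along(L_prev), prefixes)
  for (idx in groups) {
    if (length(idx) < 2L) next
    prefix <- L_prev[[idx[1L]]][seq_len(k1 - 1L)]
    tails <- sort(unique(lasts[idx]))
    cmb <- utils::combn(tails, 2L, simplify = FALSE)
    out <- c(out, lapply(cmb, function(p) c(prefix, p)))
  }
  sort_itemsets(unique(out))
}

#' Candidate pruning by the anti-monotone property
#'
#' Removes every candidate having some (k-1)-subset that is not frequent;
#' such a candidate cannot be frequent itself.
#'
#' @param candidates List of k-item character vectors.
#' @param L_prev List of frequent (k-1)-itemsets (character vectors).
#' @return The surviving candidates, order preserved.
#' @export
apriori_prune <- function(candidates, L_prev) {
  if (length(candidates) == 0L) return(list())
  prev_keys <- vapply(L_prev, function(x) paste(sort(x), collapse = "\r"),
                      character(1))
  keep <- vapply(candidates, function(cand) {
    subs <- vapply(seq_along(cand),
                   function(i) paste(cand[-i], collapse = "\r"), character(1))
    all(subs %in% prev_keys)
  }, logical(1))
  candidates[keep]
}

#' Level-wise frequent-itemset mining (Apriori)
#'
#' Finds every drug itemset of size up to `max_k` whose per-patient
#' support count meets `min_sup`, by the classic level-wise
#' generate-join-prune-count loop. Output equals exhaustive enumeration of
#' all qualifying itemsets; support counts are exact.
#'
#' @inheritParams find_frequent_1_itemsets
#' @param max_k Largest itemset size to mine (default 2: single drugs and
#'   drug pairs, the antecedent sizes reported in practice). The loop also
#'   stops as soon as a level is empty.
#' @return Data.frame with columns `items` (semicolon-joined sorted
#'   drugs), `size`, `support_count`, `support` (fraction of patients),
#'   ordered by size then lexicographically.
#' @export
mine_frequent_itemsets <- function(db, min_sup, max_k = 2L) {
  min_sup <- resolve_min_sup(min_sup, db$n)
  if (max_k < 1L) stop("max_k must be >= 1", call. = FALSE)
  L1 <- find_frequent_1_itemsets(db, min_sup)
  out <- list(L1)
  if (db$n == 0L || nrow(L1) == 0L) return(L1)
  mats <- db_matrices(db)
  L_prev <- strsplit(L1$items, ";", fixed = TRUE)
  k <- 2L
  while (k <= max_k && length(L_prev) >= 2L) {
    cand <- apriori_prune(apriori_join(L_prev), L_prev)
    if (length(cand) == 0L) break
    counts <- vapply(cand, function(items) support_count(mats$drugs, items),
                     integer(1))
    keep <- counts >= min_sup
    if (!any(keep)) break
    Lk <- cand[keep]
    out[[k]] <- itemset_frame(Lk, counts[keep], db$n)
    L_prev <- Lk
    k <- k + 1L
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write frequent itemsets as TSV
#'
#' @param itemsets Data.frame from [mine_frequent_itemsets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_itemsets_tsv <- function(itemsets, path) {
  utils::write.table(itemsets, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

support_count <- function(drug_mat, items) {
  if (!all(items %in% colnames(drug_mat))) return(0L)
  sum(rowSums(drug_mat[, items, drop = FALSE]) == length(items))
}

itemset_frame <- function(itemsets, counts, n) {
  data.frame(items = vapply(itemsets, paste, character(1), collapse = ";"),
             size = lengths(itemsets),
             support_count = as.integer(counts),
             support = if (n > 0) counts / n else numeric(length(counts)),
             stringsAsFactors = FALSE)
}

sort_itemsets <- function(sets) {
  if (length(sets) == 0L) return(list())
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets[order(keys)]
}

resolve_min_sup <- function(min_sup, n) {
  if (!is.numeric(min_sup) || length(min_sup) != 1L || is.na(min_sup) ||
      min_sup <= 0)
    stop("min_sup must be a positive count or a fraction in (0, 1)",
         call. = FALSE)
  if (min_sup < 1) return(max(1L, as.integer(floor(min_sup * n))))
  if (min_sup != floor(min_sup))
    stop("min_sup >= 1 must be an integer count", call. = FALSE)
  as.integer(min_sup)
}
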