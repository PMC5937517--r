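#' Read a patient-drug exposure table
#'
#' Reads a long-format CSV with one row per (patient, drug) exposure.
#' Drug codes are expected to be normalized to active ingredients upstream;
#' the reader only lower-cases and strips surrounding whitespace. Exact
#' duplicate (patient, drug) pairs collapse to a single membership, since
#' support counting is per-patient set membership.
#'
#' @param path Path to a CSV file with header columns
#'   `patient_id,drug_code`.
#' @return A data.frame with columns `patient_id` and `drug_code`, one row
#'   per distinct (patient, drug) pair, in first-appearance order. The
#'   number of duplicate rows removed is attached as attribute
#'   `"n_deduplicated"`.
#' @export
read_exposures <- function(path) {
  df <- read_required_csv(path, c("patient_id", "drug_code"))
  if (nrow(df) == 0L) {
    warning("exposure file ", path, " contains a header but no rows")
    return(df)
  }
  df$drug_code <- tolower(trimws(df$drug_code))
  df$patient_id <- trimws(df$patient_id)
  dup <- duplicated(df[, c("patient_id", "drug_code")])
  out <- df[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_deduplicated") <- sum(dup)
  message(sprintf("read_exposures: %d rows, %d after dedup", nrow(df), nrow(out)))
  out
}

#' Write a patient-drug exposure table
#'
#' Inverse of [read_exposures()]: writes the deduplicated exposure table as
#' CSV so that read-then-write round-trips byte-stably.
#'
#' @param exposures Data.frame with columns `patient_id`, `drug_code`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposures <- function(exposures, path) {
  utils::write.csv(exposures[, c("patient_id", "drug_code"), drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a laboratory-result table
#'
#' One row per measurement. `value`, `ref_low` and `ref_high` are parsed as
#' numbers; unparseable entries survive as `NA` so that
#' [validate_records()] can report them rather than the reader silently
#' dropping rows.
#'
#' @param path CSV with header columns
#'   `patient_id,test_code,value,ref_low,ref_high` (the reference-range
#'   columns may be empty).
#' @return Data.frame with those five columns; numeric columns parsed.
#' @export
read_lab_results <- function(path) {
  df <- read_required_csv(path, c("patient_id", "test_code", "value",
                                  "ref_low", "ref_high"))
  for (col in c("value", "ref_low", "ref_high")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$patient_id <- trimws(df$patient_id)
  df
}

#' Read a pre-graded adverse-event table
#'
#' @param path CSV with header columns `patient_id,ae_term,soc,grade`.
#' @return Data.frame with those columns, `grade` integer.
#' @export
read_ae_records <- function(path) {
  df <- read_required_csv(path, c("patient_id", "ae_term", "soc", "grade"))
  df$grade <- suppressWarnings(as.integer(df$grade))
  df$patient_id <- trimws(df$patient_id)
  df
}

#' Write a graded adverse-event table
#'
#' @param ae_records Data.frame with columns `patient_id`, `ae_term`,
#'   `soc`, `grade`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ae_records <- function(ae_records, path) {
  utils::write.csv(ae_records[, c("patient_id", "ae_term", "soc", "grade"),
                              drop = FALSE],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_required_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[, required, drop = FALSE]
}

#' Validate exposure and laboratory records (case deletion)
#'
#' Applies consistency checks and drops offending rows ("case deletion"):
#' rows with a missing/empty patient or drug/test identifier, laboratory
#' rows with a non-numeric value, and laboratory rows whose reference range
#' is inverted or degenerate (`ref_low >= ref_high` when both present).
#' Violations are counted per rule, never raised; the function is
#' deterministic and never invents rows.
#'
#' @param exposures Data.frame from [read_exposures()] (or `NULL`).
#' @param labs Data.frame from [read_lab_results()] (or `NULL`).
#' @return A list with elements `exposures`, `labs` (cleaned tables) and
#'   `report`, a named list mapping violated rule to number of rows
#'   dropped.
#' @export
validate_records <- function(exposures = NULL, labs = NULL) {
  report <- list()
  bump <- function(rule, k) {
    if (k > 0L) report[[rule]] <<- (report[[rule]] %||% 0L) + as.integer(k)
  }
  if (!is.null(exposures)) {
    bad_id <- is.na(exposures$patient_id) | exposures$patient_id == "" |
      is.na(exposures$drug_code) | exposures$drug_code == ""
    bump("missing identifier (exposures)", sum(bad_id))
    exposures <- exposures[!bad_id, , drop = FALSE]
    rownames(exposures) <- NULL
  }
  if (!is.null(labs)) {
    bad_id <- is.na(labs$patient_id) | labs$patient_id == "" |
      is.na(labs$test_code) | labs$test_code == ""
    bump("missing identifier (labs)", sum(bad_id))
    labs <- labs[!bad_id, , drop = FALSE]
    bad_val <- is.na(labs$value) | !is.finite(labs$value)
    bump("non-numeric value", sum(bad_val))
    labs <- labs[!bad_val, , drop = FALSE]
    bad_ref <- !is.na(labs$ref_low) & !is.na(labs$ref_high) &
      labs$ref_low >= labs$ref_high
    bump("inverted reference range", sum(bad_ref))
    labs <- labs[!bad_ref, , drop = FALSE]
    rownames(labs) <- NULL
  }
  message("validate_records: dropped ",
          sum(unlist(report) %||% 0L), " row(s)")
  list(exposures = exposures, labs = labs, report = report)
}

#' Write an exclusion report as JSON
#'
#' @param report The `report` element returned by [validate_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Build a per-patient transaction database
#'
#' Turns long-format exposure and adverse-event tables into per-patient
#' drug and AE sets -- the transaction database that frequent-itemset
#' mining and 2x2-table construction operate on. The patient universe is
#' the union of ids appearing in either table: patients with drugs but no
#' recorded AEs (and vice versa) are kept with empty sets, so that every
#' patient contributes to the contingency-table denominator.
#'
#' @param exposures Data.frame with columns `patient_id`, `drug_code`, or
#'   `NULL`.
#' @param ae_records Data.frame with columns `patient_id`, `ae_term` (other
#'   columns ignored), or `NULL`.
#' @param patients Optional explicit patient universe (character vector of
#'   ids). Use when the cohort is known to contain patients with neither
#'   exposures nor AEs, so they still enter the denominator. Ids appearing
#'   in the tables but not listed here are appended.
#' @return An object of class `itemset_db`: a list with `patients`
#'   (ids in first-appearance order), `drug_sets` and `ae_sets` (named
#'   lists of sorted character vectors, one per patient) and `n`.
#' @export
build_itemset_db <- function(exposures = NULL, ae_records = NULL,
                             patients = NULL) {
  ids <- as.character(patients %||% character(0))
  if (!is.null(exposures) && nrow(exposures)) ids <- c(ids, exposures$patient_id)
  if (!is.null(ae_records) && nrow(ae_records)) ids <- c(ids, ae_records$patient_id)
  patients <- unique(ids)
  empty <- stats::setNames(rep(list(character(0)), length(patients)), patients)
  drug_sets <- empty
  ae_sets <- empty
  if (!is.null(exposures) && nrow(exposures)) {
    sp <- split(exposures$drug_code, factor(exposures$patient_id, levels = patients))
    sp <- lapply(sp, function(x) sort(unique(x)))
    drug_sets[names(sp)] <- sp
  }
  if (!is.null(ae_records) && nrow(ae_records)) {
    sp <- split(ae_records$ae_term, factor(ae_records$patient_id, levels = patients))
    sp <- lapply(sp, function(x) sort(unique(x)))
    ae_sets[names(sp)] <- sp
  }
  structure(list(patients = patients, drug_sets = drug_sets,
                 ae_sets = ae_sets, n = length(patients)),
            class = "itemset_db")
}

#' @export
print.itemset_db <- function(x, ...) {
  cat("<itemset_db> ", x$n, " patients, ",
      length(unique(unlist(x$drug_sets))), " distinct drugs, ",
      length(unique(unlist(x$ae_sets))), " distinct AE terms\n", sep = "")
  invisible(x)
}

# Patient x item incidence matrices used by the miners. Column order is the
# sorted item vocabulary; row order follows db$patients.
db_matrices <- function(db) {
  inc <- function(sets) {
    vocab <- sort(unique(unlist(sets)))
    m <- matrix(FALSE, nrow = db$n, ncol = length(vocab),
                dimnames = list(db$patients, vocab))
    # sets are stored in db$patients order, so positional indexing is safe
    for (i in seq_len(db$n)) {
      s <- sets[[i]]
      if (length(s)) m[i, s] <- TRUE
    }
    m
  }
  list(drugs = inc(db$drug_sets), aes = inc(db$ae_sets))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
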