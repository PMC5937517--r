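#' Construct a severity grading rule
#'
#' A grading rule maps values of one laboratory test to adverse-event
#' grades 1..4 in the style of CTCAE laboratory criteria. A rule declares
#' a direction (`"below"`: lower is worse, e.g. hemoglobin; `"above"`:
#' higher is worse, e.g. ALT) and up to four boundaries, one per grade,
#' strictly increasing in severity. Boundaries are interpreted per
#' `boundary_type`:
#' \describe{
#'   \item{`absolute`}{cut point in the test's native unit.}
#'   \item{`ref_multiple`}{multiplier of the relevant reference limit
#'     (`ref_high` for above-rules, `ref_low` for below-rules), the usual
#'     "x upper limit of normal" phrasing.}
#'   \item{`ref_offset`}{offset from the reference limit, applied in the
#'     severity direction.}
#' }
#' Crossing a boundary exactly assigns the more severe grade.
#'
#' @param ae_term Adverse-event term the rule produces (e.g. `"Anemia"`).
#' @param soc System organ class of the term.
#' @param test_code Laboratory test the rule applies to.
#' @param direction `"above"` or `"below"`.
#' @param boundaries Numeric vector, length 1..4, grade 1 first. `NA`
#'   entries mean the grade is not defined for this term.
#' @param boundary_type One of `"absolute"`, `"ref_multiple"`,
#'   `"ref_offset"`.
#' @return An object of class `grade_rule`.
#' @export
grade_rule <- function(ae_term, soc, test_code, direction, boundaries,
                       boundary_type = "absolute") {
  direction <- match.arg(direction, c("above", "below"))
  boundary_type <- match.arg(boundary_type,
                             c("absolute", "ref_multiple", "ref_offset"))
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || length(boundaries) > 4L)
    stop("boundaries must have length 1..4", call. = FALSE)
  if (all(is.na(boundaries)))
    stop("at least one boundary must be present", call. = FALSE)
  fin <- boundaries[!is.na(boundaries)]
  if (length(fin) > 1L) {
    mono <- if (direction == "below") all(diff(fin) <= 0) else all(diff(fin) >= 0)
    # ref_offset boundaries grow with severity in either direction
    if (boundary_type == "ref_offset") mono <- all(diff(fin) >= 0)
    if (!mono)
      stop("boundaries must be monotone toward greater severity for ",
           ae_term, call. = FALSE)
  }
  structure(list(ae_term = ae_term, soc = soc, test_code = test_code,
                 direction = direction, boundaries = boundaries,
                 boundary_type = boundary_type),
            class = "grade_rule")
}

#' Read a grading configuration file
#'
#' Parses a YAML (or JSON) file with a top-level `rules:` list, each entry
#' holding the fields of [grade_rule()].
#'
#' @param path Path to the config file.
#' @return List of `grade_rule` objects.
#' @export
read_grading_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$rules)) stop("grading config has no `rules` entry", call. = FALSE)
  lapply(cfg$rules, function(r) {
    grade_rule(ae_term = r$ae_term, soc = r$soc %||% "Investigations",
               test_code = r$test_code, direction = r$direction,
               boundaries = vapply(r$boundaries,
                                   function(b) if (is.null(b)) NA_real_ else as.numeric(b),
                                   numeric(1)),
               boundary_type = r$boundary_type %||% "absolute")
  })
}

# Resolve the rule's boundaries to absolute cut points for one measurement.
# Returns NULL when the rule needs a reference limit that is absent.
resolve_boundaries <- function(rule, ref_low, ref_high) {
  b <- rule$boundaries
  if (rule$boundary_type == "absolute") return(b)
  ref <- if (rule$direction == "below") ref_low else ref_high
  if (is.na(ref)) return(NULL)
  if (rule$boundary_type == "ref_multiple") return(b * ref)
  if (rule$direction == "below") ref - b else ref + b
}

#' Grade one laboratory value
#'
#' Returns the highest grade whose boundary the value crosses, or 0 when
#' the value does not cross the grade-1 boundary (including any value
#' inside the reference range). Boundary crossing is inclusive toward the
#' more severe grade. A relative rule applied to a measurement lacking its
#' reference limit returns `NA` (ungradeable) so callers can tally it.
#'
#' @param rule A [grade_rule()].
#' @param value Numeric measurement, in the test's native unit.
#' @param ref_low,ref_high Reference limits of the measurement (may be
#'   `NA`).
#' @return Integer grade 0..4, or `NA` if ungradeable.
#' @export
grade_value <- function(rule, value, ref_low = NA_real_, ref_high = NA_real_) {
  cuts <- resolve_boundaries(rule, ref_low, ref_high)
  if (is.null(cuts)) return(NA_integer_)
  hit <- if (rule$direction == "below") value <= cuts else value >= cuts
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(0L)
  max(which(hit))
}

#' Derive graded adverse-event records from laboratory results
#'
#' Applies every matching grading rule to every measurement and rolls the
#' results up to one record per (patient, AE term) at the patient's worst
#' grade across all measurements. Grade-0 results produce no record;
#' re-grading the rollup changes nothing.
#'
#' @param labs Data.frame of laboratory results
#'   (`patient_id,test_code,value,ref_low,ref_high`).
#' @param rules List of [grade_rule()] objects.
#' @return Data.frame with columns `patient_id`, `ae_term`, `soc`,
#'   `grade`, one row per (patient, term); the number of ungradeable
#'   measurements is attached as attribute `"n_ungradeable"`.
#' @export
derive_ae_records <- function(labs, rules) {
  empty <- data.frame(patient_id = character(0), ae_term = character(0),
                      soc = character(0), grade = integer(0),
                      stringsAsFactors = FALSE)
  attr(empty, "n_ungradeable") <- 0L
  if (is.null(labs) || nrow(labs) == 0L || length(rules) == 0L) return(empty)
  n_ungradeable <- 0L
  pieces <- lapply(rules, function(rule) {
    sub <- labs[labs$test_code == rule$test_code, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    g <- mapply(grade_value, value = sub$value, ref_low = sub$ref_low,
                ref_high = sub$ref_high, MoreArgs = list(rule = rule))
    n_ungradeable <<- n_ungradeable + sum(is.na(g))
    keep <- !is.na(g) & g > 0L
    if (!any(keep)) return(NULL)
    data.frame(patient_id = sub$patient_id[keep], ae_term = rule$ae_term,
               soc = rule$soc, grade = as.integer(g[keep]),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, pieces)
  if (is.null(long)) {
    attr(empty, "n_ungradeable") <- n_ungradeable
    return(empty)
  }
  # worst-grade rollup per (patient, term)
  key <- paste(long$patient_id, long$ae_term, sep = "\r")
  ord <- order(key, -long$grade)
  long <- long[ord, , drop = FALSE]
  out <- long[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(match(out$ae_term, vapply(rules, `[[`, "", "ae_term")),
                   out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_ungradeable") <- n_ungradeable
  out
}

#' Tabulate adverse-event incidence by term and grade
#'
#' Counts, for every (SOC, AE term), the number of patients whose worst
#' grade is 1, 2, 3 and 4, the number of distinct patients with any grade
#' (`grand_total` -- always the sum of the four per-grade worst counts)
#' and the percentage of the cohort, rounded half-up to two decimals.
#'
#' @param ae_records Data.frame of graded AE records (worst grade per
#'   patient and term, as produced by [derive_ae_records()]).
#' @param n Cohort size (denominator of the percentage); must be >= 1.
#' @return Data.frame with columns `soc`, `ae_term`, `grade1`..`grade4`,
#'   `grand_total`, `percentage`.
#' @export
incidence_table <- function(ae_records, n) {
  if (n < 1L) stop("cohort size n must be >= 1", call. = FALSE)
  cols <- c("soc", "ae_term", paste0("grade", 1:4), "grand_total", "percentage")
  if (is.null(ae_records) || nrow(ae_records) == 0L) {
    out <- data.frame(soc = character(0), ae_term = character(0),
                      grade1 = integer(0), grade2 = integer(0),
                      grade3 = integer(0), grade4 = integer(0),
                      grand_total = integer(0), percentage = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  tab <- table(paste(ae_records$soc, ae_records$ae_term, sep = "\r"),
               factor(ae_records$grade, levels = 1:4))
  keys <- rownames(tab)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  counts <- matrix(as.integer(tab), nrow = nrow(tab))
  grand <- rowSums(counts)
  out <- data.frame(
    soc = vapply(parts, `[[`, "", 1L),
    ae_term = vapply(parts, `[[`, "", 2L),
    grade1 = counts[, 1L], grade2 = counts[, 2L],
    grade3 = counts[, 3L], grade4 = counts[, 4L],
    grand_total = as.integer(grand),
    percentage = round_half_up(100 * grand / n, 2L),
    stringsAsFactors = FALSE)
  out <- out[order(out$soc, out$ae_term), cols]
  rownames(out) <- NULL
  out
}

#' Write an incidence table as TSV
#'
#' @param tab Data.frame from [incidence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Round half away from zero (commercial rounding), as incidence
# percentages are conventionally reported; base round() is half-even.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
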