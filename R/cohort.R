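#' Define a Patient Safety Indicator
#'
#' Numerator / denominator logic is list-driven: code sets are matched by
#' string prefix against normalized (dot-stripped, upper-cased) codes.  No
#' official code lists ship with the package; they are an external,
#' user-supplied resource.  Mortality in low-mortality DRGs (`"mlm"`) is a
#' quasi-sentinel event: it is analysed on crude rates without patient-level
#' adjustment.
#'
#' @param name indicator name; one of `"mlm"`, `"du"`, `"cri"`, `"pe_dvt"`,
#'   `"ps"` or any user-defined string.
#' @param numerator_codes character vector of code prefixes defining events.
#' @param denominator_inclusion_codes,denominator_exclusion_codes prefixes
#'   defining the at-risk population.  All `NULL` means eligibility/event
#'   flags are taken from precomputed `eligible_<name>` / `event_<name>`
#'   columns (the synthetic-data route).
#' @param is_quasi_sentinel logical; defaults to `TRUE` for `"mlm"`.
#' @return object of class `psival_psi`.
#' @export
psi_definition <- function(name,
                           numerator_codes = NULL,
                           denominator_inclusion_codes = NULL,
                           denominator_exclusion_codes = NULL,
                           is_quasi_sentinel = identical(tolower(name), "mlm")) {
  name <- tolower(name)
  norm <- function(x) if (is.null(x)) NULL else normalize_codes(x)
  structure(list(name = name,
                 numerator_codes = norm(numerator_codes),
                 denominator_inclusion_codes = norm(denominator_inclusion_codes),
                 denominator_exclusion_codes = norm(denominator_exclusion_codes),
                 is_quasi_sentinel = isTRUE(is_quasi_sentinel)),
            class = "psival_psi")
}

#' Define a comorbidity-to-code-prefix map
#'
#' @param map named list: comorbidity name -> character vector of code
#'   prefixes (Elixhauser-style; actual lists are user-supplied).
#' @return object of class `psival_comorbidity_map`.
#' @export
comorbidity_map <- function(map) {
  if (is.null(names(map)) || anyDuplicated(names(map)))
    stop_psival("comorbidity map names must be unique and non-empty")
  map <- lapply(map, normalize_codes)
  if (any(!lengths(map)))
    stop_psival("every comorbidity must map to at least one code prefix")
  structure(map, class = "psival_comorbidity_map")
}

match_any_prefix <- function(code_list, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(code_list)))
  vapply(code_list, function(cs) {
    if (!length(cs)) return(FALSE)
    any(vapply(prefixes, function(p) any(startsWith(cs, p)), logical(1)))
  }, logical(1))
}

#' Derive comorbidity flags from secondary-diagnosis codes
#'
#' A flag is set iff any secondary-diagnosis code starts with one of the
#' mapped prefixes.  Codes are normalized (dots stripped, upper-cased)
#' before matching; the operation is idempotent.
#'
#' @param records data frame with a delimited code column.
#' @param map a [comorbidity_map()].
#' @param code_col name of the column holding `;`-delimited codes.
#' @return `records` with one 0/1 column per comorbidity.
#' @export
map_comorbidities <- function(records, map, code_col = "secondary_dx") {
  if (!code_col %in% names(records))
    stop_psival("input error: missing code column '", code_col, "'")
  codes <- split_codes(as.character(records[[code_col]]))
  for (nm in names(map))
    records[[nm]] <- as.integer(match_any_prefix(codes, map[[nm]]))
  records
}

new_cohort <- function(psi, records, hospitals) {
  structure(list(psi = psi$name,
                 quasi_sentinel = psi$is_quasi_sentinel,
                 records = records, hospitals = hospitals),
            class = "psival_cohort")
}

#' @export
print.psival_cohort <- function(x, ...) {
  cat("PSI cohort '", x$psi, "': ", nrow(x$records), " eligible discharges, ",
      nrow(x$hospitals), " hospitals, ", sum(x$records$event), " events",
      if (x$quasi_sentinel) " (quasi-sentinel)", "\n", sep = "")
  invisible(x)
}

#' Build a per-indicator analysis cohort
#'
#' Eligibility: the record matches a denominator-inclusion prefix and no
#' exclusion prefix (exclusion takes precedence).  Event: eligible and
#' matching a numerator prefix.  When the indicator carries no code sets,
#' precomputed `eligible_<name>` / `event_<name>` columns are used instead
#' (the synthetic-data round trip).
#'
#' @param records discharge records (one row per discharge).
#' @param psi a [psi_definition()].
#' @param hospital_attrs optional data frame of hospital attributes
#'   (`hospital_id`, `beds`, `teaching`) merged into the cohort's hospital
#'   table; taken from `records` columns of those names when present.
#' @param code_col column with the record's `;`-delimited codes (used only
#'   on the code-driven route).
#' @return object of class `psival_cohort` with eligible `records`
#'   (carrying a logical `event` column) and a per-hospital table
#'   (`hospital_id`, `n_eligible`, `y_obs`, attributes when available).
#' @export
build_cohort <- function(records, psi, hospital_attrs = NULL,
                         code_col = "codes") {
  stopifnot(inherits(psi, "psival_psi"))
  if (!"hospital_id" %in% names(records))
    stop_psival("records must carry hospital_id")
  if (!is.null(psi$denominator_inclusion_codes)) {
    codes <- split_codes(as.character(records[[code_col]] %||%
      stop_psival("input error: missing code column '", code_col, "'")))
    eligible <- match_any_prefix(codes, psi$denominator_inclusion_codes) &
      !match_any_prefix(codes, psi$denominator_exclusion_codes)
    event <- eligible & match_any_prefix(codes, psi$numerator_codes)
  } else {
    ecol <- paste0("eligible_", psi$name)
    vcol <- paste0("event_", psi$name)
    if (!all(c(ecol, vcol) %in% names(records)))
      stop_psival("records lack ", ecol, "/", vcol,
                  " columns and the indicator defines no code sets")
    eligible <- as.logical(records[[ecol]])
    event <- as.logical(records[[vcol]])
  }
  if (!any(eligible)) stop_psival("cohort error: empty denominator")
  rec <- records[eligible, , drop = FALSE]
  rec$event <- event[eligible]
  rownames(rec) <- NULL
  n_by <- table(rec$hospital_id)
  y_by <- tapply(rec$event, rec$hospital_id, sum)
  hosp <- data.frame(hospital_id = names(n_by),
                     n_eligible = as.integer(n_by),
                     y_obs = as.integer(y_by[names(n_by)]),
                     stringsAsFactors = FALSE)
  if (is.null(hospital_attrs) &&
      all(c("beds", "teaching") %in% names(records))) {
    hospital_attrs <- unique(records[c("hospital_id", "beds", "teaching")])
  }
  if (!is.null(hospital_attrs)) {
    keep <- intersect(c("hospital_id", "beds", "teaching", "u_true"),
                      names(hospital_attrs))
    hosp <- merge(hosp, unique(hospital_attrs[keep]), by = "hospital_id",
                  all.x = TRUE, sort = TRUE)
  }
  hosp <- hosp[order(hosp$hospital_id), , drop = FALSE]
  rownames(hosp) <- NULL
  new_cohort(psi, rec, hosp)
}

#' Exclude low-volume hospitals
#'
#' Hospitals with fewer than `min_cases` eligible discharges are removed
#' together with their records; the exclusions are logged on the returned
#' cohort (see [hospital_exclusions()]).  Idempotent.
#'
#' @param cohort a `psival_cohort`.
#' @param min_cases minimum eligible cases (default 30: hospitals with
#'   *less than* 30 eligible cases are excluded).
#' @return the filtered cohort.
#' @export
apply_hospital_filter <- function(cohort, min_cases = 30) {
  stopifnot(inherits(cohort, "psival_cohort"), min_cases >= 1)
  drop <- cohort$hospitals$n_eligible < min_cases
  prior <- attr(cohort, "exclusions")
  if (any(drop)) {
    excl <- data.frame(hospital_id = cohort$hospitals$hospital_id[drop],
                       n_eligible = cohort$hospitals$n_eligible[drop],
                       reason = sprintf("fewer than %d eligible cases",
                                        min_cases),
                       stringsAsFactors = FALSE)
    keep_ids <- cohort$hospitals$hospital_id[!drop]
    if (!length(keep_ids))
      stop_psival("empty-cohort error: all hospitals removed by the ",
                  min_cases, "-case filter")
    cohort$hospitals <- cohort$hospitals[!drop, , drop = FALSE]
    cohort$records <- cohort$records[
      cohort$records$hospital_id %in% keep_ids, , drop = FALSE]
    rownames(cohort$hospitals) <- rownames(cohort$records) <- NULL
    attr(cohort, "exclusions") <- rbind(prior, excl)
  } else if (is.null(prior)) {
    attr(cohort, "exclusions") <- data.frame(hospital_id = character(),
                                             n_eligible = integer(),
                                             reason = character(),
                                             stringsAsFactors = FALSE)
  }
  cohort
}

#' Exclusion log of a cohort
#' @param cohort a `psival_cohort`.
#' @return data frame `(hospital_id, n_eligible, reason)`.
#' @export
hospital_exclusions <- function(cohort) {
  attr(cohort, "exclusions") %||%
    data.frame(hospital_id = character(), n_eligible = integer(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Add the coding-intensity covariate
#'
#' Dichotomizes the secondary-diagnosis count at a threshold; a record at
#' the threshold falls in the high-coding category (`>=`).  With
#' `threshold = "median"` the cohort median is used and recorded in the
#' attribute `coding_threshold`.
#'
#' @param cohort a `psival_cohort` whose records carry `n_secondary_dx`.
#' @param threshold a count, or `"median"`.
#' @return cohort with a 0/1 `high_coding` record column.
#' @export
coding_intensity_covariate <- function(cohort, threshold = "median") {
  stopifnot(inherits(cohort, "psival_cohort"))
  if (!"n_secondary_dx" %in% names(cohort$records))
    stop_psival("records lack n_secondary_dx")
  thr <- if (identical(threshold, "median"))
    stats::median(cohort$records$n_secondary_dx) else threshold
  cohort$records$high_coding <-
    as.integer(cohort$records$n_secondary_dx >= thr)
  attr(cohort, "coding_threshold") <- thr
  cohort
}

#' Restrict a cohort to the largest (teaching) hospitals
#'
#' Keeps hospitals with strictly more than `min_beds` beds and, by default,
#' teaching status; the homogeneous-providers sensitivity subset.
#'
#' @param cohort a `psival_cohort` whose hospital table carries `beds` and
#'   `teaching`.
#' @param min_beds strict lower bound on beds (default 450).
#' @param teaching_only restrict to teaching hospitals.
#' @return the restricted cohort.
#' @export
subset_largest <- function(cohort, min_beds = 450, teaching_only = TRUE) {
  stopifnot(inherits(cohort, "psival_cohort"))
  h <- cohort$hospitals
  if (!"beds" %in% names(h))
    stop_psival("hospital attributes (beds) absent from cohort")
  keep <- h$beds > min_beds
  if (teaching_only) {
    if (!"teaching" %in% names(h))
      stop_psival("hospital attributes (teaching) absent from cohort")
    keep <- keep & as.logical(h$teaching)
  }
  if (!any(keep))
    stop_psival("empty-cohort error: no hospital satisfies the subset rule")
  ids <- h$hospital_id[keep]
  cohort$hospitals <- h[keep, , drop = FALSE]
  cohort$records <- cohort$records[cohort$records$hospital_id %in% ids, ,
                                   drop = FALSE]
  rownames(cohort$hospitals) <- rownames(cohort$records) <- NULL
  cohort
}
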