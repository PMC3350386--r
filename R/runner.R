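# End-to-end orchestration: one configuration drives simulation, cohort
# preparation, risk adjustment, variation statistics, multilevel models
# and profiling, with every output regenerable from (config, seed).

#' Assemble a run configuration
#'
#' Defaults mirror the pipeline's stated constants: 30-case hospital
#' filter, 2,000 bootstrap resamples with 2.5/97.5 percentile intervals,
#' 5% type-1 error.
#'
#' @param generator a [generator_config()] for synthetic input, or `NULL`
#'   when `discharges_path` is given.
#' @param discharges_path,hospitals_path delimited-text inputs (used when
#'   `generator` is `NULL`).
#' @param psi_name indicator name (defaults to the generator's).
#' @param quasi_sentinel analysed on crude rates without patient-level
#'   adjustment?
#' @param candidates candidate comorbidity columns for screening
#'   (default: the generator's comorbidities, or all 0/1 flag columns).
#' @param min_cases hospital filter threshold (default 30).
#' @param bootstrap_reps bootstrap resamples (default 2000).
#' @param alpha type-1 error (default 0.05).
#' @param or_threshold screening threshold (default 2).
#' @param method,n_quad multilevel estimation method and nodes.
#' @param largest_only,coding_intensity sensitivity-variant switches.
#' @param min_beds,teaching_only rules for the largest-hospitals subset.
#' @param zero_policy zero-rate policy for the percentile ratios.
#' @param seed integer seed for the whole run.
#' @param out_dir output directory.
#' @return object of class `psival_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       discharges_path = NULL, hospitals_path = NULL,
                       psi_name = NULL, quasi_sentinel = NULL,
                       candidates = NULL,
                       min_cases = 30, bootstrap_reps = 2000, alpha = 0.05,
                       or_threshold = 2, method = "laplace", n_quad = 9,
                       largest_only = FALSE, coding_intensity = FALSE,
                       min_beds = 450, teaching_only = TRUE,
                       zero_policy = "error",
                       seed = 1L, out_dir = "psival-run") {
  psi_name <- psi_name %||% (if (!is.null(generator)) generator$psi_name
                             else stop_psival("psi_name required"))
  structure(list(generator = generator,
                 discharges_path = discharges_path,
                 hospitals_path = hospitals_path,
                 psi_name = tolower(psi_name),
                 quasi_sentinel = quasi_sentinel %||%
                   identical(tolower(psi_name), "mlm"),
                 candidates = candidates,
                 min_cases = min_cases, bootstrap_reps = bootstrap_reps,
                 alpha = alpha, or_threshold = or_threshold,
                 method = method, n_quad = n_quad,
                 largest_only = largest_only,
                 coding_intensity = coding_intensity,
                 min_beds = min_beds, teaching_only = teaching_only,
                 zero_policy = zero_policy,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "psival_run_config")
}

#' Read a run configuration from a JSON file
#'
#' The file may carry any [run_config()] field; a `generator` object is
#' interpreted as [generator_config()] arguments.
#'
#' @param path JSON file.
#' @return a `psival_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$generator)) {
    gargs <- raw$generator
    if (!is.null(gargs$beta)) gargs$beta <- as.list(gargs$beta)
    if (!is.null(gargs$comorbidity_prevalences))
      gargs$comorbidity_prevalences <- unlist(gargs$comorbidity_prevalences)
    raw$generator <- do.call(generator_config, gargs)
  }
  do.call(run_config, raw)
}

run_stage_order <- c("simulate", "prepare", "adjust", "variation",
                     "glmm", "profile")

#' Execute the analysis pipeline
#'
#' Runs simulate -> prepare -> adjust -> variation -> glmm -> profile and
#' writes, under `config$out_dir`: the discharge/hospital tables, the
#' exclusion report, the incidence-and-variation table (`table1.tsv`), the
#' model-sequence table (`table2.tsv`), dot-plot and caterpillar data, the
#' flag report, and a `manifest.json` (package version, seed, config,
#' md5 of every emitted file).  Rerunning the same config reproduces
#' byte-identical outputs.
#'
#' @param config a `psival_run_config`.
#' @param stages stages whose outputs should be written (prerequisites are
#'   always computed); default all.
#' @return the manifest, invisibly.
#' @export
run_analysis <- function(config, stages = run_stage_order) {
  stopifnot(inherits(config, "psival_run_config"))
  stages <- match.arg(stages, run_stage_order, several.ok = TRUE)
  last <- max(match(stages, run_stage_order))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name, stage) {
    if (stage %in% stages) {
      path <- file.path(config$out_dir, name)
      write_tsv(df, path)
      files <<- c(files, path)
    }
  }
  emit_json <- function(x, name, stage) {
    if (stage %in% stages) {
      path <- file.path(config$out_dir, name)
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      files <<- c(files, path)
    }
  }

  # -- simulate / load ------------------------------------------------
  if (!is.null(config$generator)) {
    gen <- config$generator
    gen$seed <- config$seed
    hospitals <- generate_hospitals(gen)
    discharges <- generate_discharges(hospitals, gen)
  } else {
    discharges <- read_discharges(config$discharges_path)
    hospitals <- if (!is.null(config$hospitals_path))
      read_hospitals(config$hospitals_path) else NULL
  }
  emit(discharges, "discharges.tsv", "simulate")
  if (!is.null(hospitals)) emit(hospitals, "hospitals.tsv", "simulate")

  # -- prepare --------------------------------------------------------
  psi <- psi_definition(config$psi_name,
                        is_quasi_sentinel = config$quasi_sentinel)
  cohort <- build_cohort(discharges, psi, hospital_attrs = hospitals)
  cohort <- apply_hospital_filter(cohort, config$min_cases)
  if (config$largest_only)
    cohort <- subset_largest(cohort, config$min_beds, config$teaching_only)
  if (config$coding_intensity)
    cohort <- coding_intensity_covariate(cohort, "median")
  emit(hospital_exclusions(cohort), "exclusions.tsv", "prepare")
  emit(cohort$hospitals, "cohort_hospitals.tsv", "prepare")
  if (last < match("adjust", run_stage_order))
    return(invisible(write_manifest(config, files)))

  # -- adjust ---------------------------------------------------------
  candidates <- config$candidates %||%
    (if (!is.null(config$generator)) comorbidity_names(config$generator)
     else setdiff(names(Filter(function(x)
       is.numeric(x) && all(x %in% 0:1), cohort$records)),
       c("n_secondary_dx", "high_coding")))
  if (config$quasi_sentinel) {
    screened <- character()
    summ <- data.frame(hospital_id = cohort$hospitals$hospital_id,
                       y_obs = cohort$hospitals$y_obs,
                       e_exp = cohort$hospitals$n_eligible *
                         sum(cohort$hospitals$y_obs) /
                         sum(cohort$hospitals$n_eligible),
                       n = cohort$hospitals$n_eligible,
                       stringsAsFactors = FALSE)
    summ$rate_crude <- 1000 * summ$y_obs / summ$n
    summ <- adjusted_incidence(summ, quasi_sentinel = TRUE)
    cstat <- NA_real_
  } else {
    screened <- screen_comorbidities(cohort, candidates,
                                     config$or_threshold)
    fitlog <- fit_logistic(cohort, screened)
    cstat <- c_statistic(fitlog)
    summ <- hospital_summaries(fitlog, cohort)
    summ <- adjusted_incidence(summ, quasi_sentinel = FALSE)
    emit(coef_table(fitlog), "risk_model_coefficients.tsv", "adjust")
  }
  emit(summ, "hospital_summaries.tsv", "adjust")
  if (last < match("variation", run_stage_order))
    return(invisible(write_manifest(config, files)))

  # -- variation ------------------------------------------------------
  vrep <- variation_report(summ, quasi_sentinel = config$quasi_sentinel,
                           reps = config$bootstrap_reps,
                           alpha = config$alpha,
                           seed = substream_seed(config$seed, "misc"),
                           zero_policy = config$zero_policy)
  table1 <- data.frame(
    psi = config$psi_name,
    cases = sum(summ$y_obs), patients_at_risk = sum(summ$n),
    pooled_rate_per_1000 = 1000 * sum(summ$y_obs) / sum(summ$n),
    p5 = unname(stats::quantile(summ$rate_adjusted, 0.05, type = 7)),
    p95 = unname(stats::quantile(summ$rate_adjusted, 0.95, type = 7)),
    c_statistic = cstat,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vrep$table))) {
    s <- vrep$table$statistic[i]
    table1[[s]] <- vrep$table$point[i]
    table1[[paste0(s, "_lo")]] <- vrep$table$lo[i]
    table1[[paste0(s, "_hi")]] <- vrep$table$hi[i]
  }
  emit(table1, "table1.tsv", "variation")
  emit(vrep$table, "variation_report.tsv", "variation")
  emit(centered_log_incidence(summ), "figure1_data.tsv", "variation")
  if (last < match("glmm", run_stage_order))
    return(invisible(write_manifest(config, files)))

  # -- glmm -----------------------------------------------------------
  covs <- if (config$coding_intensity) c(screened, "high_coding")
          else screened
  fits <- model_sequence(cohort, covs, method = config$method,
                         n_quad = config$n_quad)
  emit(model_table(fits), "table2.tsv", "glmm")
  if (last < match("profile", run_stage_order))
    return(invisible(write_manifest(config, files)))

  # -- profile --------------------------------------------------------
  final_fit <- fits[[length(fits)]]
  est <- shrunken_residuals(final_fit)
  flags <- flag_hospitals(est, config$alpha)
  emit(caterpillar_data(flags$estimates, config$alpha),
       "caterpillar.tsv", "profile")
  emit_json(flags$report, "flag_report.json", "profile")
  invisible(write_manifest(config, files,
                           extra = list(flag_report = flags$report)))
}

write_manifest <- function(config, files, extra = NULL) {
  cfg <- unclass(config)
  cfg$generator <- if (!is.null(cfg$generator)) unclass(cfg$generator)
  manifest <- c(list(package = "psival",
                     version = as.character(utils::packageVersion("psival")),
                     seed = config$seed,
                     config = cfg,
                     files = lapply(stats::setNames(nm = basename(files)),
                                    function(f) unname(tools::md5sum(
                                      file.path(config$out_dir, f))))),
                extra)
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
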