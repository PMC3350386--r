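#' Configuration for the synthetic discharge-data generator
#'
#' Describes a population of hospitals and patients from which discharge
#' records with a rare adverse event are simulated.  The event model is a
#' two-level logistic model: for patient i in hospital j,
#' \deqn{logit P(event) = \beta_0 + \beta_{age} age + \beta_{sex} female +
#'   \sum_c \beta_c flag_c + u_j,\qquad u_j \sim N(0, \sigma^2).}
#' Comorbidity flags are generated independently of each other (real
#' comorbidities co-occur; this simplification is deliberate and documented
#' in the methods vignette).  All randomness derives from `seed` through
#' fixed per-stream sub-seeds, so every generator is a pure function of
#' `(config, seed)`.
#'
#' Defaults emulate a decubitus-ulcer-like indicator in a national discharge
#' register: 175 hospitals with heavily skewed volumes, per-year age effect
#' 1.046 on the odds scale, comorbidity odds ratios between 1.87 and 5.16,
#' and hospital variance 0.38 on the log-odds scale.
#'
#' @param n_hospitals number of hospitals.
#' @param hospital_size_law list(mean, dispersion): eligible admissions per
#'   hospital drawn from a negative binomial with this mean and size
#'   (dispersion) parameter, floored at 1.
#' @param sigma2_hospital variance of the hospital random intercept
#'   (log-odds scale), `>= 0`.
#' @param beta named list of log-odds coefficients: `intercept`, `age`
#'   (per year), `sex` (female vs male), and one entry per comorbidity.
#' @param comorbidity_prevalences named vector of per-flag probabilities in
#'   (0,1); names must match the comorbidity entries of `beta`.
#' @param age_law list(mean, sd, min, max) in years (truncated normal).
#' @param prop_female probability a discharge is female.
#' @param beds_law list(meanlog, sdlog): hospital beds, lognormal.
#' @param coding_intensity_effect in `[0, 1)`: maximum hospital-specific
#'   under-recording of true comorbidity flags.  Each hospital records a
#'   true flag with probability `d_j ~ Uniform(1 - effect, 1)`; the mean of
#'   the secondary-diagnosis count scales with `d_j`.  True event risk is
#'   unaffected (recording artifact, not case-mix).
#' @param secondary_dx_law list(mu, size): negative-binomial law for the
#'   number of secondary diagnoses (defaults give median 4).
#' @param p_eligible probability a generated discharge is eligible for the
#'   indicator (default 1: the generator emits the at-risk cohort).
#' @param psi_name short lowercase indicator name used for the
#'   `eligible_<psi>` / `event_<psi>` columns.
#' @param seed integer global seed.
#' @return an object of class `psival_config`.
#' @export
generator_config <- function(n_hospitals = 175,
                             hospital_size_law = list(mean = 7000, dispersion = 0.5),
                             sigma2_hospital = 0.38,
                             beta = list(intercept = log(0.00018),
                                         age = log(1.046),
                                         sex = log(1.14),
                                         paralysis = log(5.05),
                                         other_neuro = log(3.74),
                                         diabetes_chronic = log(1.87),
                                         weight_loss = log(5.16),
                                         fluid_electrolyte = log(2.97)),
                             comorbidity_prevalences = c(paralysis = 0.015,
                                                         other_neuro = 0.025,
                                                         diabetes_chronic = 0.03,
                                                         weight_loss = 0.02,
                                                         fluid_electrolyte = 0.10),
                             age_law = list(mean = 65, sd = 18, min = 18, max = 100),
                             prop_female = 0.55,
                             beds_law = list(meanlog = log(220), sdlog = 0.7),
                             coding_intensity_effect = 0,
                             secondary_dx_law = list(mu = 5, size = 2),
                             p_eligible = 1,
                             psi_name = "du",
                             seed = 1L) {
  cfg <- list(n_hospitals = n_hospitals, hospital_size_law = hospital_size_law,
              sigma2_hospital = sigma2_hospital, beta = beta,
              comorbidity_prevalences = comorbidity_prevalences,
              age_law = age_law, prop_female = prop_female,
              beds_law = beds_law,
              coding_intensity_effect = coding_intensity_effect,
              secondary_dx_law = secondary_dx_law,
              p_eligible = p_eligible, psi_name = psi_name,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "psival_config")
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_hospitals) || cfg$n_hospitals < 1)
    stop_psival("configuration error: n_hospitals must be a positive integer")
  if (cfg$sigma2_hospital < 0)
    stop_psival("configuration error: sigma2_hospital must be >= 0")
  prev <- cfg$comorbidity_prevalences
  if (any(prev <= 0 | prev >= 1))
    stop_psival("configuration error: comorbidity prevalences must lie in (0,1)")
  base <- c("intercept", "age", "sex")
  comorb_beta <- setdiff(names(cfg$beta), base)
  unknown <- setdiff(comorb_beta, names(prev))
  if (length(unknown))
    stop_psival("configuration error: beta names not among comorbidity ",
                "prevalences: ", paste(unknown, collapse = ", "))
  if (!all(base %in% names(cfg$beta)))
    stop_psival("configuration error: beta must name intercept, age and sex")
  if (cfg$prop_female <= 0 || cfg$prop_female >= 1)
    stop_psival("configuration error: prop_female must lie in (0,1)")
  if (cfg$coding_intensity_effect < 0 || cfg$coding_intensity_effect >= 1)
    stop_psival("configuration error: coding_intensity_effect must lie in [0,1)")
  invisible(cfg)
}

#' Comorbidity names declared by a generator configuration
#' @param config a [generator_config()].
#' @return character vector of comorbidity flag names.
#' @export
comorbidity_names <- function(config) {
  setdiff(names(config$beta), c("intercept", "age", "sex"))
}

#' Simulate hospital profiles
#'
#' Draws hospital volumes, structural attributes and the latent random
#' effects `u_true` (i.i.d. Normal(0, `sigma2_hospital`)).  Deterministic
#' for a fixed config seed.
#'
#' @param config a [generator_config()].
#' @return data frame with columns `hospital_id`, `n_eligible`, `beds`,
#'   `teaching`, `u_true`, `record_prob` (comorbidity recording
#'   probability, 1 unless `coding_intensity_effect > 0`).
#' @export
generate_hospitals <- function(config) {
  validate_generator_config(config)
  J <- as.integer(config$n_hospitals)
  with_seed(substream_seed(config$seed, "hospitals"), {
    sizes <- pmax(1L, stats::rnbinom(J,
                                     size = config$hospital_size_law$dispersion,
                                     mu = config$hospital_size_law$mean))
    beds <- pmax(10L, as.integer(round(stats::rlnorm(
      J, config$beds_law$meanlog, config$beds_law$sdlog))))
    teaching <- stats::runif(J) < stats::plogis((beds - 450) / 100)
    u <- if (config$sigma2_hospital > 0)
      stats::rnorm(J, 0, sqrt(config$sigma2_hospital)) else numeric(J)
    d <- 1 - config$coding_intensity_effect * stats::runif(J)
    data.frame(hospital_id = sprintf("H%04d", seq_len(J)),
               n_eligible = sizes, beds = beds, teaching = teaching,
               u_true = u, record_prob = d,
               stringsAsFactors = FALSE)
  })
}

#' Simulate discharge records
#'
#' One row per discharge, with covariates, eligibility and event flags.
#' The event indicator is Bernoulli with probability
#' `plogis(beta . x + u_true)` computed from the TRUE comorbidity flags;
#' the emitted flag columns are the RECORDED flags (subject to the
#' coding-intensity under-recording), so analyses see what a register
#' would see.
#'
#' @param hospitals output of [generate_hospitals()].
#' @param config the same [generator_config()].
#' @return data frame of class-free discharge records: `hospital_id`,
#'   `age`, `sex` (`"female"`/`"male"`), one 0/1 column per comorbidity,
#'   `n_secondary_dx`, `eligible_<psi>`, `event_<psi>`.
#' @export
generate_discharges <- function(hospitals, config) {
  validate_generator_config(config)
  if (!NROW(hospitals)) stop_psival("hospitals must be nonempty")
  J <- nrow(hospitals)
  n_j <- hospitals$n_eligible
  N <- sum(n_j)
  comorbs <- comorbidity_names(config)
  with_seed(substream_seed(config$seed, "discharges"), {
    hidx <- rep.int(seq_len(J), n_j)
    al <- config$age_law
    age <- round(rtruncnorm(N, al$mean, al$sd, al$min, al$max))
    female <- stats::runif(N) < config$prop_female
    flags_true <- matrix(0L, N, length(comorbs),
                         dimnames = list(NULL, comorbs))
    for (cm in comorbs)
      flags_true[, cm] <- as.integer(
        stats::runif(N) < config$comorbidity_prevalences[[cm]])
    eta <- config$beta$intercept + config$beta$age * age +
      config$beta$sex * female + hospitals$u_true[hidx]
    for (cm in comorbs) eta <- eta + config$beta[[cm]] * flags_true[, cm]
    eligible <- if (config$p_eligible >= 1) rep(TRUE, N)
                else stats::runif(N) < config$p_eligible
    event <- eligible & (stats::runif(N) < stats::plogis(eta))
    # recording layer: flags and secondary-dx counts as coded, not as true
    d <- hospitals$record_prob[hidx]
    flags_rec <- flags_true
    if (config$coding_intensity_effect > 0) {
      keep <- matrix(stats::runif(N * length(comorbs)) < d, N)
      flags_rec <- flags_true * keep
      storage.mode(flags_rec) <- "integer"
    }
    sdx <- stats::rnbinom(N, size = config$secondary_dx_law$size,
                          mu = config$secondary_dx_law$mu * d)
    sdx <- pmax(sdx, rowSums(flags_rec))  # a recorded flag is a secondary dx
    out <- data.frame(hospital_id = hospitals$hospital_id[hidx],
                      age = age,
                      sex = ifelse(female, "female", "male"),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(flags_rec))
    out$n_secondary_dx <- sdx
    out[[paste0("eligible_", config$psi_name)]] <- eligible
    out[[paste0("event_", config$psi_name)]] <- event
    out
  })
}

#' Simulate hospital-level event counts under a Poisson-lognormal law
#'
#' For unit j with expected count `e_j`, the relative risk is
#' `r_j = exp(N(mu, sigma2))` and the observed count
#' `y_j ~ Poisson(e_j r_j)`.  This is the count-level view used by the
#' Empirical Bayes systematic-variation statistic; the ground truth
#' `(mu, sigma2)` is attached for recovery tests.
#'
#' @param n_units number of hospitals.
#' @param mu mean of the log relative risk.
#' @param sigma2 variance of the log relative risk, `>= 0`.
#' @param expected per-unit expected counts, all `> 0` (recycled).
#' @param seed integer seed.
#' @return data frame `(unit, y, e)` with attribute `truth = list(mu, sigma2)`.
#' @export
generate_hospital_counts <- function(n_units, mu = 0, sigma2 = 0,
                                     expected, seed = 1L) {
  if (sigma2 < 0) stop_psival("domain error: sigma2 must be >= 0")
  e <- rep_len(expected, n_units)
  if (any(e <= 0)) stop_psival("expected counts must all be > 0")
  with_seed(seed, {
    r <- exp(stats::rnorm(n_units, mu, sqrt(sigma2)))
    y <- stats::rpois(n_units, e * r)
    structure(data.frame(unit = sprintf("U%04d", seq_len(n_units)),
                         y = y, e = e, stringsAsFactors = FALSE),
              truth = list(mu = mu, sigma2 = sigma2))
  })
}

#' Calibrate the generator intercept to a target marginal event rate
#'
#' Solves for the intercept such that the Monte-Carlo average of
#' `plogis(intercept + s)` equals `target_rate`, where `s` collects the
#' sampled non-intercept linear predictor (age, sex, comorbidities and the
#' hospital effect).  The draw of `s` is deterministic given the config
#' seed, and the root is found by `uniroot`, so the result is reproducible.
#'
#' @param config a [generator_config()].
#' @param target_rate marginal event probability (e.g. `17.3 / 1000`).
#' @param n_mc Monte-Carlo sample size for the covariate draw.
#' @return the config with `beta$intercept` replaced.
#' @export
calibrate_intercept <- function(config, target_rate, n_mc = 200000) {
  stopifnot(target_rate > 0, target_rate < 1)
  comorbs <- comorbidity_names(config)
  s <- with_seed(substream_seed(config$seed, "calibrate"), {
    al <- config$age_law
    age <- round(rtruncnorm(n_mc, al$mean, al$sd, al$min, al$max))
    female <- stats::runif(n_mc) < config$prop_female
    acc <- config$beta$age * age + config$beta$sex * female
    for (cm in comorbs)
      acc <- acc + config$beta[[cm]] *
        (stats::runif(n_mc) < config$comorbidity_prevalences[[cm]])
    if (config$sigma2_hospital > 0)
      acc <- acc + stats::rnorm(n_mc, 0, sqrt(config$sigma2_hospital))
    acc
  })
  f <- function(b0) mean(stats::plogis(b0 + s)) - target_rate
  sol <- stats::uniroot(f, lower = -30, upper = 10, tol = 1e-10)
  config$beta$intercept <- sol$root
  config
}

#' Write / read discharge and hospital tables as delimited text
#'
#' Tab-separated with a header row; the standard external representation
#' used by the command-line pipeline.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path` (write) or a data frame (read), invisibly for writes.
#' @export
write_discharges <- function(x, path) write_tsv(x, path)

#' @rdname write_discharges
#' @export
read_discharges <- function(path) read_tsv(path)

#' @rdname write_discharges
#' @export
write_hospitals <- function(x, path) write_tsv(x, path)

#' @rdname write_discharges
#' @export
read_hospitals <- function(path) read_tsv(path)
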