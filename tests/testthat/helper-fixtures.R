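# Shared fixtures, built in code at test time.

# Small DU-like two-covariate world used by several suites.
small_config <- function(seed = 11, sigma2 = 0.3, n_hospitals = 60,
                         size_mean = 400) {
  generator_config(
    n_hospitals = n_hospitals,
    hospital_size_law = list(mean = size_mean, dispersion = 5),
    sigma2_hospital = sigma2, seed = seed,
    beta = list(intercept = log(0.01), age = log(1.03), sex = log(1.2),
                paralysis = log(4), fluid_electrolyte = log(2.5)),
    comorbidity_prevalences = c(paralysis = 0.03, fluid_electrolyte = 0.1))
}

small_cohort <- function(...) {
  cfg <- small_config(...)
  h <- generate_hospitals(cfg)
  d <- generate_discharges(h, cfg)
  build_cohort(d, psi_definition("du"), hospital_attrs = h)
}

# Hand-built cohort from explicit per-hospital (n, y) layouts; covariates
# are noise so intercept-only models apply.
counts_cohort <- function(n, y, ids = sprintf("H%02d", seq_along(n))) {
  stopifnot(length(n) == length(y), all(y <= n))
  rec <- do.call(rbind, lapply(seq_along(n), function(j) {
    data.frame(hospital_id = ids[j],
               age = 50, sex = rep(c("female", "male"), length.out = n[j]),
               event = rep(c(TRUE, FALSE), c(y[j], n[j] - y[j])),
               stringsAsFactors = FALSE)
  }))
  rec[[paste0("eligible_", "toy")]] <- TRUE
  rec[[paste0("event_", "toy")]] <- rec$event
  rec$event <- NULL
  build_cohort(rec, psi_definition("toy"))
}

# Independent c-statistic oracle: exhaustive pair enumeration.
c_stat_pairs <- function(score, y) {
  ev <- score[y == 1]; nv <- score[y == 0]
  tot <- 0
  for (a in ev) for (b in nv)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(nv))
}

# Independent percentile oracle (linear interpolation, type 7).
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, length(x))] - x[lo + 1])
}

# Exact per-hospital marginal likelihood of a random-intercept logistic
# model by adaptive numerical integration (independent of the package's
# quadrature code paths).
glmm_ll_exact <- function(cohort, fit) {
  covs <- fit$covariates
  rec <- cohort$records
  X <- cbind(1, vapply(covs, function(cv) {
    if (cv == "sex") as.numeric(rec$sex == "female")
    else if (cv == "age") rec$age
    else as.numeric(rec[[cv]])
  }, numeric(nrow(rec))))
  beta <- fit$coefficients[c("(Intercept)", covs)]
  xb <- drop(X %*% beta)
  y <- as.numeric(rec$event)
  s <- sqrt(fit$sigma2_hospital)
  sum(vapply(fit$hospital_ids, function(id) {
    i <- rec$hospital_id == id
    const <- sum(y[i] * xb[i] - log1p(exp(xb[i])))  # value at u = 0
    f <- Vectorize(function(u)
      exp(sum(y[i] * (xb[i] + u) - log1p(exp(xb[i] + u))) - const +
            stats::dnorm(u, 0, s, log = TRUE)))
    log(stats::integrate(f, -8 * s, 8 * s, rel.tol = 1e-12)$value) + const
  }, numeric(1)))
}
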