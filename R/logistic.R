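# Patient-level logistic risk adjustment: IRLS fit, covariate screening,
# discrimination, expected counts and indirectly standardized incidence.

# Design matrix from cohort records.  Age is centered at the cohort mean
# for numerical stability; coefficients are mapped back to the raw scale.
build_design <- function(records, covariates) {
  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n))
  age_center <- 0
  dropped <- character()
  for (cv in covariates) {
    x <- if (cv == "sex") {
      as.numeric(records$sex == "female")
    } else if (cv == "age") {
      age_center <- mean(records$age)
      records$age - age_center
    } else {
      if (!cv %in% names(records))
        stop_psival("covariate '", cv, "' absent from records")
      as.numeric(records[[cv]])
    }
    if (stats::var(x) < .Machine$double.eps) {
      warning("covariate '", cv, "' is constant and was dropped",
              call. = FALSE)
      dropped <- c(dropped, cv)
    } else cols[[cv]] <- x
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, age_center = age_center, dropped = dropped,
       covariates = setdiff(covariates, dropped))
}

# Plain IRLS for a Bernoulli GLM with logit link.  Convergence: relative
# change in log-likelihood < tol (default 1e-8) or maxit iterations.
irls_logistic <- function(X, y, tol = 1e-8, maxit = 100L) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  ll_old <- -Inf
  converged <- FALSE
  separated <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (anyNA(beta))
      stop_psival("design matrix is rank deficient; drop collinear covariates")
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1pexp(eta))
    if (max(abs(beta)) > 15) { separated <- TRUE; break }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = vcov,
       log_likelihood = sum(y * eta - log1pexp(eta)), fitted = mu,
       converged = converged && !separated, separated = separated,
       iterations = it)
}

#' Fit the patient-level logistic risk-adjustment model
#'
#' Maximum likelihood by iteratively reweighted least squares; convergence
#' when the relative log-likelihood change falls below `1e-8` (at most 100
#' iterations).  Perfect separation is detected by coefficient divergence
#' beyond 15 on the log-odds scale and reported via `converged = FALSE`
#' with `separated = TRUE`, never silently truncated.  Constant covariates
#' are dropped with a warning.
#'
#' @param cohort a `psival_cohort`.
#' @param covariates character vector among `"age"`, `"sex"` and flag
#'   column names; empty for the intercept-only model.
#' @return object of class `psival_logit`: `coefficients` (raw scale),
#'   `vcov`, `log_likelihood`, `converged`, `n_obs`, fitted probabilities
#'   and bookkeeping fields.
#' @export
fit_logistic <- function(cohort, covariates = character()) {
  stopifnot(inherits(cohort, "psival_cohort"))
  y <- as.numeric(cohort$records$event)
  if (sum(y) < 1 || sum(1 - y) < 1)
    stop_psival("need at least one event and one non-event")
  d <- build_design(cohort$records, covariates)
  fit <- irls_logistic(d$X, y)
  # un-center age: intercept_raw = intercept_c - center * beta_age
  A <- diag(ncol(d$X))
  dimnames(A) <- dimnames(fit$vcov)
  if ("age" %in% colnames(d$X))
    A["(Intercept)", "age"] <- -d$age_center
  structure(list(coefficients = drop(A %*% fit$coefficients)[colnames(d$X)] |>
                   stats::setNames(colnames(d$X)),
                 vcov = A %*% fit$vcov %*% t(A),
                 log_likelihood = fit$log_likelihood,
                 converged = fit$converged,
                 separated = fit$separated,
                 n_obs = length(y),
                 fitted = fit$fitted,
                 y = y,
                 hospital_id = cohort$records$hospital_id,
                 covariates = d$covariates,
                 dropped = d$dropped,
                 age_center = d$age_center),
            class = "psival_logit")
}

#' @export
print.psival_logit <- function(x, ...) {
  cat("Logistic risk-adjustment fit: n =", x$n_obs,
      "| logLik =", format(x$log_likelihood),
      "| converged:", x$converged, "\n")
  print(coef_table(x))
  invisible(x)
}

#' Coefficient table with odds ratios
#' @param fit a `psival_logit`.
#' @param level confidence level.
#' @return data frame `(term, estimate, se, or, or_lo, or_hi)`.
#' @export
coef_table <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(se),
             or = exp(unname(fit$coefficients)),
             or_lo = exp(unname(fit$coefficients - z * se)),
             or_hi = exp(unname(fit$coefficients + z * se)),
             stringsAsFactors = FALSE)
}

#' Screen candidate comorbidities by adjusted odds ratio
#'
#' Fits one model with the base covariates plus all candidates jointly and
#' keeps a candidate iff its adjusted odds ratio is at least `or_threshold`
#' (inclusive; massive administrative samples make almost any association
#' significant, so screening is on magnitude).  Base covariates are always
#' kept.
#'
#' @param cohort a `psival_cohort`.
#' @param candidates candidate flag column names.
#' @param or_threshold inclusive OR threshold (default 2).
#' @param base_covariates always-kept covariates (default age and sex).
#' @return character vector: base covariates followed by the selected
#'   candidates, with attribute `screening` (the full OR table).
#' @export
screen_comorbidities <- function(cohort, candidates, or_threshold = 2,
                                 base_covariates = c("age", "sex")) {
  stopifnot(length(candidates) >= 1)
  fit <- fit_logistic(cohort, c(base_covariates, candidates))
  tab <- coef_table(fit)
  tab <- tab[tab$term %in% candidates, , drop = FALSE]
  # inclusive boundary, robust to optimizer round-off at exactly OR = 2
  kept <- tab$term[tab$or >= or_threshold * (1 - 1e-9)]
  structure(c(intersect(base_covariates, c("age", "sex", fit$covariates)),
              kept),
            screening = tab)
}

#' Concordance (c) statistic of a fitted logistic model
#'
#' Probability that a randomly chosen event record receives a higher
#' fitted probability than a randomly chosen non-event record, ties
#' counted one half; computed exactly by the rank method.
#'
#' @param fit a `psival_logit`.
#' @return scalar in `[0, 1]`.
#' @export
c_statistic <- function(fit) {
  y <- fit$y
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop_psival("c statistic undefined without both events and non-events")
  r <- rank(fit$fitted)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-hospital observed and expected events
#'
#' Expected events are the sum of fitted probabilities over the hospital's
#' records; with an intercept in the model the IRLS score equations make
#' expected and observed totals agree.
#'
#' @param fit a converged `psival_logit`.
#' @param cohort the cohort the model was fitted on.
#' @return data frame `(hospital_id, y_obs, e_exp, n, rate_crude)` (crude
#'   rate per 1,000), ordered by hospital id.
#' @export
hospital_summaries <- function(fit, cohort) {
  if (!fit$converged)
    stop_psival("refusing to summarize a non-converged fit")
  ids <- cohort$hospitals$hospital_id
  if (!all(fit$hospital_id %in% ids))
    stop_psival("fit contains hospitals absent from the cohort")
  e <- tapply(fit$fitted, fit$hospital_id, sum)
  out <- data.frame(hospital_id = ids,
                    y_obs = cohort$hospitals$y_obs,
                    e_exp = as.numeric(e[ids]),
                    n = cohort$hospitals$n_eligible,
                    stringsAsFactors = FALSE)
  if (anyNA(out$e_exp))
    stop_psival("hospital absent from fit data: ",
                paste(ids[is.na(out$e_exp)], collapse = ", "))
  out$rate_crude <- 1000 * out$y_obs / out$n
  out
}

#' Indirectly standardized (adjusted) incidence per 1,000
#'
#' `rate_adjusted_j = 1000 * (y_j / e_j) * (sum(y) / sum(n))`: the
#' hospital's observed-to-expected ratio rescaled by the pooled crude
#' rate.  Quasi-sentinel indicators take the crude rate unchanged.
#'
#' @param summaries output of [hospital_summaries()] (needs `y_obs`,
#'   `e_exp`, `n`, `rate_crude`).
#' @param quasi_sentinel use crude rates (no adjustment)?
#' @param method only `"indirect"` is implemented.
#' @return `summaries` with a `rate_adjusted` column.
#' @export
adjusted_incidence <- function(summaries, quasi_sentinel = FALSE,
                               method = "indirect") {
  method <- match.arg(method, "indirect")
  if (quasi_sentinel) {
    summaries$rate_adjusted <- summaries$rate_crude
    return(summaries)
  }
  if (any(summaries$e_exp <= 0))
    stop_psival("expected count is zero for hospital(s): ",
                paste(summaries$hospital_id[summaries$e_exp <= 0],
                      collapse = ", "))
  pooled <- sum(summaries$y_obs) / sum(summaries$n)
  summaries$rate_adjusted <-
    1000 * (summaries$y_obs / summaries$e_exp) * pooled
  summaries
}
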