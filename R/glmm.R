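# Two-level random-intercept logistic regression by Laplace approximation
# (adaptive Gauss-Hermite as a cross-check), and the derived cluster
# metrics: latent-variable intraclass correlation (rho) and Median Odds
# Ratio (MOR).

# Inner problem: per-hospital posterior modes of u given (beta, sigma2).
# h_j(u) = sum_i [y_i eta_i - log(1 + e^eta_i)] - u^2 / (2 sigma2)
# Solved for all hospitals simultaneously by damped Newton; cost is linear
# in the number of records per iteration.
solve_modes <- function(xb, y, hidx, J, sigma2, u0 = numeric(J),
                        tol = 1e-10, maxit = 100L) {
  u <- u0
  for (it in seq_len(maxit)) {
    eta <- xb + u[hidx]
    p <- stats::plogis(eta)
    g <- group_sum(y - p, hidx, J) - u / sigma2
    h <- group_sum(p * (1 - p), hidx, J) + 1 / sigma2
    step <- g / h
    step <- pmax(pmin(step, 4), -4)
    u <- u + step
    if (max(abs(step)) < tol) break
  }
  eta <- xb + u[hidx]
  p <- stats::plogis(eta)
  S2 <- group_sum(p * (1 - p), hidx, J)
  ll_data <- group_sum(y * eta - log1pexp(eta), hidx, J)
  list(u = u, S2 = S2, h_at_mode = ll_data - u^2 / (2 * sigma2))
}

# Laplace log marginal likelihood given the solved modes.
laplace_loglik <- function(modes, sigma2) {
  sum(modes$h_at_mode) - 0.5 * sum(log(sigma2 * (modes$S2 + 1 / sigma2)))
}

# Adaptive Gauss-Hermite log marginal likelihood: nodes centered at the
# per-hospital mode with the posterior curvature scale.
agq_loglik <- function(xb, y, hidx, J, sigma2, modes, gh) {
  tau <- 1 / sqrt(modes$S2 + 1 / sigma2)
  K <- length(gh$nodes)
  hmat <- matrix(0, J, K)
  for (k in seq_len(K)) {
    uk <- modes$u + sqrt(2) * tau * gh$nodes[k]
    eta <- xb + uk[hidx]
    hmat[, k] <- group_sum(y * eta - log1pexp(eta), hidx, J) -
      uk^2 / (2 * sigma2)
  }
  lw <- sweep(hmat, 2, log(gh$weights) + gh$nodes^2, `+`)
  sum(lse_rows(lw) + 0.5 * log(2) + log(tau) - 0.5 * log(2 * pi * sigma2))
}

# Objective + analytic gradient for the marginal likelihood in theta =
# (beta, log sigma).  Gradient of the Laplace objective: envelope theorem
# for the profiled h_j(u*), plus the mode sensitivity du*/dtheta (implicit
# differentiation of the score equation) required by the log-determinant.
glmm_objective_env <- function(X, y, hidx, J, method, gh) {
  env <- new.env(parent = emptyenv())
  env$u <- numeric(J)
  p <- ncol(X)
  eval_at <- function(theta, want_hess = FALSE) {
    theta <- unname(theta)
    if (!want_hess && identical(theta, env$theta)) return(env$res)
    beta <- theta[seq_len(p)]
    sigma2 <- exp(2 * theta[p + 1])
    xb <- drop(X %*% beta)
    modes <- solve_modes(xb, y, hidx, J, sigma2, env$u)
    env$u <- modes$u
    ll <- if (method == "laplace") laplace_loglik(modes, sigma2)
          else agq_loglik(xb, y, hidx, J, sigma2, modes, gh)
    # gradient of the Laplace objective (for AGQ an accurate
    # quasi-gradient, the two surfaces being close)
    eta <- xb + modes$u[hidx]
    pr <- stats::plogis(eta)
    pq <- pr * (1 - pr)
    w3 <- pq * (1 - 2 * pr)                    # d(pq)/d(eta)
    denom <- modes$S2 + 1 / sigma2             # per-hospital curvature
    Tj <- group_sum(w3, hidx, J)               # dS2/du at the mode
    # per-hospital rowsums of pq * x and w3 * x (rows ordered 1..J)
    Bj <- rowsum(X * pq, hidx)
    Cj <- rowsum(X * w3, hidx)
    ord <- as.integer(rownames(Bj))
    Bj[ord, ] <- Bj; Cj[ord, ] <- Cj
    gbeta <- drop(crossprod(X, y - pr)) -
      0.5 * colSums((Cj - (Tj / denom) * Bj) / denom)
    u <- modes$u
    dF_ds2 <- sum(u^2) / (2 * sigma2^2) -
      0.5 * sum((modes$S2 + Tj * u / (sigma2 * denom)) / (sigma2 * denom))
    grad <- c(gbeta, 2 * sigma2 * dF_ds2)
    res <- list(value = -ll, grad = -grad)
    if (want_hess)
      # profile (marginal) curvature in beta: conditional information
      # minus the between-cluster correction from the mode movement
      res$hess_beta <- crossprod(X * sqrt(pq)) -
        crossprod(Bj / sqrt(denom))
    env$theta <- theta
    env$res <- res[c("value", "grad")]
    res
  }
  # maximize over beta at fixed log-sd by damped Newton with the exact
  # gradient and the profile Hessian; warm-started across calls
  env$beta <- NULL
  solve_beta <- function(ls, tol = 1e-7, maxit = 50L) {
    beta <- env$beta %||% numeric(p)
    for (it in seq_len(maxit)) {
      st <- eval_at(c(beta, ls), want_hess = TRUE)
      step <- tryCatch(solve(st$hess_beta, -st$grad[seq_len(p)]),
                       error = function(e) -st$grad[seq_len(p)] /
                         max(diag(st$hess_beta)))
      lam <- 1
      repeat {  # backtracking on the objective
        cand <- beta + lam * step
        if (eval_at(c(cand, ls))$value <= st$value + 1e-12 || lam < 1e-4)
          break
        lam <- lam / 2
      }
      beta <- beta + lam * step
      if (max(abs(lam * step)) < tol) break
    }
    env$beta <- beta
    list(beta = beta, value = eval_at(c(beta, ls))$value, iters = it)
  }
  list(eval_at = eval_at, solve_beta = solve_beta, env = env)
}

#' Fit a two-level random-intercept logistic model
#'
#' Patients nested in hospitals:
#' `logit P(event_ij) = x_ij' beta + u_j`, `u_j ~ N(0, sigma2)`.  The
#' marginal likelihood integrates the hospital effects out; it is
#' approximated by the Laplace method (default) or adaptive Gauss-Hermite
#' quadrature (`method = "agq"`, `n_quad` nodes centered and scaled at the
#' per-hospital posterior mode).  `sigma2 >= 0` via optimization of
#' `log(sigma)`; an optimum collapsing below `1e-8` is reported as
#' converged at the boundary `sigma2 = 0`.  Standard errors come from the
#' numerically differentiated Hessian at the optimum.  `sigma2_fixed = 0`
#' reduces the fit to the ordinary logistic model through the same code
#' path (used by tests and by quasi-sentinel sequences).
#'
#' @param cohort a `psival_cohort`.
#' @param covariates fixed-effect covariate names (may be empty: random
#'   intercept only).
#' @param method `"laplace"` or `"agq"`.
#' @param n_quad quadrature nodes for `"agq"`.
#' @param sigma2_fixed optional non-negative value at which to fix the
#'   hospital variance (no variance estimation).
#' @return object of class `psival_glmm` with `fixed_effects` (table),
#'   `coefficients`, `sigma2_hospital`, `sigma2_se`, `logsd_se`,
#'   `log_likelihood`, `converged`, `boundary`, per-hospital posterior
#'   modes `u_hat` and curvature pieces used by [shrunken_residuals()].
#' @export
fit_random_intercept_logistic <- function(cohort, covariates = character(),
                                          method = c("laplace", "agq"),
                                          n_quad = 9, sigma2_fixed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "psival_cohort"))
  ids <- sort(unique(cohort$records$hospital_id))
  J <- length(ids)
  if (J < 2 && is.null(sigma2_fixed))
    stop_psival("need at least 2 hospitals")
  y <- as.numeric(cohort$records$event)
  hosp_events <- tapply(y, cohort$records$hospital_id, sum)
  if (is.null(sigma2_fixed) && sum(hosp_events > 0) < 2)
    stop_psival("events present in fewer than 2 hospitals")
  d <- build_design(cohort$records, covariates)
  X <- d$X
  hidx <- match(cohort$records$hospital_id, ids)
  gh <- gauss_hermite(n_quad)

  # start at the ordinary logistic solution
  init <- irls_logistic(X, y)
  if (init$separated) {
    worst <- names(init$coefficients)[which.max(abs(init$coefficients))]
    stop_psival("separation detected for covariate '", worst, "'")
  }

  if (!is.null(sigma2_fixed) && sigma2_fixed == 0) {
    fit <- init
    A0 <- diag(ncol(X))
    dimnames(A0) <- list(colnames(X), colnames(X))
    if ("age" %in% colnames(X)) A0["(Intercept)", "age"] <- -d$age_center
    res <- make_glmm_fit(stats::setNames(drop(A0 %*% fit$coefficients),
                                         colnames(X)),
                         A0 %*% fit$vcov %*% t(A0), 0, NA_real_, NA_real_,
                         fit$log_likelihood, method, n_quad,
                         fit$converged, boundary = TRUE,
                         u = numeric(J), S2 = group_sum(
                           fit$fitted * (1 - fit$fitted), hidx, J),
                         ids = ids, d = d, n_obs = length(y),
                         cohort = cohort, hidx = hidx, X = X, y = y)
    return(res)
  }

  p <- ncol(X)
  fns <- glmm_objective_env(X, y, hidx, J, method, gh)
  fns$env$beta <- unname(init$coefficients)
  ls_lo <- log(sqrt(1e-8)); ls_hi <- log(sqrt(16))
  if (!is.null(sigma2_fixed)) {
    ls_fix <- log(sqrt(sigma2_fixed))
    sol <- fns$solve_beta(ls_fix)
    theta <- c(sol$beta, ls_fix)
    conv_outer <- TRUE
  } else {
    # profiled 1-D search over log-sd (fixed effects solved by Newton at
    # every evaluation, warm-started), then a safeguarded refinement
    profile_obj <- function(ls) fns$solve_beta(ls)$value
    opt <- stats::optimize(profile_obj, c(ls_lo, ls_hi), tol = 1e-7)
    ls_hat <- opt$minimum
    # boundary check: the profile can be monotone into the corner
    if (profile_obj(ls_lo) <= opt$objective + 1e-10) ls_hat <- ls_lo
    sol <- fns$solve_beta(ls_hat)
    theta <- c(sol$beta, ls_hat)
    conv_outer <- TRUE
  }
  theta <- unname(theta)
  beta <- theta[seq_len(p)]
  if (max(abs(beta)) > 15) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop_psival("separation detected for covariate '", worst, "'")
  }
  sigma2 <- exp(2 * theta[p + 1])
  boundary <- is.null(sigma2_fixed) && sigma2 <= 2e-8
  if (boundary) sigma2 <- max(sigma2, 1e-10)
  # converged: stationary fixed effects and (interior) small profile score
  grad_opt <- fns$eval_at(theta)$grad
  converged <- max(abs(grad_opt[seq_len(p)])) < 1e-2 &&
    (boundary || !is.null(sigma2_fixed) || abs(grad_opt[p + 1]) < 1)

  # curvature at the optimum (central differences of the analytic gradient)
  free <- if (is.null(sigma2_fixed)) seq_len(p + 1) else seq_len(p)
  H <- num_hessian_from_grad(function(th) fns$eval_at(th)$grad, theta, free)
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(free), length(free)))
  se_all <- rep(NA_real_, p + 1)
  se_all[free] <- sqrt(pmax(diag(V), 0))
  vcov_beta <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  bfree <- intersect(free, seq_len(p))
  vcov_beta[bfree, bfree] <- V[seq_along(bfree), seq_along(bfree)]
  logsd_se <- if (is.null(sigma2_fixed) && !boundary) se_all[p + 1]
              else NA_real_
  sigma2_se <- if (is.finite(logsd_se)) 2 * sigma2 * logsd_se else NA_real_

  # final modes at the optimum
  xb <- drop(X %*% beta)
  modes <- solve_modes(xb, y, hidx, J, sigma2)
  ll <- if (method == "laplace") laplace_loglik(modes, sigma2)
        else agq_loglik(xb, y, hidx, J, sigma2, modes, gh)

  # un-center age
  A <- diag(p)
  dimnames(A) <- list(colnames(X), colnames(X))
  if ("age" %in% colnames(X)) A["(Intercept)", "age"] <- -d$age_center
  beta_raw <- stats::setNames(drop(A %*% beta), colnames(X))
  vcov_raw <- A %*% vcov_beta %*% t(A)

  make_glmm_fit(beta_raw, vcov_raw, if (boundary) 0 else sigma2,
                sigma2_se, logsd_se, ll, method, n_quad,
                converged = converged,
                boundary = boundary, u = modes$u, S2 = modes$S2,
                ids = ids, d = d, n_obs = length(y), cohort = cohort,
                hidx = hidx, X = X, y = y)
}

make_glmm_fit <- function(beta, vcov_beta, sigma2, sigma2_se, logsd_se, ll,
                          method, n_quad, converged, boundary, u, S2, ids,
                          d, n_obs, cohort, hidx, X, y) {
  se <- sqrt(pmax(diag(vcov_beta), 0))
  fe <- data.frame(term = names(beta), estimate = unname(beta),
                   se = unname(se), or = exp(unname(beta)),
                   stringsAsFactors = FALSE)
  structure(list(fixed_effects = fe, coefficients = beta,
                 vcov = vcov_beta,
                 sigma2_hospital = sigma2, sigma2_se = sigma2_se,
                 logsd_se = logsd_se,
                 log_likelihood = ll, method = method, n_quad = n_quad,
                 converged = converged, boundary = boundary,
                 u_hat = u, S2 = S2, hospital_ids = ids,
                 covariates = d$covariates, dropped = d$dropped,
                 age_center = d$age_center, n_obs = n_obs,
                 n_hospitals = length(ids)),
            class = "psival_glmm")
}

#' @export
print.psival_glmm <- function(x, ...) {
  cat("Random-intercept logistic fit (", x$method, "): ",
      x$n_obs, " records in ", x$n_hospitals, " hospitals\n", sep = "")
  cat("  sigma2 =", format(x$sigma2_hospital, digits = 4),
      if (is.finite(x$sigma2_se)) paste0("(SE ", format(x$sigma2_se,
                                                        digits = 3), ")"),
      "| rho =", format(rho_icc(x$sigma2_hospital), digits = 3),
      "| MOR =", format(median_odds_ratio(x$sigma2_hospital), digits = 3),
      "\n")
  print(x$fixed_effects, row.names = FALSE)
  invisible(x)
}

# Central-difference Hessian from an analytic gradient, restricted to the
# free coordinates and symmetrized.
num_hessian_from_grad <- function(gr, x, free = seq_along(x), h = 1e-5) {
  k <- length(free)
  H <- matrix(0, k, k)
  step <- pmax(abs(x[free]), 1) * h
  for (a in seq_len(k)) {
    e <- numeric(length(x))
    e[free[a]] <- step[a]
    H[a, ] <- (gr(x + e)[free] - gr(x - e)[free]) / (2 * step[a])
  }
  (H + t(H)) / 2
}

#' Nested model sequence for one indicator
#'
#' Model 1: hospital random intercept only; model 2 adds age and sex;
#' model 3 adds the screened comorbidities.  A quasi-sentinel indicator is
#' fitted with model 1 only (no patient-level adjustment).
#'
#' @param cohort a `psival_cohort`.
#' @param screened_covariates output of [screen_comorbidities()] (ignored
#'   for quasi-sentinel cohorts).
#' @param method,n_quad passed to [fit_random_intercept_logistic()].
#' @return named list of `psival_glmm` fits (`model1`, and for
#'   non-quasi-sentinel indicators `model2`, `model3`), class
#'   `psival_model_sequence`.
#' @export
model_sequence <- function(cohort, screened_covariates = c("age", "sex"),
                           method = "laplace", n_quad = 9) {
  fits <- list(model1 = fit_random_intercept_logistic(
    cohort, character(), method = method, n_quad = n_quad))
  if (!cohort$quasi_sentinel) {
    base <- intersect(c("age", "sex"), screened_covariates)
    if (!length(base)) base <- c("age", "sex")
    fits$model2 <- fit_random_intercept_logistic(
      cohort, base, method = method, n_quad = n_quad)
    fits$model3 <- fit_random_intercept_logistic(
      cohort, union(base, screened_covariates), method = method,
      n_quad = n_quad)
  }
  structure(fits, class = "psival_model_sequence")
}

#' Export a model sequence as a side-by-side table
#'
#' One row per quantity (constant and covariate odds ratios, hospital
#' variance, rho, MOR), one column per model.
#'
#' @param fits a `psival_model_sequence`.
#' @param level confidence level for the cluster-metric intervals.
#' @return data frame.
#' @export
model_table <- function(fits, level = 0.95) {
  stopifnot(inherits(fits, "psival_model_sequence"))
  terms <- unique(unlist(lapply(fits, function(f) f$fixed_effects$term)))
  fmt <- function(x) formatC(x, digits = 3, format = "g")
  rows <- lapply(terms, function(tm) {
    vals <- vapply(fits, function(f) {
      i <- match(tm, f$fixed_effects$term)
      if (is.na(i)) "" else {
        z <- stats::qnorm(1 - (1 - level) / 2)
        est <- f$fixed_effects$estimate[i]; se <- f$fixed_effects$se[i]
        sprintf("%s (%s to %s)", fmt(exp(est)),
                fmt(exp(est - z * se)), fmt(exp(est + z * se)))
      }
    }, character(1))
    c(quantity = if (tm == "(Intercept)") "Constant (OR)" else
        paste0(tm, " (OR)"), vals)
  })
  metr <- lapply(c("sigma2", "rho", "mor"), function(m) {
    vals <- vapply(fits, function(f) {
      ci <- tryCatch(suppressWarnings(cluster_metric_ci(f, m,
                                                        level = level)),
                     error = function(e) c(NA_real_, NA_real_))
      pt <- switch(m, sigma2 = f$sigma2_hospital,
                   rho = rho_icc(f$sigma2_hospital),
                   mor = median_odds_ratio(f$sigma2_hospital))
      if (all(is.finite(ci)))
        sprintf("%s (%s to %s)", fmt(pt), fmt(ci[1]), fmt(ci[2]))
      else fmt(pt)
    }, character(1))
    c(quantity = switch(m, sigma2 = "Hospital-level variance",
                        rho = "Rho", mor = "MOR"), vals)
  })
  out <- as.data.frame(do.call(rbind, c(rows, metr)),
                       stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Latent-variable intraclass correlation (rho)
#'
#' Share of latent outcome variance attributable to hospitals in a
#' logistic random-intercept model: `sigma2 / (sigma2 + pi^2/3)`, the
#' individual-level error following the standard logistic distribution
#' with variance `pi^2/3`.
#'
#' @param sigma2 hospital-level variance, `>= 0` (vectorized).
#' @return rho in `[0, 1)`.
#' @export
rho_icc <- function(sigma2) {
  if (any(sigma2 < 0)) stop_psival("domain error: sigma2 must be >= 0")
  sigma2 / (sigma2 + pi^2 / 3)
}

#' Median Odds Ratio (MOR)
#'
#' Median of the odds ratio between the higher- and lower-risk hospital
#' when two patients with identical covariates are drawn from two randomly
#' chosen hospitals: `exp(sqrt(2 sigma2) * qnorm(0.75))`.  Equals 1 when
#' there is no between-hospital variance.
#'
#' @param sigma2 hospital-level variance, `>= 0` (vectorized).
#' @return MOR `>= 1`.
#' @export
median_odds_ratio <- function(sigma2) {
  if (any(sigma2 < 0)) stop_psival("domain error: sigma2 must be >= 0")
  exp(sqrt(2 * sigma2) * stats::qnorm(0.75))
}

#' Invert the cluster metrics back to the variance scale
#' @param rho,mor metric values on their natural ranges.
#' @return the hospital-level variance.
#' @export
sigma2_from_rho <- function(rho) {
  if (any(rho < 0 | rho >= 1)) stop_psival("rho must lie in [0, 1)")
  pi^2 / 3 * rho / (1 - rho)
}

#' @rdname sigma2_from_rho
#' @export
sigma2_from_mor <- function(mor) {
  if (any(mor < 1)) stop_psival("MOR must be >= 1")
  (log(mor) / stats::qnorm(0.75))^2 / 2
}

#' Confidence interval for a cluster metric
#'
#' Wald interval for `log(sigma2)` using the fitted curvature, transformed
#' through the metric's strictly monotone map, so the interval endpoints
#' of rho and MOR are the metric applied to the variance endpoints.
#' Boundary fits (`sigma2 = 0`) return a one-sided interval anchored at
#' the null value with a warning.
#'
#' @param fit a `psival_glmm`.
#' @param metric `"sigma2"`, `"rho"` or `"mor"`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lo, hi)`.
#' @export
cluster_metric_ci <- function(fit, metric = c("sigma2", "rho", "mor"),
                              level = 0.95) {
  metric <- match.arg(metric)
  map <- switch(metric, sigma2 = identity, rho = rho_icc,
                mor = median_odds_ratio)
  if (fit$boundary || fit$sigma2_hospital <= 0) {
    warning("variance at the boundary; interval is one-sided",
            call. = FALSE)
    return(c(map(0), map(0)))
  }
  if (!is.finite(fit$logsd_se))
    stop_psival("fit carries no finite SE for the variance")
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_log_sigma2 <- 2 * fit$logsd_se
  lo <- fit$sigma2_hospital * exp(-z * se_log_sigma2)
  hi <- fit$sigma2_hospital * exp(z * se_log_sigma2)
  c(map(lo), map(hi))
}
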