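# Between-hospital systematic variation: percentile ratios of variation,
# the Empirical Bayes statistic from a hierarchical Poisson-lognormal
# model, and nonparametric cluster-bootstrap percentile intervals.

#' Percentile ratio of variation
#'
#' Ratio of the `hi`-th to the `lo`-th percentile of per-hospital rates,
#' with linear-interpolation percentiles (`stats::quantile` type 7).  A
#' zero low percentile is an error by default because the ratio is then
#' undefined; `zero_policy = "truncate"` substitutes the smallest nonzero
#' rate for the low percentile instead.
#'
#' @param rates per-hospital non-negative rates.
#' @param hi,lo percentiles in (0, 100), `hi > lo`.
#' @param zero_policy `"error"` or `"truncate"`.
#' @return scalar ratio `>= 1` for any rate vector.
#' @export
ratio_of_variation <- function(rates, hi = 95, lo = 5,
                               zero_policy = c("error", "truncate")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(hi > lo, lo > 0, hi < 100)
  q <- unname(stats::quantile(rates, c(lo, hi) / 100, type = 7))
  if (q[1] <= 0) {
    if (zero_policy == "error")
      stop_psival("low percentile is zero; set zero_policy = \"truncate\" ",
                  "to use the smallest nonzero rate instead")
    pos <- rates[rates > 0]
    if (!length(pos)) stop_psival("all rates are zero; ratio undefined")
    q[1] <- min(pos)
  }
  q[2] / q[1]
}

# Marginal log-likelihood of (mu, sigma) for counts y with offsets e under
# y_j | b_j ~ Poisson(e_j exp(b_j)), b_j ~ N(mu, sigma^2), by ADAPTIVE
# Gauss-Hermite quadrature: for large e_j the Poisson term is much
# narrower than the prior, so nodes are centered at each unit's posterior
# mode and scaled by the posterior curvature (plain prior-scaled nodes
# would straddle the peak and bias sigma2 toward 0).
pln_loglik <- function(mu, sigma, y, e, gh, b0 = NULL) {
  J <- length(y)
  s2 <- sigma^2
  # per-unit posterior mode of b: maximize y b - e exp(b) - (b-mu)^2/(2 s2)
  b <- b0 %||% log((y + 0.5) / e)
  for (it in 1:50) {
    lam <- e * exp(b)
    g <- y - lam - (b - mu) / s2
    h <- lam + 1 / s2
    step <- pmax(pmin(g / h, 3), -3)
    b <- b + step
    if (max(abs(step)) < 1e-11) break
  }
  tau <- 1 / sqrt(e * exp(b) + 1 / s2)
  K <- length(gh$nodes)
  bk <- b + (sqrt(2) * tau) %o% gh$nodes          # J x K
  lam <- e * exp(bk)
  lf <- y * (log(e) + bk) - lam - lgamma(y + 1) - # Poisson log density
    (bk - mu)^2 / (2 * s2) - log(sigma) - 0.5 * log(2 * pi) +
    rep(gh$nodes^2 + log(gh$weights), each = J)
  ls <- lse_rows(lf)
  lj <- ls + 0.5 * log(2) + log(tau)
  # score via posterior expectations under the quadrature weights:
  # d/dmu = E[(b - mu)]/s2, d/dlog(sigma) = E[(b - mu)^2]/s2 - 1 per unit
  w <- exp(lf - ls)
  dev <- bk - mu
  structure(sum(lj), modes = b,
            grad = c(sum(rowSums(w * dev)) / s2,
                     sum(rowSums(w * dev^2) / s2 - 1)))
}

#' Fit the hierarchical Poisson-lognormal model to hospital counts
#'
#' Maximizes the marginal likelihood of `(mu, sigma2)` where the observed
#' count of hospital j is `y_j | r_j ~ Poisson(e_j r_j)` and
#' `log r_j ~ N(mu, sigma2)`.  The integral over the log relative risk is
#' evaluated by Gauss-Hermite quadrature (default 30 nodes); `sigma2 >= 0`
#' is enforced by optimizing `log(sigma)` with boundary handling: when the
#' optimum collapses below `sigma2 = 1e-8` the Poisson (no-heterogeneity)
#' solution is reported with `boundary = TRUE`.  The fitted `sigma2` is
#' the Empirical Bayes systematic-variation statistic: 0 means the spread
#' of counts is compatible with Poisson noise alone.
#'
#' @param counts data frame with columns `y` (observed) and `e` (expected,
#'   all `> 0`); at least 5 units.
#' @param n_quad number of quadrature nodes.
#' @param start optional `c(mu, log_sigma)` starting values.
#' @return object of class `psival_pln`: `mu`, `sigma2`,
#'   `log_marginal_likelihood`, `n_quadrature`, `converged`, `boundary`.
#' @export
fit_poisson_lognormal <- function(counts, n_quad = 30, start = NULL) {
  y <- counts$y; e <- counts$e
  if (length(y) < 5) stop_psival("need at least 5 units")
  if (any(e <= 0)) stop_psival("all expected counts must be > 0")
  gh <- gauss_hermite(n_quad)
  if (all(y == 0)) {
    return(structure(list(mu = -Inf, sigma2 = 0,
                          log_marginal_likelihood = sum(stats::dpois(y, 0,
                                                                     log = TRUE)),
                          n_quadrature = n_quad, converged = TRUE,
                          boundary = TRUE),
                     class = "psival_pln"))
  }
  env <- new.env(parent = emptyenv())  # warm modes + memoized last eval
  eval_at <- function(th) {
    if (!identical(th, env$th)) {
      v <- pln_loglik(th[1], exp(th[2]), y, e, gh, b0 = env$b)
      env$b <- attr(v, "modes")
      env$th <- th
      env$v <- v
    }
    env$v
  }
  obj <- function(th) -as.numeric(eval_at(th))
  gr <- function(th) -attr(eval_at(th), "grad")
  mu0 <- log(sum(y) / sum(e))
  # method-of-moments start for sigma, floored away from the boundary
  s0 <- sqrt(max(stats::var(log((y + 0.5) / e)) - mean(1 / (y + 0.5)), 0.01))
  starts <- if (is.null(start)) list(c(mu0, log(s0))) else list(start)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(stats::nlminb(st, obj, gr,
                                  lower = c(-30, log(1e-5)),
                                  upper = c(10, log(10)),
                                  control = list(iter.max = 500, eval.max = 2000,
                                                 rel.tol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop_psival("Poisson-lognormal fit failed to converge; check counts")
  sigma2 <- exp(2 * best$par[2])
  boundary <- sigma2 < 1e-8
  if (boundary) sigma2 <- 0
  structure(list(mu = best$par[1], sigma2 = sigma2,
                 log_marginal_likelihood = -best$objective,
                 n_quadrature = n_quad,
                 converged = best$convergence == 0 || boundary,
                 boundary = boundary),
            class = "psival_pln")
}

#' @export
print.psival_pln <- function(x, ...) {
  cat("Poisson-lognormal fit: mu =", format(x$mu, digits = 4),
      "| sigma2 (EB) =", format(x$sigma2, digits = 4),
      "| logLik =", format(x$log_marginal_likelihood),
      if (x$boundary) "| at boundary sigma2 = 0", "\n")
  invisible(x)
}

#' Cluster-bootstrap percentile confidence interval
#'
#' Resamples the units (hospitals) with replacement, recomputes the
#' statistic on each resample, and returns the empirical 2.5 / 97.5
#' percentiles (for `alpha = 0.05`).  Resamples on which the statistic is
#' undefined (error or `NA`) are redrawn and counted; more than 10%
#' undefined draws is an error.
#'
#' @param statistic function taking a resampled unit table (or vector) and
#'   returning a scalar.
#' @param units data frame (rows = hospitals) or vector to resample.
#' @param reps number of bootstrap resamples (default 2000).
#' @param alpha two-sided type-1 error (default 0.05).
#' @param seed integer seed; the interval is reproducible given it.
#' @return list `(lo, hi, reps, n_undefined, stats)`.
#' @export
bootstrap_percentile_ci <- function(statistic, units, reps = 2000,
                                    alpha = 0.05, seed = 1L) {
  n <- NROW(units)
  if (n < 2) stop_psival("need at least 2 units to bootstrap")
  take <- function(idx) if (is.data.frame(units))
    units[idx, , drop = FALSE] else units[idx]
  with_seed(substream_seed(seed, "bootstrap"), {
    out <- numeric(reps)
    bad <- 0L
    max_bad <- ceiling(0.1 * reps)
    for (r in seq_len(reps)) {
      repeat {
        v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NA_real_)
        if (length(v) == 1 && is.finite(v)) break
        bad <- bad + 1L
        if (bad > max_bad)
          stop_psival("more than 10% of bootstrap resamples left the ",
                      "statistic undefined")
      }
      out[r] <- v
    }
    q <- unname(stats::quantile(out, c(alpha / 2, 1 - alpha / 2), type = 7))
    list(lo = q[1], hi = q[2], reps = reps, n_undefined = bad, stats = out)
  })
}

#' Systematic-variation report for one indicator
#'
#' Computes RV95-5 and RV75-25 on the adjusted rates (crude rates for a
#' quasi-sentinel indicator) and the Empirical Bayes statistic on the
#' observed/expected counts, each with a cluster-bootstrap percentile
#' interval (hospitals resampled with replacement).
#'
#' @param summaries output of [adjusted_incidence()]: columns `y_obs`,
#'   `e_exp`, `n`, `rate_adjusted`.
#' @param quasi_sentinel rate basis is crude, and EB uses `n`-proportional
#'   expected counts (no risk model).
#' @param reps bootstrap resamples (default 2000).
#' @param alpha two-sided level (default 0.05).
#' @param seed integer seed.
#' @param n_quad quadrature nodes for the Poisson-lognormal fits.
#' @param zero_policy passed to [ratio_of_variation()].
#' @return object of class `psival_variation`: data frame `table` with one
#'   row per statistic `(statistic, point, lo, hi)` plus `n_hospitals`,
#'   `bootstrap_reps`, `seed`.
#' @export
variation_report <- function(summaries, quasi_sentinel = FALSE, reps = 2000,
                             alpha = 0.05, seed = 1L, n_quad = 30,
                             zero_policy = c("error", "truncate")) {
  zero_policy <- match.arg(zero_policy)
  if (nrow(summaries) < 5) stop_psival("need at least 5 hospitals")
  if (quasi_sentinel) {
    # no risk model for a quasi-sentinel event: expected counts are
    # volume-proportional (pooled rate times denominator)
    summaries$e_exp <- summaries$n * sum(summaries$y_obs) / sum(summaries$n)
    summaries$rate_adjusted <- summaries$rate_crude
  }
  rates <- summaries$rate_adjusted
  stat_rv <- function(hi, lo) {
    function(s) ratio_of_variation(s$rate_adjusted, hi, lo,
                                   zero_policy = zero_policy)
  }
  stat_eb <- function(s) fit_poisson_lognormal(
    data.frame(y = s$y_obs, e = s$e_exp), n_quad = n_quad)$sigma2
  point <- c(rv_95_5 = ratio_of_variation(rates, 95, 5, zero_policy),
             rv_75_25 = ratio_of_variation(rates, 75, 25, zero_policy),
             eb = stat_eb(summaries))
  cis <- list(
    rv_95_5 = bootstrap_percentile_ci(stat_rv(95, 5), summaries, reps,
                                      alpha, seed),
    rv_75_25 = bootstrap_percentile_ci(stat_rv(75, 25), summaries, reps,
                                       alpha, seed + 1L),
    eb = bootstrap_percentile_ci(stat_eb, summaries, reps, alpha,
                                 seed + 2L))
  tab <- data.frame(statistic = names(point),
                    point = unname(point),
                    lo = vapply(cis, `[[`, 0, "lo"),
                    hi = vapply(cis, `[[`, 0, "hi"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, n_hospitals = nrow(summaries),
                 bootstrap_reps = reps, alpha = alpha, seed = seed),
            class = "psival_variation")
}

#' @export
print.psival_variation <- function(x, ...) {
  cat("Variation report over", x$n_hospitals, "hospitals (",
      x$bootstrap_reps, "bootstrap resamples):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Mean-centred log incidence (dot-plot data)
#'
#' Per-hospital `log(rate) - mean(log(rate))`, the scale on which
#' indicators with different baseline incidence can be compared visually.
#' Hospitals with zero rate carry `NA` (with a warning) since the log is
#' undefined.
#'
#' @param summaries output of [adjusted_incidence()].
#' @return data frame `(hospital_id, centred_log_rate)`.
#' @export
centered_log_incidence <- function(summaries) {
  r <- summaries$rate_adjusted
  lr <- ifelse(r > 0, log(r), NA_real_)
  if (anyNA(lr))
    warning("zero adjusted rates dropped from centred-log incidence",
            call. = FALSE)
  data.frame(hospital_id = summaries$hospital_id,
             centred_log_rate = lr - mean(lr, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
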