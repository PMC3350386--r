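# Hospital profiling from the multilevel fit: empirical-Bayes shrunken
# residuals, outlier flagging against the population-average prediction,
# caterpillar plot data and sensitivity-variant comparison.

#' Shrunken residuals of the hospital random effects
#'
#' For each hospital, the mode of the conditional posterior of its random
#' effect given the data and the fitted parameters, with the comparative
#' standard error from the curvature at the mode
#' (`1 / sqrt(S2_j + 1/sigma2)`).  The residual is the hospital's
#' deviation, on the log-odds scale, from the population-average ("expected")
#' prediction; shrinkage pulls low-information hospitals toward 0, which
#' disentangles true hospital variation from noise.
#'
#' @param fit a converged `psival_glmm`.
#' @return data frame of class `psival_ranef`: `hospital_id`, `u_hat`,
#'   `se_comp`, `rank` (ascending in `u_hat`), `flag` (`"none"` until
#'   [flag_hospitals()] is applied).
#' @export
shrunken_residuals <- function(fit) {
  stopifnot(inherits(fit, "psival_glmm"))
  if (!fit$converged)
    stop_psival("refusing residuals from a non-converged fit")
  sigma2 <- fit$sigma2_hospital
  if (sigma2 <= 0) {
    u <- numeric(fit$n_hospitals)
    se <- rep(NA_real_, fit$n_hospitals)
    # complete shrinkage: zero residual, vanishing comparative variance
    se[] <- 0
  } else {
    u <- fit$u_hat
    se <- 1 / sqrt(fit$S2 + 1 / sigma2)
  }
  out <- data.frame(hospital_id = fit$hospital_ids, u_hat = u,
                    se_comp = se, stringsAsFactors = FALSE)
  out$rank <- rank(out$u_hat, ties.method = "first")
  out$flag <- "none"
  class(out) <- c("psival_ranef", "data.frame")
  out
}

#' Flag hospitals above or below the expected rate
#'
#' A hospital is flagged `"above"` when the lower end of the
#' `1 - alpha` interval around its shrunken residual stays above 0
#' (`u_hat - z * se > 0` with `z = qnorm(1 - alpha/2)`), `"below"` when
#' the upper end stays under 0.
#'
#' @param estimates output of [shrunken_residuals()].
#' @param alpha two-sided type-1 error (default 0.05).
#' @return list with `estimates` (flag column filled) and `report`
#'   (`n_hospitals`, `n_above`, `n_below`, `fraction_above`, `alpha`).
#' @export
flag_hospitals <- function(estimates, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  lo <- estimates$u_hat - z * estimates$se_comp
  hi <- estimates$u_hat + z * estimates$se_comp
  estimates$flag <- ifelse(lo > 0, "above", ifelse(hi < 0, "below", "none"))
  estimates$flag[is.na(estimates$flag)] <- "none"
  report <- list(n_hospitals = nrow(estimates),
                 n_above = sum(estimates$flag == "above"),
                 n_below = sum(estimates$flag == "below"),
                 fraction_above = mean(estimates$flag == "above"),
                 alpha = alpha)
  list(estimates = estimates, report = report)
}

#' Caterpillar plot data
#'
#' Hospitals sorted ascending by shrunken residual (ties broken by
#' hospital id) with interval endpoints, ready for plotting residuals
#' around the population average.
#'
#' @param estimates output of [shrunken_residuals()] (flags optional).
#' @param alpha interval level matching [flag_hospitals()].
#' @return data frame `(position, hospital_id, u_hat, lo, hi, flag)`.
#' @export
caterpillar_data <- function(estimates, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  ord <- order(estimates$u_hat, estimates$hospital_id)
  out <- data.frame(position = seq_along(ord),
                    hospital_id = estimates$hospital_id[ord],
                    u_hat = estimates$u_hat[ord],
                    lo = estimates$u_hat[ord] - z * estimates$se_comp[ord],
                    hi = estimates$u_hat[ord] + z * estimates$se_comp[ord],
                    flag = estimates$flag[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare random-effect estimates between two model variants
#'
#' Pearson correlation between the two vectors of shrunken residuals over
#' the common (identical) hospital set, plus the number of hospitals
#' whose flag changed category — the sensitivity summary used when a
#' recalibrated model (e.g. with the coding-intensity covariate) is
#' compared against the original.
#'
#' @param estimates_a,estimates_b outputs of [shrunken_residuals()] /
#'   [flag_hospitals()] on the same hospitals.
#' @param alpha flag level used when an input carries no flags yet.
#' @return list `(correlation, n_flag_changes, changes)` where `changes`
#'   lists the hospitals with `flag_a != flag_b`.
#' @export
compare_model_variants <- function(estimates_a, estimates_b, alpha = 0.05) {
  a <- estimates_a; b <- estimates_b
  if (!setequal(a$hospital_id, b$hospital_id) ||
      nrow(a) != nrow(b))
    stop_psival("hospital sets differ between the two estimate sets")
  b <- b[match(a$hospital_id, b$hospital_id), , drop = FALSE]
  if (all(a$flag == "none")) a <- flag_hospitals(a, alpha)$estimates
  if (all(b$flag == "none")) b <- flag_hospitals(b, alpha)$estimates
  changed <- a$flag != b$flag
  list(correlation = stats::cor(a$u_hat, b$u_hat),
       n_flag_changes = sum(changed),
       changes = data.frame(hospital_id = a$hospital_id[changed],
                            flag_a = a$flag[changed],
                            flag_b = b$flag[changed],
                            stringsAsFactors = FALSE))
}
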