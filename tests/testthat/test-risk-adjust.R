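# Patient-level risk adjustment: logistic fit, screening, discrimination,
# expected counts and indirect standardization.

# 2x2 layout: exposed 10/100 events, unexposed 5/100.
two_by_two <- function(a = 10, b = 90, c = 5, d = 95) {
  rec <- data.frame(
    hospital_id = "H1", age = 50,
    sex = rep(c("female", "male"), length.out = a + b + c + d),
    exposed = rep(c(1, 0), c(a + b, c + d)),
    eligible_toy = TRUE,
    event_toy = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d)),
    stringsAsFactors = FALSE)
  build_cohort(rec, psi_definition("toy"))
}

test_that("logistic coefficient matches the 2x2 closed form", {
  co <- two_by_two()
  fit <- fit_logistic(co, "exposed")
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["exposed"]] - log((10 * 95) / (90 * 5))),
            1e-8)
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - log(5 / 95)), 1e-8)
  # matches the standard GLM route (independent oracle)
  g <- glm(fit$y ~ co$records$exposed, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(g)))), tolerance = 1e-4)
})

test_that("intercept-only fit reproduces the pooled rate exactly", {
  co <- counts_cohort(n = c(100, 200), y = c(3, 10))
  fit <- fit_logistic(co, character())
  expect_equal(unique(round(fit$fitted, 12)), round(13 / 300, 12))
  expect_equal(sum(fit$fitted), 13, tolerance = 1e-10)
})

test_that("known coefficients are recovered within 3 SEs", {
  co <- small_cohort(seed = 19)
  fit <- fit_logistic(co, c("age", "sex", "paralysis", "fluid_electrolyte"))
  truth <- c(log(0.01), log(1.03), log(1.2), log(4), log(2.5))
  se <- sqrt(diag(fit$vcov))
  for (k in 2:5)
    expect_lt(abs(fit$coefficients[[k]] - truth[k]), 3 * se[k])
})

test_that("constant covariates are dropped with a warning; separation flagged", {
  co <- counts_cohort(n = c(100, 100), y = c(5, 7))
  co$records$flat <- 1
  expect_warning(fit <- fit_logistic(co, c("sex", "flat")), "constant")
  expect_false("flat" %in% names(fit$coefficients))
  # perfect separation
  co2 <- two_by_two(a = 20, b = 0, c = 0, d = 80)
  fit2 <- fit_logistic(co2, "exposed")
  expect_false(fit2$converged)
  expect_true(fit2$separated)
  expect_error(hospital_summaries(fit2, co2), "non-converged")
})

test_that("screening keeps OR >= 2 inclusively and drops null effects", {
  # engineered exact OR = 2: exposed 20/100, unexposed 10/90 vs 80
  co <- two_by_two(a = 20, b = 80, c = 10, d = 80)
  sel <- screen_comorbidities(co, "exposed", or_threshold = 2,
                              base_covariates = character())
  expect_true("exposed" %in% sel)
  sel_hi <- screen_comorbidities(co, "exposed", or_threshold = 2.05,
                                 base_covariates = character())
  expect_false("exposed" %in% sel_hi)

  # large simulation: OR 4 kept, OR ~1 (fluid set to null) excluded
  cfg <- small_config(seed = 29, n_hospitals = 40, size_mean = 800,
                      sigma2 = 0.1)
  cfg$beta$fluid_electrolyte <- log(1.3)
  d <- generate_discharges(generate_hospitals(cfg), cfg)
  co2 <- build_cohort(d, psi_definition("du"))
  sel2 <- screen_comorbidities(co2, c("paralysis", "fluid_electrolyte"))
  expect_true("paralysis" %in% sel2)
  expect_false("fluid_electrolyte" %in% sel2)
  expect_true(all(c("age", "sex") %in% sel2))
})

test_that("c statistic: trivial cases, pair-enumeration oracle, monotone
           invariance", {
  co <- counts_cohort(n = c(8, 8), y = c(4, 2))
  fit <- fit_logistic(co, character())
  expect_equal(c_statistic(fit), 0.5)   # constant score: all ties

  set.seed(8)
  y <- c(1, 1, 1, 0, 0, 0, 0, 1)
  s <- c(0.9, 0.8, 0.3, 0.3, 0.2, 0.7, 0.1, 0.5)
  fake <- structure(list(fitted = s, y = y), class = "psival_logit")
  expect_equal(c_statistic(fake), c_stat_pairs(s, y))
  # perfectly separating score
  expect_equal(c_statistic(structure(list(fitted = y * 10 + 1, y = y),
                                     class = "psival_logit")), 1)
  # invariance under strictly monotone transform
  fake3 <- structure(list(fitted = exp(3 * s), y = y),
                     class = "psival_logit")
  expect_equal(c_statistic(fake3), c_statistic(fake))
})

test_that("hospital summaries: totals identity and hand-summed fixture", {
  co <- small_cohort(seed = 37, n_hospitals = 10, size_mean = 150)
  fit <- fit_logistic(co, c("age", "sex"))
  s <- hospital_summaries(fit, co)
  expect_equal(sum(s$e_exp), sum(s$y_obs), tolerance = 1e-8)
  # direct per-hospital summation oracle
  byhand <- tapply(fit$fitted, co$records$hospital_id, sum)
  expect_equal(s$e_exp, as.numeric(byhand[s$hospital_id]))
  expect_equal(s$rate_crude, 1000 * s$y_obs / s$n)
  # intercept-only: e = n * pooled rate
  fit0 <- fit_logistic(co, character())
  s0 <- hospital_summaries(fit0, co)
  expect_equal(s0$e_exp, s0$n * sum(s0$y_obs) / sum(s0$n), tolerance = 1e-8)
})

test_that("indirect standardization identities", {
  s <- data.frame(hospital_id = c("A", "B", "C"),
                  y_obs = c(4, 10, 2), e_exp = c(5, 8, 3),
                  n = c(1000, 2000, 500))
  s$rate_crude <- 1000 * s$y_obs / s$n
  a <- adjusted_incidence(s)
  pooled <- 1000 * sum(s$y_obs) / sum(s$n)
  expect_equal(a$rate_adjusted, 1000 * (s$y_obs / s$e_exp) *
                 sum(s$y_obs) / sum(s$n))
  # y = e for every hospital -> all adjusted rates equal the pooled rate
  s2 <- s; s2$e_exp <- s2$y_obs
  expect_equal(unique(adjusted_incidence(s2)$rate_adjusted), pooled)
  # e-weighted mean of O/E-scaled rates equals the pooled rate
  a2 <- adjusted_incidence(s)
  expect_equal(sum(a2$rate_adjusted * s$e_exp) / sum(s$e_exp) *
                 sum(s$e_exp) / sum(s$y_obs), pooled,
               tolerance = 1e-10)
  # scale consistency: doubling y and e leaves O/E unchanged
  s3 <- s; s3$y_obs <- 2 * s3$y_obs; s3$e_exp <- 2 * s3$e_exp
  expect_equal(adjusted_incidence(s3)$rate_adjusted /
                 (sum(s3$y_obs) / sum(s3$n)) * (sum(s$y_obs) / sum(s$n)),
               a$rate_adjusted, tolerance = 1e-12)
  # quasi-sentinel: crude rates pass through
  q <- adjusted_incidence(s, quasi_sentinel = TRUE)
  expect_equal(q$rate_adjusted, s$rate_crude)
  s4 <- s; s4$e_exp[2] <- 0
  expect_error(adjusted_incidence(s4), "B")
})
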