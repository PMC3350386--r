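# Random-intercept logistic models, rho and the Median Odds Ratio.

test_that("rho and MOR closed forms and round-trip inversion", {
  # printed-variance spot values (2 dp)
  expect_equal(round(rho_icc(0.20), 2), 0.06)
  expect_equal(round(median_odds_ratio(0.20), 2), 1.53)
  expect_equal(rho_icc(0), 0)
  expect_equal(median_odds_ratio(0), 1)
  expect_equal(rho_icc(pi^2 / 3), 0.5)
  expect_error(rho_icc(-0.1), "domain")
  expect_error(median_odds_ratio(-0.1), "domain")
  # strictly increasing bijections; inverse accurate to 1e-10
  s2 <- c(1e-6, 0.05, 0.2, 0.38, 1.05, 3, 10)
  expect_true(all(diff(rho_icc(s2)) > 0))
  expect_true(all(diff(median_odds_ratio(s2)) > 0))
  expect_equal(sigma2_from_rho(rho_icc(s2)), s2, tolerance = 1e-10)
  expect_equal(sigma2_from_mor(median_odds_ratio(s2)), s2,
               tolerance = 1e-10)
})

test_that("sigma2 fixed at 0 reduces to the ordinary logistic fit", {
  co <- small_cohort(seed = 11, n_hospitals = 20, size_mean = 200)
  g <- fit_random_intercept_logistic(co, c("age", "sex"), sigma2_fixed = 0)
  l <- fit_logistic(co, c("age", "sex"))
  expect_equal(g$coefficients, l$coefficients, tolerance = 1e-6)
  expect_equal(g$log_likelihood, l$log_likelihood, tolerance = 1e-8)
  expect_equal(g$sigma2_hospital, 0)
})

test_that("Laplace and AGQ agree with exact integration and lme4", {
  # prior-dominated toy fixture: Laplace is accurate here (see vignette)
  cfg <- generator_config(
    n_hospitals = 6, hospital_size_law = list(mean = 50, dispersion = 1000),
    sigma2_hospital = 0.15, seed = 2,
    beta = list(intercept = 0, age = 0, sex = log(1.3), paralysis = log(2)),
    comorbidity_prevalences = c(paralysis = 0.2))
  h <- generate_hospitals(cfg)
  co <- build_cohort(generate_discharges(h, cfg), psi_definition("du"),
                     hospital_attrs = h)
  fit <- fit_random_intercept_logistic(co, c("sex", "paralysis"))
  expect_gt(fit$sigma2_hospital, 1e-5)
  ll_exact <- glmm_ll_exact(co, fit)
  expect_lt(abs(fit$log_likelihood - ll_exact), 1e-3)

  # harder fixture: AGQ(25) matches exact integration tightly
  cfg2 <- cfg; cfg2$seed <- 4L
  h2 <- generate_hospitals(cfg2)
  co2 <- build_cohort(generate_discharges(h2, cfg2), psi_definition("du"),
                      hospital_attrs = h2)
  fa <- fit_random_intercept_logistic(co2, c("sex", "paralysis"),
                                      method = "agq", n_quad = 25)
  expect_lt(abs(fa$log_likelihood - glmm_ll_exact(co2, fa)), 1e-6)

  # lme4 as an independent route on a moderate cohort
  co3 <- small_cohort(seed = 11)
  fit3 <- fit_random_intercept_logistic(
    co3, c("age", "sex", "paralysis", "fluid_electrolyte"))
  d3 <- co3$records
  d3$female <- as.numeric(d3$sex == "female")
  m <- suppressWarnings(  # lme4 complains about raw-age scaling only
    lme4::glmer(event ~ age + female + paralysis + fluid_electrolyte +
                  (1 | hospital_id), data = d3, family = binomial))
  expect_equal(fit3$sigma2_hospital,
               unname(lme4::VarCorr(m)$hospital_id[1]), tolerance = 0.01)
  expect_equal(unname(fit3$coefficients),
               unname(lme4::fixef(m)), tolerance = 0.01)
  expect_equal(fit3$log_likelihood, as.numeric(stats::logLik(m)),
               tolerance = 1e-5)
})

test_that("Laplace and AGQ(25) sigma2 agree within 5% on a dense fixture", {
  co <- small_cohort(seed = 57, n_hospitals = 30, size_mean = 300)
  fl <- fit_random_intercept_logistic(co, c("age", "sex"))
  fa <- fit_random_intercept_logistic(co, c("age", "sex"),
                                      method = "agq", n_quad = 25)
  expect_lt(abs(fl$sigma2_hospital - fa$sigma2_hospital) /
              fa$sigma2_hospital, 0.05)
})

test_that("model sequence: quasi-sentinel gets one model; variance drops
           when a confounded covariate is adjusted", {
  co <- small_cohort(seed = 11, n_hospitals = 20, size_mean = 200)
  co$quasi_sentinel <- TRUE
  fits <- model_sequence(co)
  expect_length(fits, 1)
  expect_named(fits, "model1")

  # case-mix clustering: comorbidity prevalence varies by hospital while
  # the true hospital effect is absent, so adjusting it shrinks sigma2
  set.seed(61)
  J <- 40; m <- 400
  prev <- plogis(qlogis(0.15) + rnorm(J, 0, 0.9))
  rec <- do.call(rbind, lapply(seq_len(J), function(j) {
    flag <- as.integer(runif(m) < prev[j])
    eta <- qlogis(0.01) + log(6) * flag
    data.frame(hospital_id = sprintf("H%02d", j), age = 50,
               sex = rep(c("female", "male"), length.out = m),
               risky = flag, eligible_toy = TRUE,
               event_toy = runif(m) < plogis(eta),
               stringsAsFactors = FALSE)
  }))
  co2 <- build_cohort(rec, psi_definition("toy"))
  f1 <- fit_random_intercept_logistic(co2, character())
  f3 <- fit_random_intercept_logistic(co2, "risky")
  expect_gt(f1$sigma2_hospital, f3$sigma2_hospital)

  fits2 <- model_sequence(co2, c("sex", "risky"))
  expect_named(fits2, c("model1", "model2", "model3"))
  tab <- model_table(fits2)
  expect_true("Hospital-level variance" %in% tab$quantity)
  expect_equal(ncol(tab), 4)
})

test_that("cluster metric CIs transform monotonely and cover", {
  co <- small_cohort(seed = 11)
  fit <- fit_random_intercept_logistic(co, c("age", "sex"))
  ci_s <- cluster_metric_ci(fit, "sigma2")
  ci_r <- cluster_metric_ci(fit, "rho")
  ci_m <- cluster_metric_ci(fit, "mor")
  expect_equal(ci_r, rho_icc(ci_s))
  expect_equal(ci_m, median_odds_ratio(ci_s))
  expect_true(ci_s[1] < fit$sigma2_hospital &
                fit$sigma2_hospital < ci_s[2])
  # boundary: one-sided with warning
  f0 <- fit_random_intercept_logistic(co, c("age", "sex"), sigma2_fixed = 0)
  expect_warning(ci0 <- cluster_metric_ci(f0, "mor"), "one-sided")
  expect_equal(ci0[1], 1)
})

test_that("GLMM on sigma2 = 0 data matches ordinary logistic within 3 SEs", {
  co <- small_cohort(seed = 71, sigma2 = 0, n_hospitals = 30,
                     size_mean = 300)
  g <- fit_random_intercept_logistic(co, c("age", "sex"))
  l <- fit_logistic(co, c("age", "sex"))
  se <- sqrt(diag(l$vcov))
  for (k in seq_along(se))
    expect_lt(abs(g$coefficients[[k]] - l$coefficients[[k]]), 3 * se[k])
  expect_lt(g$sigma2_hospital, 0.05)
})
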