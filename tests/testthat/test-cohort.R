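# Cohort preparation: comorbidity mapping, eligibility, filters.

toy_map <- comorbidity_map(list(
  congestive_heart_failure = c("428"),
  paralysis = c("342", "344"),
  weight_loss = c("260", "261", "262", "263")))

test_that("comorbidity mapping by code prefix", {
  rec <- data.frame(hospital_id = "H1",
                    secondary_dx = c("4280", "342.1", "", "7802;2639", NA),
                    stringsAsFactors = FALSE)
  out <- map_comorbidities(rec, toy_map)
  expect_equal(out$congestive_heart_failure, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(out$paralysis, c(0L, 1L, 0L, 0L, 0L))   # dot stripped
  expect_equal(out$weight_loss, c(0L, 0L, 0L, 1L, 0L))
  # idempotent
  expect_identical(map_comorbidities(out, toy_map), out)
  expect_error(map_comorbidities(data.frame(x = 1), toy_map), "missing code")
})

test_that("20-record mapping matches a brute-force oracle", {
  set.seed(4)
  pool <- c("4280", "4281", "3421", "3440", "2601", "2630", "7802",
            "V100", "25000", "4019")
  recs <- data.frame(hospital_id = "H1", secondary_dx = vapply(1:20,
    function(i) paste(sample(pool, sample(0:4, 1)), collapse = ";"),
    character(1)), stringsAsFactors = FALSE)
  out <- map_comorbidities(recs, toy_map)
  for (i in 1:20) {
    codes <- strsplit(recs$secondary_dx[i], ";")[[1]]
    for (nm in names(toy_map)) {
      want <- FALSE
      for (cd in codes) for (pre in toy_map[[nm]])
        if (substr(cd, 1, nchar(pre)) == pre) want <- TRUE
      expect_identical(out[[nm]][i] == 1L, want)
    }
  }
})

test_that("code-driven cohort build: exclusion precedence and enumeration", {
  psi <- psi_definition("ps",
                        numerator_codes = "9985",
                        denominator_inclusion_codes = c("80", "81"),
                        denominator_exclusion_codes = "805")
  rec <- data.frame(
    hospital_id = rep("H1", 12),
    codes = c("8000", "8100;9985", "8050", "8050;9985", "8200", "9985",
              "8099", "8150;9985", "80.50", "8111", "8111;9985", ""),
    stringsAsFactors = FALSE)
  co <- build_cohort(rec, psi)
  # hand enumeration: eligible = starts 80/81 and not 805 ->
  # rows 1,2,7,8,10,11 (row 9 is 8050 after dot-stripping)
  expect_equal(nrow(co$records), 6)
  expect_equal(sum(co$records$event), 3)  # rows 2, 8, 11
  expect_false(co$quasi_sentinel)
  # exclusion wins regardless of numerator (row 4)
  expect_false("8050;9985" %in% co$records$codes)
  expect_error(build_cohort(rec[3:4, ], psi), "empty denominator")
})

test_that("flag-driven cohort build round-trips the generator", {
  cfg <- small_config(seed = 31, n_hospitals = 15, size_mean = 120)
  h <- generate_hospitals(cfg)
  d <- generate_discharges(h, cfg)
  co <- build_cohort(d, psi_definition("du"), hospital_attrs = h)
  expect_equal(nrow(co$records), sum(d$eligible_du))
  expect_equal(sum(co$hospitals$n_eligible), nrow(co$records))
  expect_equal(sum(co$records$event), sum(d$event_du))
  expect_true(all(c("beds", "teaching") %in% names(co$hospitals)))
})

test_that("hospital filter: 30-case boundary, idempotence, logging", {
  co <- counts_cohort(n = c(10, 29, 30, 500), y = c(1, 2, 3, 25))
  f <- apply_hospital_filter(co, 30)
  expect_setequal(f$hospitals$hospital_id, c("H03", "H04"))
  expect_equal(sum(f$hospitals$n_eligible), nrow(f$records))
  excl <- hospital_exclusions(f)
  expect_setequal(excl$hospital_id, c("H01", "H02"))
  # idempotent, and min_cases = 1 is the identity
  expect_equal(apply_hospital_filter(f, 30)$hospitals, f$hospitals)
  expect_equal(apply_hospital_filter(co, 1)$hospitals, co$hospitals)
  # exactly one dropped from {10, 30, 500}
  f2 <- apply_hospital_filter(counts_cohort(c(10, 30, 500), c(0, 1, 5)), 30)
  expect_equal(nrow(f2$hospitals), 2)
  expect_error(apply_hospital_filter(counts_cohort(c(5, 8), c(0, 1)), 30),
               "all hospitals")
})

test_that("coding-intensity covariate dichotomizes at >= threshold", {
  co <- counts_cohort(n = c(40, 40), y = c(2, 3))
  co$records$n_secondary_dx <- rep(c(0, 2, 4, 9), 20)
  out <- coding_intensity_covariate(co, threshold = 4)
  expect_equal(out$records$high_coding,
               rep(c(0L, 0L, 1L, 1L), 20))  # 4 falls in the high category
  med <- coding_intensity_covariate(co, "median")
  expect_equal(attr(med, "coding_threshold"),
               median(co$records$n_secondary_dx))
  expect_equal(mean(med$records$high_coding),
               mean(co$records$n_secondary_dx >=
                      median(co$records$n_secondary_dx)))
})

test_that("largest-hospitals subset uses strict beds > 450 and teaching", {
  co <- counts_cohort(n = rep(50, 60), y = rep(2, 60))
  co$hospitals$beds <- c(rep(450, 5), rep(600, 47), rep(200, 8))
  co$hospitals$teaching <- c(rep(TRUE, 52), rep(FALSE, 8))
  sub <- subset_largest(co)
  expect_equal(nrow(sub$hospitals), 47)   # beds = 450 excluded
  expect_true(all(sub$hospitals$beds > 450 & sub$hospitals$teaching))
  expect_equal(sum(sub$hospitals$n_eligible), nrow(sub$records))
  # identity when everything qualifies
  co2 <- counts_cohort(n = rep(50, 4), y = rep(2, 4))
  co2$hospitals$beds <- rep(900, 4); co2$hospitals$teaching <- TRUE
  expect_equal(subset_largest(co2)$hospitals, co2$hospitals)
  co2$hospitals$beds <- rep(100, 4)
  expect_error(subset_largest(co2), "empty-cohort")
})

test_that("eligibility is order-independent", {
  cfg <- small_config(seed = 41, n_hospitals = 8, size_mean = 80)
  d <- generate_discharges(generate_hospitals(cfg), cfg)
  co1 <- build_cohort(d, psi_definition("du"))
  perm <- sample(nrow(d))
  co2 <- build_cohort(d[perm, ], psi_definition("du"))
  expect_equal(co1$hospitals, co2$hospitals)
})
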