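test_that("cohort generator hits the target prevalence exactly and deterministically", {
  for (seed in c(1, 7, 123)) {
    rec <- generate_cohort(cohort_spec(n_cases = 50, pr_prevalence = 0.56,
                                       rng_seed = seed),
                           keep_images = FALSE)$records
    expect_equal(sum(rec$pr), 28)
    expect_equal(nrow(rec), 50)
  }
  a <- generate_cohort(cohort_spec(rng_seed = 5), keep_images = FALSE)$records
  b <- generate_cohort(cohort_spec(rng_seed = 5), keep_images = FALSE)$records
  expect_identical(a, b)
})

test_that("degenerate class requests are rejected", {
  expect_error(cohort_spec(pr_prevalence = 1.0), "between 0 and 1")
  expect_error(cohort_spec(pr_prevalence = 0), "between 0 and 1")
  expect_error(cohort_spec(n_cases = 4, pr_prevalence = 0.1), ">= 2 cases")
})

test_that("generated follow-up dimensions always satisfy the >2 mm rule for the recorded label", {
  rec <- generate_cohort(cohort_spec(n_cases = 120, rng_seed = 11),
                         keep_images = FALSE)$records
  lab <- vapply(seq_len(nrow(rec)), function(i) {
    label_progression(unlist(rec[i, c("base_d1", "base_d2", "base_d3")]),
                      unlist(rec[i, c("fu_d1", "fu_d2", "fu_d3")]))
  }, logical(1))
  expect_identical(lab, rec$pr)
  # resection labels agree with the <10 % residual rule
  res <- vapply(seq_len(nrow(rec)), function(i) {
    classify_resection(rec$volume_cm3[i],
                       rec$volume_cm3[i] * rec$residual_fraction[i])
  }, character(1))
  expect_identical(res, rec$resection)
})

test_that("class-conditional tumor heights recover their nominal medians at n = 500", {
  rec <- generate_cohort(cohort_spec(n_cases = 500, rng_seed = 2),
                         keep_images = FALSE)$records
  expect_lt(abs(median(rec$height_mm[rec$pr]) - 35.5), 2.5)
  expect_lt(abs(median(rec$height_mm[!rec$pr]) - 18), 2.5)
  # P/R tumors carry the coarser texture on average
  expect_gt(median(rec$texture_granularity_mm[rec$pr]),
            median(rec$texture_granularity_mm[!rec$pr]))
})

test_that("simulate_survival censors administratively and recovers the hazard ratio", {
  # near-zero horizon censors every record
  s0 <- simulate_survival(rep(0, 50), list(baseline_rate = 0.05, coef = 0),
                          censor_months = 1e-6, seed = 1)
  expect_true(all(!s0$event))
  expect_true(all(s0$time_months > 0))
  expect_error(simulate_survival(0, list(baseline_rate = 0.05, coef = 0), 0),
               "positive")
  expect_error(simulate_survival(0, list(baseline_rate = -1, coef = 0), 10),
               "positive")
  s1 <- simulate_survival(rep(0:1, 100), list(baseline_rate = 0.03,
                                              coef = log(2)),
                          censor_months = 60, seed = 9)
  s2 <- simulate_survival(rep(0:1, 100), list(baseline_rate = 0.03,
                                              coef = log(2)),
                          censor_months = 60, seed = 9)
  expect_identical(s1, s2)
  # Cox recovers HR = 2 within the 95% CI in most replicates at n = 500
  hit <- vapply(1:30, function(r) {
    z <- rep(0:1, each = 250)
    d <- simulate_survival(z, list(baseline_rate = log(2) / 40,
                                   coef = log(2)),
                           censor_months = 80, seed = 100 + r)
    d$z <- z
    fit <- survival::coxph(survival::Surv(time_months, event) ~ z, data = d)
    ci <- exp(confint(fit))
    ci[1] <= 2 && 2 <= ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
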