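test_that("the >2 mm progression rule is strict and axis-wise", {
  expect_true(label_progression(c(38, 30, 25), c(48, 30, 25)))
  expect_false(label_progression(c(20, 18, 15), c(20, 18, 15)))
  expect_false(label_progression(c(20, 18, 15), c(22, 18, 15)))  # exactly +2
  expect_true(label_progression(c(20, 18, 15), c(20.0, 18, 17.1)))
  expect_error(label_progression(c(-1, 10), c(5, 10)), "positive")
  expect_error(label_progression(c(10, 10), c(5, 10, 11)), "length")
})

test_that("resection is classified by the 10 % residual-volume rule", {
  expect_equal(classify_resection(10, 0), "GTR")
  expect_equal(classify_resection(10.0, 0.9), "GTR")   # ratio 0.09
  expect_equal(classify_resection(10.0, 1.5), "STR")   # ratio 0.15
  expect_equal(classify_resection(10.0, 1.0), "STR")   # boundary 0.10
  expect_error(classify_resection(10, 11), "exceeds")
  expect_error(classify_resection(0, 0), "positive")
})

test_that("group comparison picks chi-square vs Fisher by expected counts and reproduces the published example", {
  # 26/28 vs 13/22 with visual disturbance: min expected count < 5 -> Fisher
  rec <- data.frame(
    pr = rep(c(TRUE, FALSE), c(28, 22)),
    visual_disturbance = c(rep(c(TRUE, FALSE), c(26, 2)),
                           rep(c(TRUE, FALSE), c(13, 9))))
  out <- compare_groups(rec, "visual_disturbance")
  expect_equal(out$test, "fisher")
  expect_lt(abs(out$p - 0.006), 0.002)

  # balanced categorical with large expected counts -> chi-square
  rec2 <- data.frame(pr = rep(c(TRUE, FALSE), each = 40),
                     flag = rep(c(TRUE, FALSE), 40))
  expect_equal(compare_groups(rec2, "flag")$test, "chi-square")
  # identical degenerate distributions: Fisher p = 1
  rec3 <- data.frame(pr = rep(c(TRUE, FALSE), each = 4),
                     g = c("a", "b", "a", "b", "a", "b", "a", "b"))
  expect_equal(compare_groups(rec3, "g")$p, 1)
  expect_error(compare_groups(data.frame(pr = c(TRUE, FALSE), v = c(1, 1)),
                              "v"), "constant")
})

test_that("continuous comparisons use Mann-Whitney with uniform null p-values", {
  rec <- data.frame(pr = rep(c(TRUE, FALSE), each = 30),
                    x = c(rnorm(30, 1), rnorm(30)))
  out <- compare_groups(rec, "x")
  expect_equal(out$test, "mann-whitney")
  expect_true(grepl("\\(", out$summary[1]))  # median (IQR) formatting

  set.seed(31)
  ps <- vapply(1:200, function(i) {
    g <- rep(c(TRUE, FALSE), each = 250)
    v <- rnorm(500)
    stats::wilcox.test(v ~ g, exact = FALSE)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Kaplan-Meier equals the empirical survival without censoring and log-rank detects true separation", {
  t_obs <- c(3, 5, 5, 8, 12)
  rec <- data.frame(time_months = t_obs, event = TRUE,
                    g = c("a", "a", "a", "a", "a"))
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = rec)
  emp <- vapply(summary(fit)$time,
                function(t) mean(t_obs > t), numeric(1))
  expect_equal(summary(fit)$surv, emp)

  # power: HR = 3 between groups
  set.seed(17)
  detect <- vapply(1:50, function(i) {
    z <- rep(0:1, each = 50)
    d <- simulate_survival(z, list(baseline_rate = 0.02, coef = log(3)),
                           censor_months = 60)
    d$g <- z
    km_logrank(d, function(r) r$g)$p < 0.01
  }, logical(1))
  expect_gte(mean(detect), 0.9)
  expect_error(km_logrank(data.frame(time_months = 1, event = FALSE,
                                     g = "a"), "g"), "one event")
})

test_that("Cox promotion carries exactly the univariate-significant covariates into the multivariate model", {
  set.seed(23)
  n <- 300
  strong1 <- rep(0:1, each = n / 2)
  strong2 <- rnorm(n)
  noise1 <- rnorm(n)
  noise2 <- sample(0:1, n, TRUE)
  lat <- log(3) * strong1 + 0.8 * strong2
  d <- simulate_survival(lat, list(baseline_rate = 0.02, coef = 1),
                         censor_months = 80)
  rec <- cbind(d, strong1, strong2, noise1, noise2)
  uni <- cox_fit(rec, c("strong1", "strong2", "noise1", "noise2"),
                 mode = "univariate")
  expect_s3_class(uni, "cox_result")
  expect_true(all(uni$ci_low <= uni$hr & uni$hr <= uni$ci_high))
  expect_true(all(uni$hr > 0))
  multi <- cox_fit(rec, c("strong1", "strong2", "noise1", "noise2"),
                   mode = "multivariate")
  promoted <- attr(multi, "variables_included")
  sig_uni <- c("strong1", "strong2", "noise1", "noise2")[uni$p < 0.05]
  expect_identical(promoted, sig_uni)
  expect_true(all(c("strong1", "strong2") %in% promoted))

  # null covariate: HR close to 1
  expect_gt(uni$p[uni$variable == "noise1"], 0.001)
})

test_that("log-rank and Cox agree in direction on a binary covariate", {
  set.seed(29)
  z <- rep(0:1, each = 100)
  d <- simulate_survival(z, list(baseline_rate = 0.02, coef = log(2)),
                         censor_months = 70)
  rec <- cbind(d, z = z)
  cx <- cox_fit(rec, "z", mode = "univariate")
  km <- km_logrank(rec, function(r) r$z)
  expect_gt(cx$hr, 1)          # group 1 has the higher hazard...
  expect_lt(km$p, 0.05)        # ...and the curves separate
})
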