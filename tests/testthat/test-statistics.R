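test_that("group summaries use the n-1 standard deviation", {
  s <- summarize_group(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)

  expect_warning(s1 <- summarize_group(5), "single observation")
  expect_equal(s1$sd, 0)

  withr::local_seed(40)
  draws <- rnorm(1000, mean = 5, sd = 2)
  expect_lt(abs(summarize_group(draws)$mean - 5), 0.2)

  expect_error(summarize_group(numeric(0)), "non-empty")
})

test_that("printed summaries reproduce the reported significance calls", {
  d <- reference_densities()
  wb <- function(dd) {
    r <- d[d$region == "wound_bed" & d$compartment == "whole" & d$day == dd, ]
    group_summary(r$mean, r$sd, r$n)
  }
  # day 15 vs day 3: significant under both variants
  for (v in c("welch", "pooled")) {
    tt <- ttest_from_summaries(wb(15), wb(3), variant = v)
    expect_lt(tt$p, 0.05)
    expect_true(tt$significant)
  }
  # day 3 vs unwounded: significantly reduced innervation
  t3 <- ttest_from_summaries(wb(3), wb(0))
  expect_lt(t3$p, 0.05)
  # day 15 vs unwounded: not significant under Welch (the reported call),
  # significant under the pooled variant
  expect_false(ttest_from_summaries(wb(15), wb(0), "welch")$significant)
  expect_true(ttest_from_summaries(wb(15), wb(0), "pooled")$significant)
})

test_that("pooled t matches the hand-computed textbook case", {
  a <- group_summary(10, 2, 8)
  b <- group_summary(12, 2, 8)
  tt <- ttest_from_summaries(a, b, variant = "pooled")
  expect_equal(tt$t, -2)
  expect_equal(tt$df, 14)
})

test_that("t-tests agree with the independent reference implementation", {
  withr::local_seed(41)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1), mean = runif(1, 0, 5), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:12, 1), mean = runif(1, 0, 5), sd = runif(1, 0.5, 2))
    for (v in c("welch", "pooled")) {
      mine <- ttest_from_samples(a, b, variant = v)
      ref <- stats::t.test(a, b, var.equal = (v == "pooled"))
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("t-test symmetry, degenerate cases and path equivalence hold", {
  withr::local_seed(42)
  a <- rnorm(6); b <- rnorm(8, 1)
  f <- ttest_from_samples(a, b)
  r <- ttest_from_samples(b, a)
  expect_equal(f$t, -r$t)
  expect_equal(f$p, r$p)

  same <- ttest_from_samples(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  expect_error(ttest_from_summaries(group_summary(1, 0, 3),
                                    group_summary(2, 0, 3)),
               "degenerate variance")
  expect_error(ttest_from_samples(1, c(1, 2)), "n >= 2")

  # summaries path is definitionally identical to the samples path
  via_sum <- ttest_from_summaries(summarize_group(a), summarize_group(b))
  expect_identical(f$t, via_sum$t)
  expect_identical(f$p, via_sum$p)
})

test_that("p-value decreases as the mean separation grows", {
  p_prev <- 1
  for (delta in c(0.5, 1, 2, 4)) {
    p <- ttest_from_summaries(group_summary(0, 1, 5),
                              group_summary(delta, 1, 5))$p
    expect_lt(p, p_prev)
    p_prev <- p
  }
})

test_that("OLS fits match the normal-equations oracle", {
  x <- c(1, 2, 3, 4)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  expect_equal(linear_fit(x, rep(3, 4))$r_squared, 0)

  withr::local_seed(43)
  y <- 1.5 * x - 2 + rnorm(4, 0, 0.3)
  f2 <- linear_fit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(f2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f2$slope, beta[2], tolerance = 1e-10)
  resid <- y - X %*% beta
  expect_equal(f2$r_squared, 1 - sum(resid^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)

  # R^2 is invariant under affine rescaling of x
  f3 <- linear_fit(10 * x + 100, y)
  expect_equal(f3$r_squared, f2$r_squared, tolerance = 1e-12)

  expect_error(linear_fit(1:3, 1:4), "length mismatch")
  expect_error(linear_fit(c(2, 2, 2), 1:3), "distinct x")
})

test_that("re-epithelialization percentage follows the length ratio", {
  expect_equal(reepithelialization_percent(2, 3, 10), 50)
  expect_equal(reepithelialization_percent(5, 5, 10), 100)
  expect_equal(reepithelialization_percent(0, 0, 8), 0)
  expect_error(reepithelialization_percent(6, 5, 10), "exceeds")
  expect_error(reepithelialization_percent(-1, 0, 10), "non-negative")
  expect_error(reepithelialization_percent(0, 0, 0), "positive")
})

test_that("the time-course report aggregates, tests and correlates", {
  withr::local_seed(44)
  days <- rep(c(3, 7, 10, 15), each = 3)
  dens <- c(1, 1.2, 0.9, 2, 2.2, 1.9, 4, 4.3, 3.8, 8, 8.5, 7.7) * 1000
  records <- tibble::tibble(sample_id = paste0("s", seq_along(days)),
                            day = days, region = "wound_bed",
                            compartment = "whole", density = dens)
  # re-epithelialization exactly proportional to per-day mean density
  reepi <- tibble::tibble(day = c(3, 7, 10, 15),
                          percent = c(1.0333, 2.0333, 4.0333, 8.0667) * 10)
  rep <- timecourse_report(records, reepi)
  expect_equal(nrow(rep$summaries), 4)
  expect_true(all(diff(rep$summaries$mean_density) > 0))
  expect_equal(nrow(rep$tests), choose(4, 2))
  expect_equal(rep$n_tests, 6)
  expect_gt(rep$fit$r_squared, 0.999)

  single <- records[records$day == 3, ]
  expect_error(timecourse_report(single, reepi), "at least 2 days")

  # day alignment failure
  expect_error(timecourse_report(records,
                                 tibble::tibble(day = 99, percent = 10)),
               "fewer than 2 days")
})

test_that("tidy and glance methods return one-row tibbles", {
  tt <- ttest_from_summaries(group_summary(1, 1, 5), group_summary(3, 1, 5))
  td <- tidy(tt)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "df", "p.value", "variant", "alpha",
                     "significant"))
  f <- linear_fit(1:5, 2 * (1:5))
  expect_equal(glance(f)$r.squared, 1)
  expect_equal(nrow(tidy(f)), 2)
})
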