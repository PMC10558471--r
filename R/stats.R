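#' Group summary (mean, SD, n)
#'
#' Sample standard deviation uses the `n - 1` denominator. A single value
#' yields SD 0 with a warning.
#'
#' @param values Numeric vector (length >= 1).
#' @return A list of class `group_summary` with `mean`, `sd`, `n`.
#' @export
summarize_group <- function(values) {
  n <- length(values)
  if (n < 1L || anyNA(values)) {
    stop("`values` must be non-empty and free of NA", call. = FALSE)
  }
  s <- if (n == 1L) {
    warning("single observation: SD defined as 0", call. = FALSE)
    0
  } else {
    stats::sd(values)
  }
  structure(list(mean = mean(values), sd = s, n = n), class = "group_summary")
}

#' Construct a group summary from printed values
#'
#' Convenience constructor for summaries transcribed from a table
#' (mean +/- SD, n).
#'
#' @param mean,sd,n The printed group mean, standard deviation and size.
#' @return A `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %.4g +/- %.4g (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Unpaired two-tailed t-test from group summaries
#'
#' Computes the two-sample t statistic directly from (mean, SD, n) pairs, so
#' printed table values can be tested without the underlying samples. The
#' Welch variant uses the Welch-Satterthwaite degrees of freedom; the pooled
#' variant assumes equal variances with `n_a + n_b - 2` degrees of freedom.
#' The variant is always recorded in the result.
#'
#' @param a,b [group_summary()] objects (each `n >= 2`).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @param alpha Significance level. Default 0.05.
#' @return A list of class `innerva_ttest`: `t`, `df`, `p`, `variant`,
#'   `alpha`, `significant` (`p < alpha`).
#' @examples
#' day15 <- group_summary(0.169, 0.009, 3)
#' day3 <- group_summary(0.02, 0.01, 3)
#' ttest_from_summaries(day15, day3)
#' @export
ttest_from_summaries <- function(a, b, variant = c("welch", "pooled"),
                                 alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2L || b$n < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (a$sd == 0 && b$sd == 0) {
    stop("degenerate variance in both groups", call. = FALSE)
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (variant == "welch") {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- (a$mean - b$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, variant = variant, alpha = alpha,
                 significant = p < alpha),
            class = "innerva_ttest")
}

#' Unpaired two-tailed t-test from samples
#'
#' Definitionally equivalent to [ttest_from_summaries()] applied to
#' [summarize_group()] of each sample.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @inheritParams ttest_from_summaries
#' @return An `innerva_ttest`.
#' @export
ttest_from_samples <- function(a, b, variant = c("welch", "pooled"),
                               alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  ttest_from_summaries(summarize_group(a), summarize_group(b),
                       variant = variant, alpha = alpha)
}

#' @export
print.innerva_ttest <- function(x, ...) {
  cat(sprintf("<t-test (%s)> t = %.4g, df = %.4g, p = %.4g (%s at alpha = %g)\n",
              x$variant, x$t, x$df, x$p,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' @export
tidy.innerva_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p.value = x$p,
                 variant = x$variant, alpha = x$alpha,
                 significant = x$significant)
}

#' @export
glance.innerva_ttest <- function(x, ...) tidy.innerva_ttest(x)

#' Ordinary least squares fit of y on x
#'
#' Wraps [stats::lm()]; reports slope, intercept and the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot` (0 when y is constant).
#'
#' @param x,y Numeric vectors of equal length; `x` must contain at least two
#'   distinct values.
#' @return A list of class `innerva_fit`: `slope`, `intercept`, `r_squared`,
#'   and the underlying `lm` object as `model`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("need at least 2 distinct x values", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, model = fit),
            class = "innerva_fit")
}

#' @export
print.innerva_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g x + %.4g, R^2 = %.4g\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.innerva_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.innerva_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared)
}

#' Re-epithelialization percentage
#'
#' The percentage of the combined left and right re-epithelialization length
#' to the total wound length. Vectorized.
#'
#' @param left_length,right_length Lengths of new epithelium from each wound
#'   edge (same unit as `total_wound_length`).
#' @param total_wound_length Total wound length (> 0).
#' @return Percentage in `[0, 100]`.
#' @examples
#' reepithelialization_percent(2, 3, 10)  # 50
#' @export
reepithelialization_percent <- function(left_length, right_length,
                                        total_wound_length) {
  if (any(left_length < 0) || any(right_length < 0)) {
    stop("lengths must be non-negative", call. = FALSE)
  }
  if (any(total_wound_length <= 0)) {
    stop("total wound length must be positive", call. = FALSE)
  }
  if (any(left_length + right_length > total_wound_length + 1e-12)) {
    stop("combined re-epithelialization exceeds total wound length",
         call. = FALSE)
  }
  100 * (left_length + right_length) / total_wound_length
}

#' Time-course report: per-day summaries, t-tests and the
#' density-re-epithelialization correlation
#'
#' Summarizes nerve-fiber density by day, runs every pairwise day-vs-day
#' unpaired two-tailed t-test (no multiple-testing correction is applied; the
#' number of tests is reported), and fits mean density against mean
#' re-epithelialization percentage across days by ordinary least squares.
#' Day 0 records are treated as unwounded skin: they enter the summaries and
#' the t-tests but not the correlation, which is computed on the healing
#' time-course days only.
#'
#' @param records A density-record tibble (see [quantify_image()]) with
#'   columns `day`, `compartment`, `density`.
#' @param reepi A tibble with either a `percent` column or
#'   `left_length`/`right_length`/`total_wound_length` columns, plus `day`.
#' @param compartment Which compartment's densities to analyze. Default
#'   `"whole"`.
#' @param variant,alpha Passed to [ttest_from_samples()].
#' @return A list of class `innerva_timecourse`: `summaries` (tibble),
#'   `tests` (tibble, one row per day pair), `fit` (an [linear_fit()] over
#'   per-day means), `n_tests`, `variant`, `alpha`.
#' @export
timecourse_report <- function(records, reepi, compartment = "whole",
                              variant = c("welch", "pooled"), alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(records), is.data.frame(reepi))
  recs <- dplyr::filter(records, .data$compartment == !!compartment,
                        !is.na(.data$day))
  days <- sort(unique(recs$day))
  if (length(days) < 2L) stop("need at least 2 days of records", call. = FALSE)

  summaries <- recs |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_density = mean(.data$density),
                     sd_density = stats::sd(.data$density),
                     n = dplyr::n(), .groups = "drop")

  pairs <- utils::combn(days, 2)
  tests <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    d1 <- pairs[1, i]; d2 <- pairs[2, i]
    tt <- ttest_from_samples(recs$density[recs$day == d2],
                             recs$density[recs$day == d1],
                             variant = variant, alpha = alpha)
    dplyr::bind_cols(tibble::tibble(day_a = d2, day_b = d1), tidy(tt))
  })

  if (!"percent" %in% names(reepi)) {
    reepi <- dplyr::mutate(reepi, percent = reepithelialization_percent(
      .data$left_length, .data$right_length, .data$total_wound_length))
  }
  reepi_by_day <- reepi |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_percent = mean(.data$percent), .groups = "drop")
  joint <- dplyr::inner_join(
    dplyr::filter(summaries, .data$day > 0),
    dplyr::filter(reepi_by_day, .data$day > 0), by = "day")
  if (nrow(joint) < 2L) {
    stop("densities and re-epithelialization share fewer than 2 days",
         call. = FALSE)
  }
  fit <- linear_fit(joint$mean_percent, joint$mean_density)

  structure(list(summaries = summaries, tests = tests, fit = fit,
                 joint = joint, n_tests = nrow(tests), variant = variant,
                 alpha = alpha, compartment = compartment),
            class = "innerva_timecourse")
}

#' @export
print.innerva_timecourse <- function(x, ...) {
  cat(sprintf("<timecourse report> compartment '%s', %d days, %d %s t-tests (uncorrected)\n",
              x$compartment, nrow(x$summaries), x$n_tests, x$variant))
  print(x$summaries)
  cat(sprintf("density vs re-epithelialization: R^2 = %.3f\n",
              x$fit$r_squared))
  invisible(x)
}

#' @export
tidy.innerva_timecourse <- function(x, ...) x$tests

#' @export
glance.innerva_timecourse <- function(x, ...) {
  tibble::tibble(r.squared = x$fit$r_squared, n_days = nrow(x$summaries),
                 n_tests = x$n_tests, variant = x$variant, alpha = x$alpha)
}
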