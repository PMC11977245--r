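# Method-comparison statistics and cohort-level age/sex trend analysis,
# including the piecewise-regression breakpoint scan.

check_cohort <- function(cohort, sex = NULL) {
  need <- c("age", "sex", "rate")
  if (!all(need %in% names(cohort)))
    stop_lipdesq("cohort needs columns ", paste(need, collapse = ", "))
  if (!is.null(sex)) cohort <- cohort[cohort$sex == sex, , drop = FALSE]
  if (any(cohort$rate < 0)) stop_lipdesq("rates must be non-negative")
  cohort
}

#' Min-max normalize desquamation rates
#'
#' Rescales rates linearly to `[0, 1]`; used to place the image-based and
#' tape-stripping methods on a common bounded axis before comparing their
#' fit against VA scores.
#'
#' @param rates Numeric vector with at least two distinct values.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_rates <- function(rates) {
  if (length(rates) < 2L) stop_lipdesq("need at least 2 subjects")
  rng <- range(rates)
  if (diff(rng) == 0) stop_lipdesq("cannot normalize constant rates")
  (rates - rng[1]) / diff(rng)
}

#' Compare a measurement method against visual assessment
#'
#' Pearson correlation (with two-sided p-value) between the method's
#' rates and the final VA scores, plus the mean squared error of the
#' min-max-normalized rates about their ordinary least-squares regression
#' line on VA. The MSE measures how tightly the measurements concentrate
#' around the fitted line, with VA treated as the ground-truth axis.
#'
#' @param rates Numeric vector of desquamation rates (percent).
#' @param va Numeric vector of final VA scores, same length.
#' @param normalize Min-max normalize the rates before regression
#'   (default `TRUE`); the correlation is unaffected.
#' @return List of class `method_comparison`: `r`, `p`, `mse`, `slope`,
#'   `intercept`, `n`, `normalization`.
#' @export
compare_to_va <- function(rates, va, normalize = TRUE) {
  if (length(rates) != length(va)) stop_lipdesq("rates and va must be paired")
  if (length(rates) < 3L) stop_lipdesq("need at least 3 subjects")
  if (stats::sd(rates) == 0 || stats::sd(va) == 0)
    stop_lipdesq("zero variance in rates or VA scores")
  y <- if (normalize) normalize_rates(rates) else rates
  ct <- stats::cor.test(rates, va, method = "pearson")
  fit <- stats::lm(y ~ va)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 mse = mean(stats::residuals(fit)^2),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(rates),
                 normalization = if (normalize) "minmax" else "none"),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> r = %.3f (p = %.3g), MSE = %.4f (n = %d)\n",
              x$r, x$p, x$mse, x$n))
  invisible(x)
}

decade_label <- function(age) paste0(10 * (age %/% 10), "s")

#' Per-decade summary and group tests of desquamation rates
#'
#' Groups a cohort by age decade (20s ... 60s), reports per-group mean
#' rates, an overall Kruskal-Wallis test, and pairwise two-sided Wilcoxon
#' rank-sum tests both Holm-adjusted and unadjusted.
#'
#' @param cohort Data frame with columns `age`, `sex`, `rate`.
#' @param sex Optional subset (`"male"` or `"female"`).
#' @return List with `summary` (data frame: group, n, mean_rate, sd_rate),
#'   `kruskal_p`, `pairwise_p_holm` and `pairwise_p_unadjusted`
#'   (lower-triangular matrices).
#' @export
group_summary <- function(cohort, sex = NULL) {
  cohort <- check_cohort(cohort, sex)
  cohort$group <- decade_label(cohort$age)
  tab <- table(cohort$group)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping groups with fewer than 2 members: ",
            paste(small, collapse = ", "), call. = FALSE)
    cohort <- cohort[!cohort$group %in% small, , drop = FALSE]
  }
  if (length(unique(cohort$group)) < 2L)
    stop_lipdesq("need at least 2 age groups")
  cohort$group <- factor(cohort$group, levels = sort(unique(cohort$group)))
  summ <- do.call(rbind, lapply(split(cohort$rate, cohort$group), function(r)
    data.frame(n = length(r), mean_rate = mean(r), sd_rate = stats::sd(r))))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  kw <- stats::kruskal.test(rate ~ group, data = cohort)
  pw_holm <- stats::pairwise.wilcox.test(cohort$rate, cohort$group,
                                         p.adjust.method = "holm",
                                         exact = FALSE)
  pw_none <- stats::pairwise.wilcox.test(cohort$rate, cohort$group,
                                         p.adjust.method = "none",
                                         exact = FALSE)
  list(summary = summ, kruskal_p = kw$p.value,
       pairwise_p_holm = pw_holm$p.value,
       pairwise_p_unadjusted = pw_none$p.value)
}

#' Rank and linear trend tests of rate versus age
#'
#' Spearman correlation of rate with age and the ordinary least-squares
#' slope of rate on age, with two-sided p-values. A Shapiro-Wilk
#' normality p-value for the rates is reported alongside (capped at
#' n = 5000, the test's supported range); both parametric and rank
#' statistics are always computed rather than auto-switching.
#'
#' @inheritParams group_summary
#' @return List with `spearman_rho`, `spearman_p`, `slope`, `slope_p`,
#'   `slope_ci` (95%), `pearson_r`, `pearson_p`, `shapiro_p`, `n`.
#' @export
trend_tests <- function(cohort, sex = NULL) {
  cohort <- check_cohort(cohort, sex)
  if (nrow(cohort) < 10L) stop_lipdesq("need at least 10 records")
  rho <- p_rho <- NA_real_
  if (stats::sd(cohort$rate) > 0) {
    st <- stats::cor.test(cohort$age, cohort$rate, method = "spearman",
                          exact = FALSE)
    rho <- unname(st$estimate); p_rho <- st$p.value
  }
  pr <- p_pr <- NA_real_
  if (stats::sd(cohort$rate) > 0) {
    pt <- stats::cor.test(cohort$age, cohort$rate, method = "pearson")
    pr <- unname(pt$estimate); p_pr <- pt$p.value
  }
  fit <- stats::lm(rate ~ age, data = cohort)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["age", ]
  sw <- tryCatch(stats::shapiro.test(
    if (nrow(cohort) > 5000) sample(cohort$rate, 5000) else cohort$rate)$p.value,
    error = function(e) NA_real_)
  list(spearman_rho = rho, spearman_p = p_rho,
       slope = unname(sm["age", "Estimate"]),
       slope_p = unname(sm["age", "Pr(>|t|)"]),
       slope_ci = unname(ci),
       pearson_r = pr, pearson_p = p_pr,
       shapiro_p = sw, n = nrow(cohort))
}

#' Local-regression trend of rate versus age
#'
#' Locally weighted regression (loess, degree 2) of rate on age,
#' evaluated at every integer age in the observed range; used to
#' visualize nonlinear age trends such as the mid-life peak in females.
#'
#' @inheritParams group_summary
#' @param span Loess span in `(0, 1]` (default 0.75).
#' @return Data frame with columns `age` and `fitted`.
#' @export
local_trend <- function(cohort, sex = NULL, span = 0.75) {
  cohort <- check_cohort(cohort, sex)
  if (nrow(cohort) < 20L) stop_lipdesq("need at least 20 records")
  if (!is_scalar_number(span) || span <= 0 || span > 1)
    stop_lipdesq("span must lie in (0, 1]")
  fit <- stats::loess(rate ~ age, data = cohort, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  ages <- seq(min(cohort$age), max(cohort$age))
  data.frame(age = ages,
             fitted = stats::predict(fit, newdata = data.frame(age = ages)))
}

slope_of <- function(d) {
  if (nrow(d) < 2L || stats::sd(d$age) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(rate ~ age, data = d))[2])
}

#' Scan for the age at which the rate-versus-age slope changes
#'
#' For every candidate age `a` that leaves at least `min_side_n` records
#' on each side, fits a model with separate slopes below and above the
#' candidate and tests the slope difference. The default is the single
#' continuous piecewise (segmented) regression
#' `rate ~ age + pmax(age - a, 0)`, with the t-test on the slope-change
#' term; fitting the two segments independently and z-testing the slope
#' difference is available as an alternative.
#' The breakpoint is the candidate with the smallest p-value (ties break
#' toward the younger age). Because the scan performs one test per
#' candidate age, the reported significance is Bonferroni-adjusted for
#' the number of candidates.
#'
#' @inheritParams group_summary
#' @param min_side_n Minimum records required on each side of a candidate
#'   split (default 30).
#' @param age_range Optional length-2 vector restricting the scanned ages.
#' @param method `"piecewise"` (default) or `"separate"`.
#' @param alpha Significance level for the adjusted minimum p (default
#'   0.05).
#' @return An object of class `inflection_result`: `breakpoint_age`,
#'   `slope_before`, `slope_after`, `p_by_age` (named vector), `min_p`,
#'   `p_adjusted`, `significant`, `n_candidates`, `method`.
#' @export
find_inflection <- function(cohort, sex = NULL, min_side_n = 30,
                            age_range = NULL,
                            method = c("piecewise", "separate"),
                            alpha = 0.05) {
  method <- match.arg(method)
  cohort <- check_cohort(cohort, sex)
  ages <- sort(unique(cohort$age))
  cand <- ages[vapply(ages, function(a)
    sum(cohort$age < a) >= min_side_n && sum(cohort$age >= a) >= min_side_n,
    logical(1))]
  if (!is.null(age_range))
    cand <- cand[cand >= age_range[1] & cand <= age_range[2]]
  if (!length(cand))
    stop_lipdesq("no candidate age leaves ", min_side_n,
                 " records on both sides")

  p_by_age <- vapply(cand, function(a) {
    if (method == "piecewise") {
      hinge <- pmax(cohort$age - a, 0)
      fit <- stats::lm(rate ~ age + hinge, data = cohort)
      sm <- suppressWarnings(summary(fit))$coefficients
      est <- sm["hinge", "Estimate"]; p <- sm["hinge", "Pr(>|t|)"]
      if (!is.finite(p)) p <- if (abs(est) > 1e-12) 0 else 1
      p
    } else {
      lo <- cohort[cohort$age < a, ]; hi <- cohort[cohort$age >= a, ]
      f1 <- stats::lm(rate ~ age, data = lo)
      f2 <- stats::lm(rate ~ age, data = hi)
      b1 <- stats::coef(f1)[2]; b2 <- stats::coef(f2)[2]
      se <- sqrt(summary(f1)$coefficients[2, "Std. Error"]^2 +
                 summary(f2)$coefficients[2, "Std. Error"]^2)
      if (se == 0) return(if (abs(b1 - b2) > 1e-12) 0 else 1)
      2 * stats::pnorm(-abs((b1 - b2) / se))
    }
  }, numeric(1))
  names(p_by_age) <- cand

  best <- cand[which.min(p_by_age)]   # which.min takes the first (youngest) tie
  min_p <- min(p_by_age)
  structure(list(
    breakpoint_age = best,
    slope_before = slope_of(cohort[cohort$age < best, ]),
    slope_after = slope_of(cohort[cohort$age >= best, ]),
    p_by_age = p_by_age,
    min_p = min_p,
    p_adjusted = min(1, min_p * length(cand)),
    significant = min(1, min_p * length(cand)) < alpha,
    n_candidates = length(cand),
    method = method), class = "inflection_result")
}

#' @export
print.inflection_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<inflection_result> breakpoint at age %d (adj. p = %.3g%s)\n",
    "slopes: %.4f before, %.4f after (%d candidates, %s test)\n"),
    x$breakpoint_age, x$p_adjusted,
    if (x$significant) ", significant" else ", not significant",
    x$slope_before, x$slope_after, x$n_candidates, x$method))
  invisible(x)
}

#' Read a cohort CSV
#'
#' @param path CSV with columns `subject_id`, `age`, `sex`, `rate`.
#' @param age_range Permitted age range (default 20--69).
#' @return Data frame.
#' @export
read_cohort <- function(path, age_range = c(20, 69)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "rate")
  if (!all(need %in% names(d)))
    stop_lipdesq("cohort CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(d) == 0L) stop_lipdesq("cohort CSV is empty")
  if (any(d$age < age_range[1] | d$age > age_range[2]))
    warning("ages outside the configured range ", age_range[1], "-",
            age_range[2], call. = FALSE)
  check_cohort(d)
}
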