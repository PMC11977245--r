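make_cohort <- function(rate_fn, ages = 20:69, n_per_age = 4,
                        sex = "female", noise_sd = 0, seed = 1) {
  age <- rep(ages, each = n_per_age)
  rate <- lipdesq:::with_local_seed(seed,
    pmax(0, rate_fn(age) + stats::rnorm(length(age), 0, noise_sd)))
  data.frame(subject_id = seq_along(age), age = age, sex = sex, rate = rate)
}

test_that("rate normalization is a min-max map to [0, 1]", {
  expect_equal(normalize_rates(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(normalize_rates(x), x)                      # idempotent
  expect_equal(normalize_rates(3 * x + 7), normalize_rates(x))  # affine-invariant
  expect_error(normalize_rates(rep(2, 5)), "constant")
  expect_error(normalize_rates(1), "2 subjects")
})

test_that("method comparison reproduces textbook Pearson and MSE formulas", {
  va <- c(0, 1, 2, 3, 4)
  expect_equal(compare_to_va(0.1 + 0.2 * va, va)$r, 1)
  expect_lt(compare_to_va(0.1 + 0.2 * va, va)$mse, 1e-20)

  rates <- c(0.42, 0.17, 0.89, 0.33, 0.55, 0.21, 0.74, 0.06, 0.61, 0.48)
  va10 <- c(1, 0, 3, 1, 2, 1, 3, 0, 2, 2)
  cmp <- compare_to_va(rates, va10)
  # independent closed-form computation
  r_manual <- sum((rates - mean(rates)) * (va10 - mean(va10))) /
    sqrt(sum((rates - mean(rates))^2) * sum((va10 - mean(va10))^2))
  y <- (rates - min(rates)) / diff(range(rates))
  b <- sum((va10 - mean(va10)) * (y - mean(y))) / sum((va10 - mean(va10))^2)
  a <- mean(y) - b * mean(va10)
  mse_manual <- mean((y - a - b * va10)^2)
  expect_equal(cmp$r, r_manual, tolerance = 1e-9)
  expect_equal(cmp$mse, mse_manual, tolerance = 1e-9)
  expect_equal(cmp$slope, b, tolerance = 1e-9)

  perm <- sample(10)
  cmp2 <- compare_to_va(rates[perm], va10[perm])
  expect_equal(cmp2$r, cmp$r)
  expect_equal(cmp2$mse, cmp$mse)

  expect_error(compare_to_va(rep(1, 5), va), "zero variance")
})

test_that("decade summaries run Kruskal-Wallis and pairwise Wilcoxon", {
  coh <- make_cohort(function(a) 0.5 + 0.4 * (a >= 40), noise_sd = 0.05,
                     seed = 3)
  gs <- group_summary(coh)
  expect_equal(gs$summary$group, c("20s", "30s", "40s", "50s", "60s"))
  expect_lt(gs$kruskal_p, 1e-6)
  expect_lt(gs$pairwise_p_holm["40s", "30s"], 0.001)
  expect_gt(gs$pairwise_p_unadjusted["30s", "20s"], 0.05)

  one <- coh[coh$age < 30, ]
  expect_error(group_summary(one), "2 age groups")
  tiny <- coh[c(which(coh$age < 40), which(coh$age == 45)[1]), ]
  expect_warning(group_summary(tiny), "fewer than 2")
})

test_that("trend tests recover exact linear structure", {
  coh <- make_cohort(function(a) 0.01 * a)
  tt <- suppressWarnings(trend_tests(coh))
  expect_equal(tt$slope, 0.01, tolerance = 1e-12)
  expect_equal(tt$spearman_rho, 1)

  rev_coh <- coh
  rev_coh$age <- max(coh$age) + min(coh$age) - coh$age
  expect_equal(suppressWarnings(trend_tests(rev_coh))$spearman_rho, -1)
  expect_error(trend_tests(coh[1:5, ]), "10 records")
})

test_that("null slopes are covered by the confidence interval", {
  hits <- 0L
  for (i in 1:40) {
    coh <- make_cohort(function(a) rep(0.5, length(a)), noise_sd = 0.1,
                       seed = 100 + i, n_per_age = 2)
    ci <- trend_tests(coh)$slope_ci
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # 95% CI should cover 0 in at least 90% of nulls
})

test_that("local regression reproduces lines and recovers planted peaks", {
  lin <- make_cohort(function(a) 0.2 + 0.01 * a)
  lt <- local_trend(lin)
  interior <- lt$age > 25 & lt$age < 64
  expect_equal(lt$fitted[interior], (0.2 + 0.01 * lt$age)[interior],
               tolerance = 1e-6)

  peaked <- make_cohort(function(a) ifelse(a <= 42, 0.2 + 0.02 * (a - 20),
                                           0.64 - 0.01 * (a - 42)),
                        noise_sd = 0.05, seed = 7, n_per_age = 6)
  lt2 <- local_trend(peaked, span = 0.5)
  expect_lte(abs(lt2$age[which.max(lt2$fitted)] - 42), 3)

  rough <- function(x) sum(diff(diff(x))^2)
  expect_lte(rough(local_trend(peaked, span = 1)$fitted),
             rough(local_trend(peaked, span = 0.3)$fitted))
  expect_error(local_trend(lin, span = 0), "span")
  expect_error(local_trend(lin[1:10, ], span = 0.5), "20 records")
})

test_that("a noiseless V-shaped trend yields its vertex as the breakpoint", {
  v <- make_cohort(function(a) abs(a - 45) * 0.02 + 0.1, n_per_age = 4)
  infl <- suppressWarnings(find_inflection(v, min_side_n = 20))
  expect_equal(infl$breakpoint_age, 45)
  expect_true(infl$significant)
  expect_equal(infl$slope_before, -0.02, tolerance = 1e-10)
  expect_equal(infl$slope_after, 0.02, tolerance = 1e-10)
})

test_that("the breakpoint scan is invariant to record order and rate scale", {
  coh <- make_cohort(function(a) ifelse(a <= 38, 0.217 + 0.019 * (a - 20),
                                        0.559 - 0.005 * (a - 38)),
                     noise_sd = 0.1, seed = 11, n_per_age = 10)
  infl <- find_inflection(coh)
  shuffled <- coh[sample(nrow(coh)), ]
  infl2 <- find_inflection(shuffled)
  expect_equal(infl2$breakpoint_age, infl$breakpoint_age)
  expect_equal(infl2$p_by_age, infl$p_by_age)

  scaled <- coh
  scaled$rate <- 3 * coh$rate + 5
  infl3 <- find_inflection(scaled)
  expect_equal(infl3$breakpoint_age, infl$breakpoint_age)
  expect_equal(infl3$p_by_age, infl$p_by_age, tolerance = 1e-9)
  expect_equal(infl3$slope_before, 3 * infl$slope_before, tolerance = 1e-9)

  # the default female trend parameters localize near the planted break
  expect_lte(abs(infl$breakpoint_age - 38), 3)

  expect_error(find_inflection(coh[coh$age < 25, ], min_side_n = 30),
               "no candidate")
})

test_that("the two-fit z-test alternative agrees on strong breaks", {
  coh <- make_cohort(function(a) ifelse(a <= 40, 0.01 * (a - 20),
                                        0.2 - 0.01 * (a - 40)),
                     noise_sd = 0.05, seed = 5, n_per_age = 8)
  i1 <- find_inflection(coh, method = "piecewise")
  i2 <- find_inflection(coh, method = "separate")
  expect_lte(abs(i1$breakpoint_age - 40), 3)
  expect_lte(abs(i2$breakpoint_age - 40), 3)
  expect_true(i1$significant && i2$significant)
})

test_that("cohort CSVs validate their schema on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  coh <- make_cohort(function(a) 0.4 + 0 * a)
  utils::write.csv(coh, path, row.names = FALSE)
  expect_equal(nrow(read_cohort(path)), nrow(coh))
  utils::write.csv(coh[, c("age", "rate")], path, row.names = FALSE)
  expect_error(read_cohort(path), "must have columns")
  utils::write.csv(coh[0, ], path, row.names = FALSE)
  expect_error(read_cohort(path), "empty")
})
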