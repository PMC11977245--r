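test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_flake_image(flake_image_spec(seed = 7))
  b <- generate_flake_image(flake_image_spec(seed = 7))
  expect_identical(a$gray, b$gray)
  expect_identical(a$mask, b$mask)
  c1 <- generate_trend_cohort(cohort_spec(seed = 3))
  c2 <- generate_trend_cohort(cohort_spec(seed = 3))
  expect_identical(c1, c2)
  expect_false(identical(
    generate_flake_image(flake_image_spec(seed = 8))$gray, a$gray))
})

test_that("planted flake area tracks the requested fraction", {
  empty <- generate_flake_image(flake_image_spec(flake_area_fraction = 0,
                                                 seed = 2))
  expect_false(any(empty$mask))

  sim <- generate_flake_image(flake_image_spec(flake_area_fraction = 0.02,
                                               seed = 7))
  got <- mean(sim$mask)
  expect_gte(got, 0.018)
  expect_lte(got, 0.022)

  expect_error(flake_image_spec(flake_area_fraction = 0.5), "\\[0, 0.2\\]")
  expect_error(flake_image_spec(width = 16, height = 150, n_flakes = 1,
                                flake_area_fraction = 0.2),
               "infeasible packing")
})

test_that("invisible flakes leave only the false-positive floor", {
  sim <- generate_flake_image(flake_image_spec(flake_contrast = 0, seed = 4))
  g <- sim$gray
  rate <- desquamation_rate(segment_flakes(g, compute_threshold(g, 2.5)))$rate
  expect_lte(rate, 0.3)
})

test_that("generated lip histograms are long-tailed unimodal", {
  for (f in c(0.01, 0.02, 0.05)) for (seed in 1:4) {
    g <- generate_flake_image(flake_image_spec(flake_area_fraction = f,
                                               seed = seed))$gray
    expect_equal(count_histogram_modes(g), 1L)
    # long right tail: bright extreme lies farther from the mean than dark
    expect_gt(max(g) - mean(g), mean(g) - min(g))
  }
})

test_that("face fixtures reproduce the bare lip-region measurement", {
  sp <- flake_image_spec(seed = 13, flake_area_fraction = 0.03)
  fix <- generate_face_fixture(sp)
  bare <- generate_flake_image(sp)
  res_fix <- quantify(fix$image, fix$landmarks)
  spec <- compute_threshold(bare$gray)
  res_bare <- desquamation_rate(segment_flakes(bare$gray, spec), spec)
  expect_equal(res_fix$rate, res_bare$rate, tolerance = 0.05)

  shifted <- generate_face_fixture(sp, x0 = 60L, y0 = 52L)
  expect_equal(quantify(shifted$image, shifted$landmarks)$rate, res_fix$rate)

  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(fix$landmarks, path)
  expect_equal(unclass(extract_target_region(read_landmarks(path))),
               unclass(fix$roi))

  expect_error(generate_face_fixture(sp, frame_width = 100L), "outside")
})

test_that("VA cohorts link severity, flake fraction and rater scores", {
  quiet <- generate_va_cohort(n_subjects = 12, rater_noise_sd = 0,
                              seed = 5)
  expect_equal(inter_rater_reliability(quiet$scores)$mean_r, 1)

  coh <- generate_va_cohort(n_subjects = 55, seed = 1)
  irr <- inter_rater_reliability(coh$scores)$mean_r
  expect_gte(irr, 0.7)
  expect_lte(irr, 0.95)
  expect_gt(stats::cor(coh$subjects$va_final, coh$subjects$true_fraction,
                       method = "spearman"), 0.8)
  expect_error(generate_va_cohort(n_subjects = 5), "10 subjects")
})

test_that("trend cohorts follow the piecewise-linear age structure", {
  spec <- cohort_spec(noise_sd = 0)
  coh <- generate_trend_cohort(spec)
  expect_equal(nrow(coh), 1000L)
  expect_equal(sum(coh$sex == "female"), 500L)

  at_break <- coh$rate[coh$sex == "female" & coh$age == 38][1]
  expect_equal(at_break, 0.217 + 0.019 * 18, tolerance = 1e-12)  # 0.559
  at20 <- coh$rate[coh$sex == "female" & coh$age == 20][1]
  expect_equal(at20, 0.217, tolerance = 1e-12)

  expect_equal(mean(coh$rate[coh$sex == "male"]), 0.440, tolerance = 1e-12)

  flat <- generate_trend_cohort(cohort_spec(male_slope = 0, noise_sd = 0,
                                            male_mean_rate = 0.44))
  expect_equal(stats::sd(flat$rate[flat$sex == "male"]), 0)

  expect_error(cohort_spec(female_rate_at_20 = 0.01, female_slope_before = -0.05),
               "negative")
})
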