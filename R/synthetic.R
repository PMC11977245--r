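# Ground-truthed synthetic data: lip-region images with planted flakes,
# whole-frame fixtures with landmarks, VA-linked calibration cohorts and
# age/sex trend cohorts. Everything is deterministic under a single
# per-call seed; nested generators draw their sub-seeds through
# derive_seed() so that per-item streams are independent.

#' Specification for a synthetic lip-region image
#'
#' The generated image emulates the grayscale structure of a cropped
#' lower-lip region: a spatially correlated texture field bounded well
#' below the SD-outlier threshold, vertical wrinkle ridges whose crests
#' carry a narrow band of specular gloss, and bright desquamated flakes
#' planted as flat-topped, soft-edged, irregular elliptical blobs. The
#' pooled histogram is unimodal with a long right tail - the regime in
#' which bimodal-assuming global thresholds fail.
#'
#' @param width,height Image dimensions in pixels.
#' @param background_mean,background_sd Mean and standard deviation of
#'   the background texture in grayscale units.
#' @param texture_correlation_length Gaussian correlation length of the
#'   texture in pixels.
#' @param n_flakes Nominal number of flakes the target area is divided
#'   into (individual sizes are jittered).
#' @param flake_area_fraction Target fraction of the image covered by
#'   flakes, in `[0, 0.2]`.
#' @param flake_contrast Flake brightness above the background mean, in
#'   multiples of `background_sd`.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return An object of class `flake_image_spec`.
#' @export
flake_image_spec <- function(width = 160L, height = 120L,
                             background_mean = 120, background_sd = 10,
                             texture_correlation_length = 4,
                             n_flakes = 8L, flake_area_fraction = 0.02,
                             flake_contrast = 5, seed = 1L) {
  if (flake_area_fraction < 0 || flake_area_fraction > 0.2)
    stop_lipdesq("flake_area_fraction must lie in [0, 0.2]")
  if (flake_contrast < 0) stop_lipdesq("flake_contrast must be >= 0")
  if (width < 16 || height < 16) stop_lipdesq("image must be at least 16x16")
  target <- flake_area_fraction * width * height
  if (n_flakes >= 1 && target / n_flakes > (min(width, height) / 3)^2 * pi)
    stop_lipdesq("infeasible packing: flakes too large for the image")
  structure(list(width = as.integer(width), height = as.integer(height),
                 background_mean = background_mean,
                 background_sd = background_sd,
                 texture_correlation_length = texture_correlation_length,
                 n_flakes = as.integer(n_flakes),
                 flake_area_fraction = flake_area_fraction,
                 flake_contrast = flake_contrast,
                 seed = as.integer(seed)),
            class = "flake_image_spec")
}

# Periodic Gaussian-smoothed white noise, standardized to mean 0, sd 1.
smooth_noise_field <- function(h, w, corlen) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (corlen > 0) {
    fy <- c(0:(floor(h / 2)), -((ceiling(h / 2) - 1):1)) / h
    fx <- c(0:(floor(w / 2)), -((ceiling(w / 2) - 1):1)) / w
    G <- outer(exp(-2 * (pi * corlen * fy)^2), exp(-2 * (pi * corlen * fx)^2))
    z <- Re(stats::fft(stats::fft(z) * G, inverse = TRUE)) / length(z)
  }
  (z - mean(z)) / stats::sd(z)
}

# Bounded background marginal: the bulk of the standardized texture+ridge
# field keeps its bell shape up to 1.45 sd; the next stretch is thinned
# (matte-to-gloss transition) and the extreme upper quantiles - ridge
# crests - collapse onto a narrow specular "gloss shelf" just below
# 2.5 population-sd, so the flake-free background never crosses the
# k = 2.5 outlier threshold.
gloss_shelf_map <- function(z) {
  az <- abs(z)
  y <- ifelse(az <= 1.45, az,
       ifelse(az <= 2.05, 1.45 + (az - 1.45) * 0.25,
              2.17 + 0.08 * tanh(az - 2.05)))
  sign(z) * y
}

# Fixed reddish lip tone whose BT.601 luma is exactly 1, so the
# grayscale conversion recovers the generated intensity field.
lip_tone <- local({
  tone <- c(1.15, 0.95, 0.85)
  tone / sum(tone * c(0.299, 0.587, 0.114))
})

gray_to_lip_rgb <- function(gray) {
  d <- dim(gray)
  rgb <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) rgb[, , ch] <- clamp(gray * lip_tone[ch], 0, 255)
  rgb
}

#' Generate a synthetic lip-region image with ground truth
#'
#' See [flake_image_spec()] for the image model. The returned mask marks
#' flake interiors (inside the perturbed elliptical boundary); flake
#' edges decay softly over about 1.4 px centred on that boundary. The
#' realized flake area is kept within 10% of the requested fraction
#' whenever geometry permits.
#'
#' @param spec A [flake_image_spec()].
#' @return List with `image` (RGB array, `[0, 255]`), `gray` (the
#'   underlying intensity field), `mask` (logical ground-truth flake
#'   mask) and `spec`.
#' @export
generate_flake_image <- function(spec = flake_image_spec()) {
  stopifnot(inherits(spec, "flake_image_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    z <- smooth_noise_field(h, w, spec$texture_correlation_length)

    # wrinkle ridges: bright, slightly curved near-vertical lines
    n_ridges <- stats::rpois(1, 12) + 2L
    xx <- matrix(rep(seq_len(w), each = h), h, w)
    yy <- matrix(rep(seq_len(h), w), h, w)
    for (i in seq_len(n_ridges)) {
      x0 <- stats::runif(1, 1, w)
      amp <- stats::runif(1, 1, 2.8)
      wid <- stats::runif(1, 0.8, 1.8)
      bend <- stats::runif(1, -6, 6)
      ph <- stats::runif(1, 0, 2 * pi)
      xc <- x0 + bend * sin(2 * pi * yy / h + ph)
      z <- z + amp * exp(-((xx - xc)^2) / (2 * wid^2))
    }
    z <- gloss_shelf_map((z - mean(z)) / stats::sd(z))
    z <- (z - mean(z)) / stats::sd(z)
    gray <- spec$background_mean + spec$background_sd * z

    mask <- matrix(FALSE, h, w)
    target <- spec$flake_area_fraction * h * w
    if (target > 0 && spec$flake_contrast >= 0 && spec$n_flakes >= 1) {
      r0 <- sqrt(max(4, target / spec$n_flakes) / pi)
      edge_width <- 0.7
      occlusion <- 0.92       # flakes mostly occlude the texture beneath
      guard <- 0L
      while (sum(mask) < 0.92 * target && guard < 4000L) {
        guard <- guard + 1L
        a <- r0 * stats::runif(1, 0.75, 1.35)
        b <- r0 * stats::runif(1, 0.65, 1.2)
        phi <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
        ci <- spec$flake_contrast * stats::runif(1, 0.8, 1.15)
        cm <- stats::runif(3, 0, 0.12); ps <- stats::runif(3, 0, 2 * pi)
        ext <- ceiling(max(a, b) * 1.15 + edge_width + 2)
        xs <- max(1, floor(cx - ext)):min(w, ceiling(cx + ext))
        ys <- max(1, floor(cy - ext)):min(h, ceiling(cy + ext))
        dx <- outer(rep(1, length(ys)), xs - cx)
        dy <- outer(ys - cy, rep(1, length(xs)))
        u <- (dx * cos(phi) + dy * sin(phi)) / a
        v <- (-dx * sin(phi) + dy * cos(phi)) / b
        rho <- sqrt(u^2 + v^2)
        th <- atan2(v, u)
        # irregular boundary: low-order Fourier perturbation of the radius
        rb <- 1 + cm[1] * cos(2 * th + ps[1]) + cm[2] * cos(3 * th + ps[2]) +
          cm[3] * cos(4 * th + ps[3])
        dpx <- (rho / rb - 1) * sqrt(a * b) * rb   # signed px distance
        wgt <- clamp(0.5 - dpx / edge_width, 0, 1) # 0.5 at the boundary
        new_px <- dpx <= 0 & !mask[ys, xs]
        if (sum(mask) + sum(new_px) > 1.12 * target && sum(mask) >= 0.9 * target)
          break
        base <- gray[ys, xs]
        gray[ys, xs] <- base * (1 - occlusion * wgt) +
          (spec$background_mean + ci * spec$background_sd) * occlusion * wgt +
          (1 - occlusion) * ci * spec$background_sd * wgt
        mask[ys, xs] <- mask[ys, xs] | dpx <= 0
      }
    }
    gray <- clamp(gray, 0, 255)
    list(image = gray_to_lip_rgb(gray), gray = gray, mask = mask, spec = spec)
  })
}

#' Generate a whole-frame fixture with landmarks
#'
#' Embeds a generated lip region into a larger neutral frame and emits
#' the eight lower-lip landmarks positioned so that
#' [extract_target_region()] recovers exactly the embedded region.
#'
#' @param spec A [flake_image_spec()] for the embedded lip region.
#' @param frame_width,frame_height Frame dimensions in pixels.
#' @param x0,y0 Top-left corner (0-based pixels) of the embedded region;
#'   must leave a 4 px margin inside the frame.
#' @return List with `image` (RGB frame), `landmarks` ([landmark_set()]),
#'   `mask` (ground truth within the lip region), `roi` and `spec`.
#' @export
generate_face_fixture <- function(spec = flake_image_spec(),
                                  frame_width = spec$width + 80L,
                                  frame_height = spec$height + 80L,
                                  x0 = 40L, y0 = 40L) {
  lipres <- generate_flake_image(spec)
  w <- spec$width; h <- spec$height
  if (x0 < 0 || y0 < 4 || x0 + w > frame_width || y0 + h + 4 > frame_height)
    stop_lipdesq("lip region placement falls outside the frame")
  frame_gray <- with_local_seed(derive_seed(spec$seed, 7777L),
    matrix(140 + stats::rnorm(frame_height * frame_width, 0, 2),
           frame_height, frame_width))
  frame <- gray_to_lip_rgb(clamp(frame_gray, 0, 255))
  rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
  frame[rows, cols, ] <- lipres$image

  pts <- rbind(
    `14` = c(x0 + w / 2, y0 - 3),
    `15` = c(x0 + w / 2, y0 + 3),
    `16` = c(x0 + w / 2, y0 + h - 3),
    `17` = c(x0 + w / 2, y0 + h + 3),
    `84` = c(x0, y0 + h / 2),
    `87` = c(x0 + w, y0 + h / 2),
    `314` = c(x0 + 0.1 * w, y0 + h / 2),
    `317` = c(x0 + 0.9 * w, y0 + h / 2))
  colnames(pts) <- c("x", "y")
  lm <- landmark_set(pts, frame_width, frame_height)
  list(image = frame, landmarks = lm, mask = lipres$mask,
       roi = lip_roi(x0, y0, w, h), spec = spec)
}

#' Generate a VA-linked calibration cohort
#'
#' Emulates the calibration study design: each subject has a latent
#' desquamation severity, a flake-area fraction monotone in that
#' severity, a generated lip image, and integer scores from several
#' raters formed by discretizing the severity under independent Gaussian
#' noise.
#'
#' @param n_subjects Number of subjects (default 55).
#' @param n_raters Number of raters (default 5).
#' @param rater_noise_sd Rater noise standard deviation on the 0-4 scale
#'   (default 0.5, matching inter-rater correlations around 0.8).
#' @param severity_range Range of the uniform latent severity (default
#'   0.3 to 3.7, covering the predominantly 1-3 observed scores).
#' @param fraction_per_score Flake-area fraction added per severity unit
#'   (default 0.002: severity 2 gives 0.4% flake coverage).
#' @param image_spec Template [flake_image_spec()]; its fraction and seed
#'   are overridden per subject.
#' @param seed Integer seed.
#' @return List with `subjects` (data frame: subject_id, severity,
#'   true_fraction, va_final), `scores` (subjects x raters matrix) and
#'   `images` (list of [generate_flake_image()] results).
#' @export
generate_va_cohort <- function(n_subjects = 55L, n_raters = 5L,
                               rater_noise_sd = 0.5,
                               severity_range = c(0.3, 3.7),
                               fraction_per_score = 0.002,
                               image_spec = flake_image_spec(),
                               seed = 1L) {
  if (n_subjects < 10L) stop_lipdesq("need at least 10 subjects")
  severity <- with_local_seed(derive_seed(seed, 1L),
    stats::runif(n_subjects, severity_range[1], severity_range[2]))
  fraction <- fraction_per_score * severity
  scores <- with_local_seed(derive_seed(seed, 2L),
    matrix(clamp(round(severity + stats::rnorm(n_subjects * n_raters,
                                               0, rater_noise_sd)), 0, 4),
           n_subjects, n_raters))
  colnames(scores) <- paste0("rater", seq_len(n_raters))
  images <- lapply(seq_len(n_subjects), function(i) {
    sp <- image_spec
    sp$flake_area_fraction <- fraction[i]
    sp$seed <- derive_seed(seed, 100L + i)
    generate_flake_image(sp)
  })
  list(subjects = data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                             severity = severity,
                             true_fraction = fraction,
                             va_final = final_scores(scores)),
       scores = scores, images = images)
}

#' Specification for a synthetic age/sex trend cohort
#'
#' Defaults reproduce the fitted cohort structure: equal numbers of men
#' and women at every integer age 20-69 (10 per age and sex for n = 500
#' each); female expected rates rise at 0.019 percentage points per year
#' from 0.217% at age 20 up to a breakpoint at 38, then decline at
#' 0.005 per year; male expected rates decline linearly at 0.005 per
#' year with the intercept set so that the male mean is 0.440%.
#' Gaussian noise (sd 0.1) is added and rates are truncated at zero.
#'
#' @param n_per_age Subjects per integer age per sex.
#' @param ages Integer age range.
#' @param female_breakpoint Female breakpoint age.
#' @param female_slope_before,female_slope_after Female slopes
#'   (percentage points per year) below and above the breakpoint.
#' @param female_rate_at_20 Female expected rate at age 20 (percent).
#' @param male_slope Male slope (percentage points per year).
#' @param male_mean_rate Male mean rate (percent) used to place the male
#'   intercept.
#' @param noise_sd Gaussian noise sd (percentage points).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_age = 10L, ages = 20:69,
                        female_breakpoint = 38L,
                        female_slope_before = 0.019,
                        female_slope_after = -0.005,
                        female_rate_at_20 = 0.217,
                        male_slope = -0.005,
                        male_mean_rate = 0.440,
                        noise_sd = 0.1, seed = 1L) {
  spec <- structure(list(n_per_age = as.integer(n_per_age), ages = ages,
                         female_breakpoint = female_breakpoint,
                         female_slope_before = female_slope_before,
                         female_slope_after = female_slope_after,
                         female_rate_at_20 = female_rate_at_20,
                         male_slope = male_slope,
                         male_mean_rate = male_mean_rate,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "cohort_spec")
  if (any(expected_trend_rate(spec, spec$ages, "female") < 0) ||
      any(expected_trend_rate(spec, spec$ages, "male") < 0))
    stop_lipdesq("expected rates become negative over the age range")
  spec
}

#' Expected (noise-free) rate of a trend-cohort specification
#'
#' @param spec A [cohort_spec()].
#' @param age Numeric vector of ages.
#' @param sex `"male"` or `"female"`.
#' @return Expected desquamation rate in percent.
#' @export
expected_trend_rate <- function(spec, age, sex) {
  if (sex == "female") {
    peak <- spec$female_rate_at_20 +
      spec$female_slope_before * (spec$female_breakpoint - 20)
    ifelse(age <= spec$female_breakpoint,
           spec$female_rate_at_20 + spec$female_slope_before * (age - 20),
           peak + spec$female_slope_after * (age - spec$female_breakpoint))
  } else {
    male_rate_at_20 <- spec$male_mean_rate -
      spec$male_slope * (mean(spec$ages) - 20)
    male_rate_at_20 + spec$male_slope * (age - 20)
  }
}

#' Generate a synthetic age/sex trend cohort
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with columns `subject_id`, `age`, `sex`, `rate`.
#' @export
generate_trend_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- expand.grid(rep = seq_len(spec$n_per_age), age = spec$ages,
                      sex = c("male", "female"), stringsAsFactors = FALSE)
  mu <- ifelse(grid$sex == "female",
               expected_trend_rate(spec, grid$age, "female"),
               expected_trend_rate(spec, grid$age, "male"))
  rate <- with_local_seed(spec$seed,
    pmax(0, mu + stats::rnorm(nrow(grid), 0, spec$noise_sd)))
  data.frame(subject_id = sprintf("C%04d", seq_len(nrow(grid))),
             age = grid$age, sex = grid$sex, rate = rate)
}
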