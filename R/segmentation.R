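# Core segmentation: grayscale conversion, SD-outlier threshold, binary
# flake mask and the desquamation rate.

#' Convert an RGB raster to grayscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299, 0.587, 0.114), the common
#' default of image-processing toolchains. The weights are fixed constants
#' so that results are reproducible across sessions. Intensities are kept
#' as reals on the `[0, 255]` scale; no re-quantization is applied.
#'
#' @param rgb Numeric array `height x width x 3` with values in `[0, 255]`.
#'   A matrix (already single-channel) is passed through with a note.
#' @return Numeric matrix of grayscale intensities in `[0, 255]`.
#' @export
to_grayscale <- function(rgb) {
  if (is.matrix(rgb)) {
    message("input is already single-channel; passing through unchanged")
    return(rgb)
  }
  d <- dim(rgb)
  if (length(d) != 3L || d[3] < 3L)
    stop_lipdesq("expected an RGB array (height x width x 3)")
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Grayscale luma weights
#'
#' The fixed BT.601 red/green/blue weights used by [to_grayscale()].
#' @export
grayscale_weights <- c(r = 0.299, g = 0.587, b = 0.114)

#' Construct a threshold specification
#'
#' Bundles the statistics behind a global threshold `T`. For the
#' SD-outlier method, `T = mean + k * sd` with `mean` and `sd` the
#' population statistics of the analyzed region. For externally supplied
#' or histogram-based thresholds, `mean`, `sd` and `k` may be `NA`.
#'
#' @param mean,sd Population mean and standard deviation of the pixel
#'   intensities (grayscale units), or `NA`.
#' @param k Dimensionless multiplier, or `NA`.
#' @param T Threshold in grayscale units. If omitted it is computed as
#'   `mean + k * sd`.
#' @param method Descriptor of how the threshold was obtained.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mean = NA_real_, sd = NA_real_, k = NA_real_,
                           T = mean + k * sd, method = "sd_outlier") {
  if (!is.na(sd) && sd < 0) stop_lipdesq("sd must be >= 0")
  if (!is.finite(T)) stop_lipdesq("threshold T must be a finite number")
  structure(list(mean = mean, sd = sd, k = k, T = T, method = method),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  if (identical(x$method, "sd_outlier"))
    cat(sprintf("<threshold_spec> T = %.3f (mean %.3f + %.2f * sd %.3f)\n",
                x$T, x$mean, x$k, x$sd))
  else
    cat(sprintf("<threshold_spec> T = %.3f (%s)\n", x$T, x$method))
  invisible(x)
}

#' Compute the SD-outlier global threshold
#'
#' Treats flake pixels as brightness outliers of the region's grayscale
#' distribution: `T = Mean + k * SD`, where `Mean` and `SD` are the mean
#' and population standard deviation of all pixel intensities in the
#' analyzed (cropped) region.
#'
#' @param gray Numeric matrix of grayscale intensities.
#' @param k Positive multiplier; 2.5 is the calibrated default used
#'   throughout the package.
#' @return A [threshold_spec()].
#' @export
compute_threshold <- function(gray, k = 2.5) {
  if (length(gray) == 0L) stop_lipdesq("empty image")
  if (!is_scalar_number(k) || k <= 0) stop_lipdesq("k must be > 0")
  m <- mean(gray)
  s <- pop_sd(gray)
  threshold_spec(mean = m, sd = s, k = k)
}

#' Segment flakes with a global threshold
#'
#' Pixels strictly above `spec$T` become objects (flakes); pixels at or
#' below it become background. The strict inequality pins the boundary
#' case: a zero-variance image has `T = mean` and yields an empty mask.
#'
#' @param gray Numeric matrix of grayscale intensities.
#' @param spec A [threshold_spec()], typically from [compute_threshold()].
#' @return Logical matrix of the same dimensions (`TRUE` = object).
#' @export
segment_flakes <- function(gray, spec) {
  stopifnot(inherits(spec, "threshold_spec"))
  gray > spec$T
}

#' Desquamation rate of a binary mask
#'
#' The desquamation rate is the percentage of object (white) pixels among
#' all pixels of the segmented region.
#'
#' @param mask Logical matrix from [segment_flakes()].
#' @param threshold Optional [threshold_spec()] recorded alongside.
#' @return An object of class `desquamation_result` with fields `rate`
#'   (percent), `n_object_pixels`, `n_total_pixels` and `threshold`.
#' @export
desquamation_rate <- function(mask, threshold = NULL) {
  if (length(mask) == 0L) stop_lipdesq("empty mask")
  n_obj <- sum(mask)
  n_tot <- length(mask)
  structure(list(rate = 100 * n_obj / n_tot,
                 n_object_pixels = as.integer(n_obj),
                 n_total_pixels = as.integer(n_tot),
                 threshold = threshold),
            class = "desquamation_result")
}

#' @export
print.desquamation_result <- function(x, ...) {
  cat(sprintf("<desquamation_result> rate %.3f%% (%d / %d px)\n",
              x$rate, x$n_object_pixels, x$n_total_pixels))
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}

#' Quantify lip desquamation in a photograph
#'
#' Full measurement workflow: locate the lower-lip target rectangle from
#' the landmarks, crop it, convert to grayscale, threshold at
#' `T = Mean + k * SD` and report the percentage of above-threshold
#' pixels.
#'
#' @param image RGB array (`height x width x 3`, values `[0, 255]`) or a
#'   grayscale matrix.
#' @param lm A [landmark_set()] for this image.
#' @param k Threshold multiplier (default 2.5, the calibrated optimum).
#' @return A `desquamation_result`; see [desquamation_rate()].
#' @export
quantify <- function(image, lm, k = 2.5) {
  roi <- extract_target_region(lm)
  region <- crop_roi(image, roi)
  gray <- if (is.matrix(region)) region else to_grayscale(region)
  spec <- compute_threshold(gray, k)
  mask <- segment_flakes(gray, spec)
  res <- desquamation_rate(mask, spec)
  res$roi <- roi
  res
}

#' Desquamation rates over a grid of threshold multipliers
#'
#' Efficient helper for calibration sweeps: the region statistics are
#' computed once and reused for every `k`.
#'
#' @param gray Numeric matrix of grayscale intensities.
#' @param k_grid Numeric vector of multipliers.
#' @return Numeric vector of rates (percent), one per grid value.
#' @export
rates_over_grid <- function(gray, k_grid = default_k_grid()) {
  if (length(gray) == 0L) stop_lipdesq("empty image")
  m <- mean(gray)
  s <- pop_sd(gray)
  vapply(k_grid, function(k) 100 * mean(gray > m + k * s), numeric(1))
}

#' Default threshold-multiplier grid
#'
#' The calibration grid for `k`: 1.5 to 4.5 in steps of 0.1 (31 values).
#' @return Numeric vector.
#' @export
default_k_grid <- function() round(seq(1.5, 4.5, by = 0.1), 10)
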