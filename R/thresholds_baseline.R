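# Conventional histogram-based thresholding baselines. Both operate on a
# 256-bin histogram of the (floored) grayscale intensities and are the
# standard published formulations; they serve as comparators for the
# SD-outlier threshold on long-tailed unimodal lip histograms.

gray_histogram <- function(gray) {
  tabulate(as.integer(clamp(floor(gray), 0, 255)) + 1L, nbins = 256L)
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance of the 256-bin grayscale
#' histogram. Ties are resolved by averaging the tying bin positions. The
#' result is returned as a [threshold_spec()] whose `mean`, `sd` and `k`
#' fields are `NA` (they do not apply to histogram thresholds); pixels
#' strictly above `T` are objects, matching [segment_flakes()].
#'
#' @param gray Numeric matrix of grayscale intensities in `[0, 255]`.
#' @return A [threshold_spec()] with `method = "otsu"`.
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0L) stop_lipdesq("empty image")
  h <- gray_histogram(gray)
  p <- h / sum(h)
  levels <- 0:255
  omega <- cumsum(p)                 # class-0 probability for t = 0..255
  mu <- cumsum(p * levels)           # first moment up to t
  mu_total <- mu[256]
  sigma_b <- (mu_total * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  if (all(sigma_b == -Inf)) {
    # single-valued histogram: threshold at that value, empty mask downstream
    t_star <- levels[which(h > 0)][1]
  } else {
    t_star <- mean(levels[sigma_b == max(sigma_b)])
  }
  threshold_spec(T = t_star, method = "otsu")
}

#' Triangle threshold
#'
#' Draws a line from the histogram peak to the far end of the longer tail
#' and thresholds at the bin of maximum perpendicular distance between the
#' histogram and that line (the standard geometric construction).
#'
#' @inheritParams otsu_threshold
#' @return A [threshold_spec()] with `method = "triangle"`.
#' @export
triangle_threshold <- function(gray) {
  if (length(gray) == 0L) stop_lipdesq("empty image")
  h <- gray_histogram(gray)
  nz <- which(h > 0)
  peak <- which.max(h)
  lo <- min(nz); hi <- max(nz)
  if (lo == hi)
    return(threshold_spec(T = lo - 1, method = "triangle"))
  idx <- if (hi - peak >= peak - lo) peak:hi else peak:lo
  x1 <- peak; y1 <- h[peak]
  x2 <- idx[length(idx)]; y2 <- h[x2]
  d <- abs((y2 - y1) * idx - (x2 - x1) * h[idx] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  threshold_spec(T = idx[which.max(d)] - 1, method = "triangle")
}

#' Count modes of a smoothed grayscale histogram
#'
#' Smooths the 256-bin histogram with a Gaussian kernel and counts local
#' maxima whose prominence (height above the deepest valley separating
#' them from a taller peak) exceeds a fraction of the global maximum.
#' Used to check the shape premise of the SD-outlier method: lip-region
#' histograms are unimodal with a long right tail, not bimodal.
#'
#' @param gray Numeric matrix (or vector) of intensities in `[0, 255]`.
#' @param bandwidth Gaussian kernel standard deviation in gray levels.
#' @param min_prominence Minimum peak prominence as a fraction of the
#'   global smoothed maximum.
#' @return Integer mode count (at least 1 for a non-empty input).
#' @export
count_histogram_modes <- function(gray, bandwidth = 8, min_prominence = 0.05) {
  if (length(gray) == 0L) stop_lipdesq("empty image")
  h <- gray_histogram(gray)
  pad <- ceiling(3 * bandwidth)
  kern <- stats::dnorm(-pad:pad, 0, bandwidth)
  kern <- kern / sum(kern)
  hs <- as.numeric(stats::filter(c(rep(0, pad), h, rep(0, pad)), kern,
                                 sides = 2))
  hs <- hs[(pad + 1):(pad + 256)]
  hs[is.na(hs)] <- 0
  peaks <- which(diff(sign(diff(hs))) == -2) + 1L
  if (!length(peaks)) return(1L)
  gmax <- max(hs)
  n_modes <- 0L
  for (p in peaks) {
    taller_left <- which(hs[seq_len(p - 1)] > hs[p])
    taller_right <- which(hs[(p + 1):256] > hs[p]) + p
    if (!length(taller_left) && !length(taller_right)) {
      n_modes <- n_modes + 1L  # global maximum
      next
    }
    valley_left <- if (length(taller_left)) min(hs[max(taller_left):p]) else Inf
    valley_right <- if (length(taller_right)) min(hs[p:min(taller_right)]) else Inf
    if (hs[p] - min(valley_left, valley_right) >= min_prominence * gmax)
      n_modes <- n_modes + 1L
  }
  max(n_modes, 1L)
}
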