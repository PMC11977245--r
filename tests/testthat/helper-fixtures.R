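# Shared fixture builders. All fixtures are generated in code; nothing is
# stored on disk.

# Landmarks that bound the rectangle [x0, x0+w) x [y0, y0+h) on an
# image_width x image_height frame, in the package's placement convention.
make_lip_landmarks <- function(x0, y0, w, h, image_width, image_height,
                               dy = 3) {
  pts <- rbind(
    `14` = c(x0 + w / 2, y0 - dy),
    `15` = c(x0 + w / 2, y0 + dy),
    `16` = c(x0 + w / 2, y0 + h - dy),
    `17` = c(x0 + w / 2, y0 + h + dy),
    `84` = c(x0, y0 + h / 2),
    `87` = c(x0 + w, y0 + h / 2),
    `314` = c(x0 + 0.1 * w, y0 + h / 2),
    `317` = c(x0 + 0.9 * w, y0 + h / 2))
  colnames(pts) <- c("x", "y")
  landmark_set(pts, image_width, image_height)
}

# A flat gray RGB array.
flat_rgb <- function(h, w, value = 120) {
  array(value, c(h, w, 3))
}

# Small deterministic pseudo-random grayscale matrix.
random_gray <- function(h, w, seed = 1) {
  lipdesq:::with_local_seed(seed, matrix(stats::runif(h * w, 0, 255), h, w))
}
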