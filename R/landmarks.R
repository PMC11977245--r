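#' Face-mesh indices delimiting the lower-lip centre
#'
#' The eight landmark indices (in the 478-point face-mesh convention) that
#' together bound the centre area of the lower lip: 14--17 on the midline,
#' 84/87 on the left and 314/317 on the right.
#'
#' @format Integer vector of length 8.
#' @export
lip_landmark_indices <- c(14L, 15L, 16L, 17L, 84L, 87L, 314L, 317L)

#' Construct a landmark set
#'
#' A `landmark_set` holds 2D pixel-space landmark coordinates indexed by the
#' face-mesh numbering convention, together with the dimensions of the image
#' they refer to. Only the x/y coordinates are used; the z coordinate of 3D
#' detectors is ignored throughout.
#'
#' @param points Numeric matrix with columns `x` and `y` (pixels) and row
#'   names giving integer landmark indices, or a named list of length-2
#'   vectors.
#' @param image_width,image_height Image dimensions in pixels.
#' @param index_space Total landmark count of the indexing convention
#'   (478 for the face-mesh model).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_width, image_height, index_space = 478L) {
  if (is.list(points)) {
    idx <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p[1:2])))
    rownames(points) <- idx
  }
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(points) <- c("x", "y")
  if (is.null(rownames(points)))
    stop_lipdesq("landmark points must be indexed (row names or list names)")
  if (!is_scalar_number(image_width) || !is_scalar_number(image_height) ||
      image_width < 1 || image_height < 1)
    stop_lipdesq("image dimensions must be >= 1")
  missing_idx <- setdiff(lip_landmark_indices, as.integer(rownames(points)))
  if (length(missing_idx))
    stop_lipdesq("incomplete landmark set: missing required index ",
                 paste(missing_idx, collapse = ", "))
  if (any(points[, "x"] < 0 | points[, "x"] > image_width |
          points[, "y"] < 0 | points[, "y"] > image_height))
    stop_lipdesq("landmark coordinates fall outside the image bounds")
  structure(
    list(points = points, image_width = as.numeric(image_width),
         image_height = as.numeric(image_height),
         index_space = as.integer(index_space)),
    class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d points (index space %d) on %gx%g image\n",
              nrow(x$points), x$index_space, x$image_width, x$image_height))
  invisible(x)
}

lm_xy <- function(lm, index) {
  i <- match(as.character(index), rownames(lm$points))
  if (is.na(i))
    stop_lipdesq("incomplete landmark set: missing required index ", index)
  lm$points[i, ]
}

#' Denormalize unit-square landmark coordinates to pixel space
#'
#' Face-mesh detectors emit coordinates normalized to `[0, 1]` in both axes;
#' this maps them onto a concrete image raster.
#'
#' @param raw Named list or matrix of normalized coordinates (see
#'   [landmark_set()] for the accepted shapes); all values must lie in
#'   `[0, 1]`.
#' @param image_width,image_height Target image dimensions in pixels.
#' @inheritParams landmark_set
#' @return A [landmark_set()] in pixel coordinates.
#' @export
denormalize_landmarks <- function(raw, image_width, image_height,
                                  index_space = 478L) {
  if (is.list(raw)) {
    idx <- names(raw)
    raw <- do.call(rbind, lapply(raw, function(p) as.numeric(p[1:2])))
    rownames(raw) <- idx
  }
  raw <- as.matrix(raw)[, 1:2, drop = FALSE]
  if (any(raw < 0 | raw > 1))
    stop_lipdesq("normalized landmark coordinates must lie in [0, 1]")
  pts <- cbind(x = raw[, 1] * image_width, y = raw[, 2] * image_height)
  rownames(pts) <- rownames(raw)
  landmark_set(pts, image_width, image_height, index_space)
}

#' Construct a rectangular lip region of interest
#'
#' @param x0,y0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels (integers `>= 1`). Bounds are
#'   half-open: the ROI covers columns `[x0, x0 + width)` and rows
#'   `[y0, y0 + height)`.
#' @return An object of class `lip_roi`.
#' @export
lip_roi <- function(x0, y0, width, height) {
  x0 <- as.integer(round(x0)); y0 <- as.integer(round(y0))
  width <- as.integer(round(width)); height <- as.integer(round(height))
  if (width < 1L || height < 1L)
    stop_lipdesq("degenerate ROI: width and height must be >= 1 pixel")
  if (x0 < 0L || y0 < 0L)
    stop_lipdesq("ROI corner must be non-negative")
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "lip_roi")
}

#' @export
print.lip_roi <- function(x, ...) {
  cat(sprintf("<lip_roi> origin (%d, %d), %d x %d px\n",
              x$x0, x$y0, x$width, x$height))
  invisible(x)
}

#' Extract the lower-lip target rectangle from a landmark set
#'
#' The rectangle width is the larger of the two x-coordinate spans between
#' landmarks 84--87 and 314--317; its height is the y-coordinate difference
#' between the midpoints of landmark pairs 14--15 and 16--17. The rectangle
#' is centred horizontally on the mean x of landmarks 84, 87, 314 and 317,
#' and spans vertically from the 14--15 midpoint to the 16--17 midpoint.
#' Geometry is computed in floating point and rounded to integer pixel
#' bounds at the end; rectangles that would extend past the image are
#' clipped with a warning.
#'
#' @param lm A [landmark_set()].
#' @return A [lip_roi()].
#' @export
extract_target_region <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  p84 <- lm_xy(lm, 84); p87 <- lm_xy(lm, 87)
  p314 <- lm_xy(lm, 314); p317 <- lm_xy(lm, 317)
  p14 <- lm_xy(lm, 14); p15 <- lm_xy(lm, 15)
  p16 <- lm_xy(lm, 16); p17 <- lm_xy(lm, 17)

  width <- max(abs(p84["x"] - p87["x"]), abs(p314["x"] - p317["x"]))
  mid_top <- (p14["y"] + p15["y"]) / 2
  mid_bot <- (p16["y"] + p17["y"]) / 2
  height <- abs(mid_top - mid_bot)
  if (round(width) < 1 || round(height) < 1)
    stop_lipdesq("degenerate ROI: landmark spans give zero width or height")

  cx <- mean(c(p84["x"], p87["x"], p314["x"], p317["x"]))
  x0 <- round(cx - width / 2)
  y0 <- round(min(mid_top, mid_bot))
  w <- round(width); h <- round(height)

  # clip to image bounds
  clipped <- FALSE
  if (x0 < 0) { w <- w + x0; x0 <- 0; clipped <- TRUE }
  if (y0 < 0) { h <- h + y0; y0 <- 0; clipped <- TRUE }
  if (x0 + w > lm$image_width) { w <- lm$image_width - x0; clipped <- TRUE }
  if (y0 + h > lm$image_height) { h <- lm$image_height - y0; clipped <- TRUE }
  if (clipped)
    warning("target region extended past image bounds; clipped", call. = FALSE)
  if (w < 1 || h < 1)
    stop_lipdesq("degenerate ROI after clipping to image bounds")
  lip_roi(x0, y0, w, h)
}

#' Crop a region of interest from an image
#'
#' @param image Numeric matrix (grayscale, rows = y) or 3D array
#'   (rows x cols x channels), intensities on any scale.
#' @param roi A [lip_roi()]; must lie within the image bounds.
#' @return The sub-image, same type as the input, with dimensions
#'   `roi$height` x `roi$width`.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(roi, "lip_roi"))
  d <- dim(image)
  if (roi$x0 + roi$width > d[2] || roi$y0 + roi$height > d[1])
    stop_lipdesq("ROI lies outside the image bounds")
  rows <- (roi$y0 + 1L):(roi$y0 + roi$height)
  cols <- (roi$x0 + 1L):(roi$x0 + roi$width)
  if (length(d) == 3L) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Read a landmark file
#'
#' Landmark files are JSON objects with fields `points` (map from landmark
#' index to `[x, y]`), `normalized` (logical), `image_width`, `image_height`
#' and optionally `index_space`. Normalized coordinates are mapped to pixel
#' space on read.
#'
#' @param path Path to a landmark JSON file.
#' @return A [landmark_set()] in pixel coordinates.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("points", "normalized", "image_width", "image_height"))
    if (is.null(obj[[f]]))
      stop_lipdesq("landmark file missing field '", f, "': ", path)
  pts <- obj$points
  if (is.list(pts)) {
    idx <- names(pts)
    pts <- do.call(rbind, lapply(pts, as.numeric))
    rownames(pts) <- idx
  }
  ispace <- if (!is.null(obj$index_space)) obj$index_space else 478L
  if (isTRUE(obj$normalized))
    denormalize_landmarks(pts, obj$image_width, obj$image_height, ispace)
  else
    landmark_set(pts, obj$image_width, obj$image_height, ispace)
}

#' Write a landmark set to a JSON file
#'
#' @param lm A [landmark_set()] (pixel coordinates).
#' @param path Output path.
#' @param normalized Write unit-normalized coordinates instead of pixels.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, normalized = FALSE) {
  stopifnot(inherits(lm, "landmark_set"))
  pts <- lm$points
  if (normalized) {
    pts[, "x"] <- pts[, "x"] / lm$image_width
    pts[, "y"] <- pts[, "y"] / lm$image_height
  }
  obj <- list(
    index_space = lm$index_space,
    normalized = normalized,
    image_width = lm$image_width,
    image_height = lm$image_height,
    points = stats::setNames(
      lapply(seq_len(nrow(pts)), function(i) as.numeric(pts[i, ])),
      rownames(pts)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
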