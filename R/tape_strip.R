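# Tape-stripping comparator model: corneocyte grayscale values are
# grouped into five thickness classes (G0 even layer ... G4 thick
# flakes); the tape-strip desquamation rate is the total proportion of
# the G2-G4 groups. G0 and G1 (grayscale below 150 with the default
# scheme) are excluded from the rate as a data-quality cutoff.

#' Corneocyte grayscale grouping scheme
#'
#' Defines the bin edges for the five corneocyte groups. With the default
#' start of 80 and 35-unit intervals the edges are 80, 115, 150, 185, 220
#' and 255 (the last bin is capped at 255).
#'
#' @param start Lower display bound of G0 in grayscale units.
#' @param interval Bin width in grayscale units.
#' @param n_groups Number of groups (5: G0 through G4).
#' @return An object of class `group_scheme` with an `edges` field of
#'   length `n_groups + 1`.
#' @export
group_scheme <- function(start = 80, interval = 35, n_groups = 5L) {
  if (start < 0 || interval <= 0 || n_groups < 1)
    stop_lipdesq("invalid grouping scheme")
  edges <- pmin(start + interval * (0:n_groups), 255)
  structure(list(start = start, interval = interval,
                 n_groups = as.integer(n_groups), edges = edges),
            class = "group_scheme")
}

#' Classify corneocyte grayscale values into thickness groups
#'
#' Bins are half-open and lower-closed, `[edge_i, edge_{i+1})`, with the
#' last bin closed at 255, so e.g. the default G0 covers 80--114 and a
#' value of exactly 150 falls in G2 (and is therefore retained by the
#' quality cutoff that drops values below 150). Values below the scheme's
#' start are assigned to G0; since G0 never contributes to the rate this
#' choice only affects the reported proportions, and is pinned for
#' determinism.
#'
#' @param values Numeric vector of grayscale values in `[0, 255]`.
#' @param scheme A [group_scheme()].
#' @return An object of class `tape_strip_profile` with `proportions`
#'   (named percentages G0...G4 summing to 100) and `rate`
#'   (percent, G2 + G3 + G4).
#' @export
classify_groups <- function(values, scheme = group_scheme()) {
  stopifnot(inherits(scheme, "group_scheme"))
  if (length(values) == 0L) stop_lipdesq("no grayscale values supplied")
  if (any(values < 0 | values > 255))
    stop_lipdesq("grayscale values must lie in [0, 255]")
  edges <- scheme$edges
  n <- scheme$n_groups
  grp <- rep(1L, length(values))            # below start -> G0
  for (g in seq_len(n)) {
    in_bin <- if (g < n)
      values >= edges[g] & values < edges[g + 1]
    else
      values >= edges[g] & values <= edges[g + 1]   # last bin closed at 255
    grp[in_bin] <- g
  }
  counts <- tabulate(grp, nbins = n)
  props <- 100 * counts / length(values)
  names(props) <- paste0("G", seq_len(n) - 1L)
  structure(list(proportions = props,
                 rate = tape_rate_from_proportions(props),
                 scheme = scheme),
            class = "tape_strip_profile")
}

#' @export
print.tape_strip_profile <- function(x, ...) {
  cat("<tape_strip_profile>\n")
  print(round(x$proportions, 3))
  cat(sprintf("tape-strip rate (G2+G3+G4): %.3f%%\n", x$rate))
  invisible(x)
}

#' Tape-strip desquamation rate from group proportions
#'
#' The rate is the total proportion of detected flakes in the G2, G3 and
#' G4 groups; the thin-layer groups G0 and G1 are excluded.
#'
#' @param proportions Numeric vector of at least 5 non-negative group
#'   percentages ordered G0, G1, G2, G3, G4.
#' @return The rate in percent.
#' @export
tape_rate_from_proportions <- function(proportions) {
  if (length(proportions) < 5L)
    stop_lipdesq("need proportions for the five groups G0...G4")
  if (any(proportions < 0)) stop_lipdesq("proportions must be non-negative")
  if (sum(proportions[1:5]) > 100 + 1e-6)
    stop_lipdesq("proportions must sum to at most 100%")
  sum(proportions[3:5])
}
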