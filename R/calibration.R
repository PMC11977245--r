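# Calibration of the threshold multiplier k against visual-assessment
# scores: sweep k over a grid, correlate rates with VA, select k.

#' Sweep the threshold multiplier over a grid
#'
#' For every `k` on the grid, computes each subject's desquamation rate,
#' the Pearson (or Spearman) correlation between rates and final VA
#' scores, its two-sided p-value, and the mean rate across subjects.
#'
#' @param subjects Either a list of grayscale matrices (one cropped lip
#'   region per subject) or a pre-computed numeric matrix of rates with
#'   one row per subject and one column per grid value.
#' @param va Numeric vector of final VA scores, one per subject.
#' @param k_grid Numeric vector of multipliers (default [default_k_grid()]).
#' @param method Correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A data frame of class `calibration_curve` with columns `k`,
#'   `r`, `p`, `mean_rate`. Grid points where the rates are constant
#'   across subjects have `r = NA` and `p = NA`.
#' @export
sweep_k <- function(subjects, va, k_grid = default_k_grid(),
                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.list(subjects)) {
    rates <- vapply(subjects, rates_over_grid, numeric(length(k_grid)),
                    k_grid = k_grid)
    rates <- if (is.matrix(rates)) t(rates) else matrix(rates, ncol = 1L)
  } else {
    rates <- as.matrix(subjects)
    if (ncol(rates) != length(k_grid))
      stop_lipdesq("rate matrix must have one column per k grid value")
  }
  n <- nrow(rates)
  if (n < 3L) stop_lipdesq("need at least 3 subjects")
  if (length(va) != n)
    stop_lipdesq("need exactly one VA score per subject")

  out <- data.frame(k = k_grid, r = NA_real_, p = NA_real_,
                    mean_rate = colMeans(rates))
  for (j in seq_along(k_grid)) {
    x <- rates[, j]
    if (stats::sd(x) == 0 || stats::sd(va) == 0) next  # r undefined: missing
    ct <- stats::cor.test(x, va, method = method, exact = FALSE)
    out$r[j] <- unname(ct$estimate)
    out$p[j] <- ct$p.value
  }
  class(out) <- c("calibration_curve", class(out))
  attr(out, "method") <- method
  out
}

#' Select the operating threshold multiplier from a calibration curve
#'
#' Operationalizes "maximize the correlation with VA while minimizing the
#' omission of existing flakes": since the detected area shrinks as `k`
#' grows, the selected `k` is the smallest grid value whose correlation is
#' within `tolerance` (fractionally) of the maximum over the grid. Ties
#' break toward smaller `k`. With `tolerance = 0` this is exactly the
#' argmax rule.
#'
#' @param curve A `calibration_curve` from [sweep_k()].
#' @param tolerance Fraction of the maximum correlation that may be given
#'   up in exchange for a smaller `k` (default 0.05).
#' @return A list of class `calibration_result` with `chosen_k`,
#'   `chosen_r`, `curve` and `selection_rule`.
#' @export
select_k <- function(curve, tolerance = 0.05) {
  stopifnot(inherits(curve, "calibration_curve"))
  ok <- !is.na(curve$r)
  if (!any(ok)) stop_lipdesq("all calibration entries are missing")
  r_max <- max(curve$r[ok])
  cutoff <- (1 - tolerance) * r_max
  ord <- order(curve$k)
  cand <- ord[ok[ord] & curve$r[ord] >= cutoff]
  pick <- cand[1]
  structure(list(chosen_k = curve$k[pick], chosen_r = curve$r[pick],
                 curve = curve,
                 selection_rule = sprintf(
                   "smallest k with r >= (1 - %.3g) * max(r)", tolerance)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> chosen k = %.1f (r = %.3f); rule: %s\n",
              x$chosen_k, x$chosen_r, x$selection_rule))
  invisible(x)
}
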