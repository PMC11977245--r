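# Visual assessment: the five-level photonumeric severity scale, final
# score averaging across raters, and inter-rater reliability.

#' The photonumeric lip-desquamation scale
#'
#' Integer severity grades with their clinical descriptors.
#'
#' @format Data frame with columns `score`, `label`, `description`.
#' @export
va_scale <- data.frame(
  score = 0:4,
  label = c("None", "Normal", "Moderate", "Marked", "Severe"),
  description = c(
    "no chapping or desquamated flakes",
    "very few small flakes",
    "a few small flakes",
    "obvious flakes in various sizes and shapes",
    "very marked scaling, mainly forming large flakes"))

check_panel <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(is.na(scores) | (scores %in% 0:4)))
    stop_lipdesq("VA scores must be integers in 0..4")
  scores
}

#' Final visual-assessment scores
#'
#' The final VA score of each subject is the arithmetic mean of the
#' raters' integer scores, kept unrounded. Missing cells are averaged
#' over the available raters with a warning.
#'
#' @param scores Numeric matrix, subjects in rows, raters in columns,
#'   integer entries in 0..4 (`NA` allowed).
#' @return Numeric vector of per-subject final scores in `[0, 4]`.
#' @export
final_scores <- function(scores) {
  scores <- check_panel(scores)
  if (ncol(scores) < 1L) stop_lipdesq("need at least one rater")
  if (anyNA(scores))
    warning("missing rater scores; averaging over available raters",
            call. = FALSE)
  rowMeans(scores, na.rm = TRUE)
}

#' Inter-rater reliability of a score panel
#'
#' Pairwise correlations between raters' score sets over subjects,
#' summarized as the mean of the upper-triangle coefficients. Raters with
#' zero variance have undefined correlations; their entries are `NA` and
#' are excluded from the mean.
#'
#' @inheritParams final_scores
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `matrix` (symmetric, unit diagonal) and `mean_r`.
#' @export
inter_rater_reliability <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- check_panel(scores)
  if (ncol(scores) < 2L) stop_lipdesq("need at least 2 raters")
  if (nrow(scores) < 3L) stop_lipdesq("need at least 3 subjects")
  nr <- ncol(scores)
  m <- diag(1, nr)
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    xi <- scores[, i]; xj <- scores[, j]
    ok <- !is.na(xi) & !is.na(xj)
    m[i, j] <- m[j, i] <-
      if (stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) NA_real_
      else stats::cor(xi[ok], xj[ok], method = method)
  }
  rownames(m) <- colnames(m) <- colnames(scores)
  upper <- m[upper.tri(m)]
  list(matrix = m, mean_r = mean(upper, na.rm = TRUE))
}

#' Read a long-format ratings CSV into a score panel
#'
#' @param path CSV with columns `subject_id`, `rater_id`, `score`.
#' @return Numeric matrix, subjects in rows (row names = subject ids),
#'   raters in columns.
#' @export
read_va_scores <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "rater_id", "score")
  if (!all(need %in% names(d)))
    stop_lipdesq("ratings CSV must have columns ", paste(need, collapse = ", "))
  subjects <- unique(d$subject_id)
  raters <- unique(d$rater_id)
  m <- matrix(NA_real_, length(subjects), length(raters),
              dimnames = list(subjects, raters))
  m[cbind(match(d$subject_id, subjects), match(d$rater_id, raters))] <- d$score
  m
}
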