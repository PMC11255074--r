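# Reader-study layer: hemisphere-wise 0-3 atrophy scores, the score-based
# diagnosis rule, confusion-matrix metrics, and agreement statistics
# (Cohen's kappa, two-way ICC, Cochran's Q, exact pairwise McNemar).

#' Score-based diagnosis from hemisphere ratings
#'
#' Each hemisphere carries a 0-3 Likert atrophy score (0 none, 1 minimal to
#' moderate, 2 marked, 3 severe). A positive diagnosis is declared when the
#' bihemispheric score reaches `threshold`; the default rule takes the
#' maximum over hemispheres, with `"both"` (both hemispheres must reach it)
#' and `"sum"` (left + right) selectable because the combination rule is a
#' genuine modeling choice.
#'
#' @param score_left,score_right integer vectors of scores in 0..3.
#' @param threshold diagnosis cutoff (default 2).
#' @param rule `"max"`, `"both"` or `"sum"`.
#' @return logical vector, `TRUE` = positive.
#' @export
diagnose <- function(score_left, score_right, threshold = 2,
                     rule = c("max", "both", "sum")) {
  rule <- match.arg(rule)
  if (length(score_left) != length(score_right))
    an_stop("score vectors differ in length", "length")
  if (any(c(score_left, score_right) < 0 | c(score_left, score_right) > 3))
    an_stop("scores must lie in 0..3", "score")
  switch(rule,
         max = pmax(score_left, score_right) >= threshold,
         both = score_left >= threshold & score_right >= threshold,
         sum = (score_left + score_right) >= threshold)
}

#' Confusion counts from aligned prediction/truth vectors
#'
#' @param predictions,truth logical vectors of equal length.
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    an_stop("predictions and truth differ in length", "length")
  predictions <- as.logical(predictions); truth <- as.logical(truth)
  confusion_counts(tp = sum(predictions & truth),
                   fp = sum(predictions & !truth),
                   tn = sum(!predictions & !truth),
                   fn = sum(!predictions & truth))
}

#' @rdname confusion
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) an_stop("counts must be >= 0", "counts")
  if (sum(counts) == 0) an_stop("total count must be > 0", "counts")
  structure(as.list(counts), class = "confusion_counts")
}

#' Diagnostic accuracy metrics as integer percentages
#'
#' Accuracy, sensitivity, specificity, PPV and NPV, each times 100 and
#' rounded half-up to the nearest integer (the convention of published
#' diagnostic tables). A metric whose denominator is zero is reported as
#' `NA` (absent), never as 0.
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector `accuracy, sensitivity, specificity, ppv,
#'   npv` in percent.
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den > 0) round_half_up(100 * num / den) else NA_real_
  with(counts, c(
    accuracy = rat(tp + tn, tp + tn + fp + fn),
    sensitivity = rat(tp, tp + fn),
    specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp),
    npv = rat(tn, tn + fn)))
}

#' Cohen's kappa for two aligned categorical ratings
#'
#' kappa = (p_o - p_e) / (1 - p_e) with chance agreement from the product of
#' the marginal distributions. Supports the 4-level atrophy score and binary
#' diagnoses alike. Undefined (NA) when the expected agreement is 1 (both
#' raters confined to a single shared category).
#'
#' @param labels_a,labels_b equal-length vectors of categorical labels.
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    an_stop("label vectors differ in length", "length")
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b)
  N <- sum(tab)
  if (N == 0) an_stop("no observations", "counts")
  po <- sum(diag(tab)) / N
  pe <- sum(rowSums(tab) * colSums(tab)) / N^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Two-way intraclass correlation coefficient
#'
#' ICC(2,1) by default: two-way random effects, absolute agreement, single
#' measure, assembled from the mean squares of the two-way ANOVA
#' (subjects x raters, no missing cells). ICC(3,1) (raters fixed,
#' consistency) is selectable.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each).
#' @param type `"ICC2_1"` (default) or `"ICC3_1"`.
#' @return the ICC, or `NA` when the total variance is zero.
#' @export
icc_two_way <- function(ratings, type = c("ICC2_1", "ICC3_1")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) an_stop("need >= 2 subjects and >= 2 raters", "too_few")
  if (any(!is.finite(ratings))) an_stop("missing cells are not supported", "nonfinite")
  if (stats::var(as.vector(ratings)) == 0) return(NA_real_)
  long <- data.frame(value = as.vector(ratings),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are needed; F-tests are irrelevant (and warn on
  # perfect-agreement fits with zero residual variance)
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + rater, data = long))[["Mean Sq"]])
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  switch(type,
         ICC2_1 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
         ICC3_1 = (msr - mse) / (msr + (k - 1) * mse))
}

#' Cochran's Q test for k related binary outcomes
#'
#' Tests whether the marginal success rate differs across k conditions
#' measured on the same subjects; Q is referred to a chi-square distribution
#' with k - 1 degrees of freedom. Subjects with identical outcomes under all
#' conditions contribute nothing; with no variation at all, Q = 0 and p = 1.
#'
#' @param binary matrix of 0/1 (or logical), subjects in rows, conditions in
#'   columns (>= 2).
#' @return list with `Q`, `df`, `p`.
#' @export
cochrans_q <- function(binary) {
  X <- as.matrix(binary) * 1
  if (!all(X %in% c(0, 1))) an_stop("entries must be binary", "binary")
  k <- ncol(X)
  if (k < 2) an_stop("need >= 2 conditions", "too_few")
  Cj <- colSums(X)
  Ri <- rowSums(X)
  denom <- k * sum(Ri) - sum(Ri^2)
  if (denom == 0) return(list(Q = 0, df = k - 1, p = 1))
  Q <- (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / denom
  list(Q = Q, df = k - 1, p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' Pairwise exact McNemar tests with multiplicity correction
#'
#' For every pair of conditions, the exact binomial McNemar test on the
#' discordant pairs (two-sided, null probability 1/2); with zero discordant
#' pairs p = 1. Adjustment via [stats::p.adjust()] (Bonferroni by default,
#' capped at 1).
#'
#' @param binary matrix of 0/1, subjects in rows, conditions in columns.
#' @param correction method name for [stats::p.adjust()].
#' @return `data.frame` with columns `cond_a, cond_b, b, c, p_raw, p_adj`
#'   (`b`/`c` are the two discordant counts).
#' @export
mcnemar_pairwise <- function(binary, correction = "bonferroni") {
  X <- as.matrix(binary) * 1
  if (!all(X %in% c(0, 1))) an_stop("entries must be binary", "binary")
  k <- ncol(X)
  if (k < 2) an_stop("need >= 2 conditions", "too_few")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    b <- sum(X[, i] == 1 & X[, j] == 0)
    cc <- sum(X[, i] == 0 & X[, j] == 1)
    p <- if (b + cc == 0) 1 else stats::binom.test(b, b + cc, 0.5)$p.value
    c(b = b, c = cc, p = p)
  })
  out <- data.frame(cond_a = cn[pairs[1, ]], cond_b = cn[pairs[2, ]],
                    b = res["b", ], c = res["c", ], p_raw = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out
}
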