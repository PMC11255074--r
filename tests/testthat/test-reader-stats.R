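test_that("the score-based diagnosis rule behaves as configured", {
  expect_false(diagnose(0, 0))
  expect_true(diagnose(2, 0))
  expect_false(diagnose(1, 1))
  expect_true(diagnose(1, 1, rule = "sum"))
  expect_false(diagnose(2, 0, rule = "both"))
  expect_true(diagnose(2, 3, rule = "both"))
  expect_equal(diagnose(c(0, 2, 1), c(0, 0, 1)), c(FALSE, TRUE, FALSE))
  expect_error(diagnose(4, 0), class = "atrophynorm_error_score")
})

test_that("confusion counts partition the sample and invert as expected", {
  truth <- rep(c(TRUE, FALSE), each = 21)
  allright <- confusion(truth, truth)
  expect_equal(unlist(allright[c("tp", "tn", "fp", "fn")]),
               c(tp = 21, tn = 21, fp = 0, fn = 0))

  inv <- confusion(!truth, truth)
  expect_equal(unlist(inv[c("tp", "tn", "fp", "fn")]),
               c(tp = 0, tn = 0, fp = 21, fn = 21))

  set.seed(19)
  pred <- runif(100) > 0.5; tr <- runif(100) > 0.5
  got <- confusion(pred, tr)
  tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:100) {
    key <- if (pred[i] && tr[i]) "tp" else if (pred[i]) "fp"
           else if (tr[i]) "fn" else "tn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(got[c("tp", "fp", "tn", "fn")]), tally[c("tp", "fp", "tn", "fn")])
  expect_equal(sum(unlist(got)), 100)
})

test_that("diagnostic metrics are integer percentages with absent undefined cells", {
  m <- diagnostic_metrics(confusion_counts(tp = 16, fp = 0, tn = 21, fn = 5))
  expect_equal(m, c(accuracy = 88, sensitivity = 76, specificity = 100,
                    ppv = 100, npv = 81))

  m2 <- diagnostic_metrics(confusion_counts(tp = 15, fp = 1, tn = 20, fn = 6))
  expect_equal(m2, c(accuracy = 83, sensitivity = 71, specificity = 95,
                     ppv = 94, npv = 77))

  nopos <- diagnostic_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 2))
  expect_true(is.na(nopos["ppv"]))
  expect_false(is.na(nopos["npv"]))

  # half-up rounding convention, against a direct-ratio oracle
  set.seed(23)
  for (i in 1:20) {
    cc <- confusion_counts(tp = sample(0:30, 1), fp = sample(1:30, 1),
                           tn = sample(1:30, 1), fn = sample(1:30, 1))
    got <- diagnostic_metrics(cc)
    want <- with(cc, c(accuracy = (tp + tn) / (tp + tn + fp + fn),
                       sensitivity = tp / (tp + fn),
                       specificity = tn / (tn + fp),
                       ppv = tp / (tp + fp), npv = tn / (tn + fn)))
    expect_equal(got[!is.na(got)], floor(100 * want[!is.na(got)] + 0.5))
  }
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, 76.19)), c(1, 2, 3, 76))
})

test_that("Cohen's kappa matches direct formula evaluation", {
  expect_equal(cohens_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)

  # 2x2 counts a=8, b=2, c=2, d=8: po=0.8, pe=0.5, kappa=0.6
  a <- rep(c("x", "x", "y", "y"), c(8, 2, 2, 8))
  b <- rep(c("x", "y", "x", "y"), c(8, 2, 2, 8))
  expect_equal(cohens_kappa(a, b), 0.6)
  expect_equal(cohens_kappa(b, a), 0.6)  # symmetric

  disagree_a <- rep(c("x", "y"), c(10, 10))
  disagree_b <- rep(c("y", "x"), c(10, 10))
  expect_equal(cohens_kappa(disagree_a, disagree_b), -1)

  expect_true(is.na(cohens_kappa(rep("x", 5), rep("x", 5))))
})

test_that("two-way ICC matches a hand-computed ANOVA decomposition", {
  # identical raters with between-subject variance: perfect agreement
  col <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_two_way(cbind(col, col, col)), 1)

  # worked 6x3 matrix: mean squares computed directly from sums of squares
  M <- matrix(c(9, 6, 8, 7, 10, 6,
                2, 1, 4, 1, 5, 2,
                5, 3, 6, 2, 6, 4), nrow = 6)
  n <- 6; k <- 3
  grand <- mean(M)
  ssr <- k * sum((rowMeans(M) - grand)^2)
  ssc <- n * sum((colMeans(M) - grand)^2)
  sse <- sum((M - outer(rowMeans(M), rep(1, k)) -
                outer(rep(1, n), colMeans(M)) + grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  want21 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  want31 <- (msr - mse) / (msr + (k - 1) * mse)
  expect_equal(icc_two_way(M), want21, tolerance = 1e-12)
  expect_equal(icc_two_way(M, type = "ICC3_1"), want31, tolerance = 1e-12)

  # rater noise 10x the subject SD drives agreement toward zero
  set.seed(29)
  subj <- rnorm(200, sd = 1)
  noisy <- cbind(subj + rnorm(200, sd = 10), subj + rnorm(200, sd = 10),
                 subj + rnorm(200, sd = 10))
  expect_lt(abs(icc_two_way(noisy)), 0.2)

  expect_true(is.na(icc_two_way(matrix(3, 4, 3))))
  expect_error(icc_two_way(matrix(1:4, 4, 1)), class = "atrophynorm_error_too_few")
})

test_that("Cochran's Q matches its closed form and the k=2 McNemar identity", {
  same <- cbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(1, 0, 1, 0))
  q0 <- cochrans_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  set.seed(37)
  X <- matrix(rbinom(80, 1, 0.5), 20, 4)
  got <- cochrans_q(X)
  k <- 4; Cj <- colSums(X); Ri <- rowSums(X)
  wantQ <- (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / (k * sum(Ri) - sum(Ri^2))
  expect_equal(got$Q, wantQ, tolerance = 1e-12)
  expect_equal(got$p, pchisq(wantQ, 3, lower.tail = FALSE))
  expect_true(got$p >= 0 && got$p <= 1)

  # with two conditions Q equals the uncorrected McNemar chi-square
  X2 <- matrix(rbinom(60, 1, 0.5), 30, 2)
  b <- sum(X2[, 1] == 1 & X2[, 2] == 0)
  cc <- sum(X2[, 1] == 0 & X2[, 2] == 1)
  expect_equal(cochrans_q(X2)$Q, (b - cc)^2 / (b + cc), tolerance = 1e-12)
})

test_that("pairwise McNemar uses the exact binomial test with Bonferroni capping", {
  # balanced discordants: exact two-sided p = 1
  Xb <- cbind(c(1, 1, 1, 0, 0, 0, 1, 0), c(0, 0, 0, 1, 1, 1, 1, 0))
  expect_equal(mcnemar_pairwise(Xb)$p_raw, 1)

  # b=1, c=5 discordants: p = 2 * P(X <= 1 | n = 6, p = 1/2) = 0.21875
  X <- cbind(c(1, 0, 0, 0, 0, 0, 1, 1), c(0, 1, 1, 1, 1, 1, 1, 1))
  res <- mcnemar_pairwise(X)
  expect_equal(res$p_raw, 0.21875)

  # zero discordant pairs
  Xeq <- cbind(c(1, 0, 1), c(1, 0, 1))
  expect_equal(mcnemar_pairwise(Xeq)$p_raw, 1)

  # four conditions: 6 pairs, Bonferroni multiplies by 6 and caps at 1
  set.seed(41)
  X4 <- matrix(rbinom(120, 1, 0.5), 30, 4)
  r4 <- mcnemar_pairwise(X4)
  expect_equal(nrow(r4), 6)
  expect_equal(r4$p_adj, pmin(1, 6 * r4$p_raw))
  expect_true(all(r4$p_adj >= r4$p_raw))
  expect_true(all(r4$p_raw >= 0 & r4$p_adj <= 1))
})
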