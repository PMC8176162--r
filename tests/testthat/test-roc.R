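test_that("empirical ROC reproduces enumeration on small cases", {
  r <- empirical_roc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  expect_equal(r$n_pos, 2)
  expect_equal(r$n_neg, 2)
  # perfect separation
  rp <- empirical_roc(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rp$auc, 1)
  # label inversion flips the AUC
  ri <- empirical_roc(c(3, 5, 1, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(ri$auc, 1 - r$auc)
  expect_error(empirical_roc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("sensitivity is non-increasing in the cutoff and endpoints are reached", {
  set.seed(1)
  s <- binormal_scores(15, 20, 1, 1, 0, 1)
  r <- empirical_roc(s$scores, s$labels)
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
  expect_equal(r$sensitivity[1], 1)
  expect_equal(r$specificity[1], 0)
  expect_equal(r$sensitivity[length(r$sensitivity)], 0)
  expect_equal(r$specificity[length(r$specificity)], 1)
})

test_that("trapezoid AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(20)
  for (i in 1:1000) {
    n1 <- sample(2:15, 1)
    n0 <- sample(2:15, 1)
    # integer scores force heavy ties
    scores <- c(sample(0:6, n1, replace = TRUE) + rbinom(n1, 1, 0.5),
                sample(0:6, n0, replace = TRUE))
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- empirical_roc(scores, labels)
    u <- peepchallenge:::auc_statistic(scores, labels)
    expect_equal(r$auc, u, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  s <- binormal_scores(18, 22, 2.3, 1.7, -0.5, 1.8)
  a0 <- empirical_roc(s$scores, s$labels)$auc
  shifted <- s$scores - min(s$scores) + 1
  for (f in list(function(x) 3 * x + 10, exp, function(x) x^3,
                 function(x) log(x))) {
    expect_equal(empirical_roc(f(shifted), s$labels)$auc, a0,
                 tolerance = 1e-12)
  }
})

test_that("small-cohort pairwise enumeration agrees with the curve AUC", {
  set.seed(9)
  for (i in 1:25) {
    pos <- round(rnorm(6, 2, 2), 1)
    neg <- round(rnorm(8, 0, 2), 1)
    r <- empirical_roc(c(pos, neg), rep(c(TRUE, FALSE), c(6, 8)))
    expect_equal(r$auc, brute_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("empirical AUC and CI agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  s <- binormal_scores(18, 22, 2.3, 1.7, -0.5, 1.8)
  r <- empirical_roc(s$scores, s$labels)
  ref <- pROC::roc(s$labels, s$scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Hanley-McNeil SE matches hand calculation and Monte-Carlo spread", {
  expect_equal(hanley_mcneil_se(0.5, 18, 18), 0.0976, tolerance = 1e-3)
  # theta -> 1 drives the SE to zero
  expect_lt(hanley_mcneil_se(0.999, 18, 22), 0.01)
  # doubling both groups shrinks the SE by about sqrt(2)
  ratio <- hanley_mcneil_se(0.8, 18, 22) / hanley_mcneil_se(0.8, 36, 44)
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
  expect_error(hanley_mcneil_se(0, 18, 22), "strictly inside")
  expect_error(hanley_mcneil_se(1, 18, 22), "strictly inside")
  # Monte-Carlo SD of the empirical AUC under exchangeable scores (true
  # theta = 0.5) should sit near the closed form
  set.seed(12)
  aucs <- replicate(1500, {
    s <- binormal_scores(18, 18, 0, 1, 0, 1)
    peepchallenge:::auc_statistic(s$scores, s$labels)
  })
  expect_equal(sd(aucs), hanley_mcneil_se(0.5, 18, 18), tolerance = 0.05)
})

test_that("AUC confidence interval is the truncated normal band", {
  set.seed(13)
  s <- binormal_scores(18, 22, 2.3, 1.7, -0.5, 1.8)
  r <- empirical_roc(s$scores, s$labels)
  ci <- auc_ci(r)
  z975 <- qnorm(0.975)
  expect_equal(ci[2] - ci[1],
               min(1, r$auc + z975 * r$se_auc) -
                 max(0, r$auc - z975 * r$se_auc), tolerance = 1e-9)
  expect_lte(ci[1], r$auc)
  expect_gte(ci[2], r$auc)
  # near-perfect separation caps the upper bound at 1
  rp <- empirical_roc(c(5, 6, 7, 8, 0, 1, 2, 2.5),
                      rep(c(TRUE, FALSE), each = 4))
  expect_equal(auc_ci(rp)[2], 1)
})

test_that("AUC comparison is antisymmetric, zero for self, and reduces to the unpaired z", {
  set.seed(14)
  s <- binormal_scores(18, 22, 2.3, 1.7, -0.5, 1.8)
  a <- empirical_roc(s$scores, s$labels)
  b <- empirical_roc(s$scores + rnorm(40, 0, 1), s$labels)
  self <- compare_aucs(a, a, paired = TRUE)
  expect_equal(self$z_statistic, 0)
  expect_equal(self$p_value, 1)
  ab <- compare_aucs(a, b, paired = TRUE)
  ba <- compare_aucs(b, a, paired = TRUE)
  expect_equal(ab$z_statistic, -ba$z_statistic, tolerance = 1e-12)
  # unpaired: r forced to zero gives the two-independent-AUC test
  un <- compare_aucs(a, b, paired = FALSE)
  expect_equal(un$correlation_r, 0)
  expect_equal(un$z_statistic,
               (a$auc - b$auc) / sqrt(a$se_auc^2 + b$se_auc^2),
               tolerance = 1e-12)
  expect_gte(ab$p_value, 0)
  expect_lte(ab$p_value, 1)
  # strongly separated vs null predictor: the sign follows the difference
  s2 <- binormal_scores(18, 22, 3, 1, 0, 1)
  good <- empirical_roc(s2$scores, s2$labels)
  set.seed(15)
  noise <- empirical_roc(rnorm(40), s$labels)
  expect_gt(compare_aucs(good, noise)$z_statistic, 0)
})

test_that("paired z-test broadly agrees with the permutation cross-check", {
  set.seed(16)
  base <- binormal_scores(18, 22, 2.0, 1.5, 0, 1.5)
  other <- base$scores + rnorm(40, 0, 2)  # correlated, weaker predictor
  a <- empirical_roc(base$scores, base$labels)
  b <- empirical_roc(other, base$labels)
  z <- compare_aucs(a, b, paired = TRUE)
  perm <- permutation_auc_test(base$scores, other, base$labels, B = 600,
                               seed = 17)
  # same order of magnitude and the same side of 0.05 is all we ask of the
  # approximate normal test vs the exact resampling reference
  expect_lt(abs(z$p_value - perm$p_value), 0.15)
})

test_that("Youden cutoff maximizes J with ties broken toward the smaller cutoff", {
  r <- empirical_roc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  op <- youden_cutoff(r)
  expect_equal(op$cutoff, 1)  # J = 0.5 at cutoffs 1 and 4; smaller wins
  expect_equal(op$youden_j, 0.5)
  # perfectly separated data: J = 1 at the boundary cutoff
  rp <- empirical_roc(c(10, 11, 12, 1, 2, 3),
                      rep(c(TRUE, FALSE), each = 3))
  opp <- youden_cutoff(rp)
  expect_equal(opp$youden_j, 1)
  expect_equal(opp$cutoff, 3)
  expect_equal(opp$sensitivity[["estimate"]], 100)
  # brute-force enumeration of all cutoffs on random data
  set.seed(18)
  for (i in 1:20) {
    s <- binormal_scores(8, 9, 1, 1, 0, 1)
    r2 <- empirical_roc(s$scores, s$labels)
    op2 <- youden_cutoff(r2)
    pos <- s$scores[s$labels]
    neg <- s$scores[!s$labels]
    jj <- vapply(r2$thresholds, function(c)
      mean(pos > c) + mean(neg <= c) - 1, numeric(1))
    expect_equal(op2$youden_j, max(jj), tolerance = 1e-12)
    expect_equal(op2$cutoff, r2$thresholds[which.max(jj)])
  }
})

test_that("Wald operating-point intervals match the plug-in formula, truncated", {
  # Se 88% with n = 18 gives roughly (73, 100-truncated)
  ci <- peepchallenge:::wald_percent(15.84 / 18 * 18, 18)
  p <- 15.84 / 18
  half <- 1.959964 * sqrt(p * (1 - p) / 18)
  expect_equal(ci[["low"]], 100 * (p - half))
  expect_equal(ci[["high"]], min(100, 100 * (p + half)))
  expect_lt(ci[["low"]], 75)
  expect_gt(ci[["low"]], 70)
})

test_that("predictive values follow the confusion counts and handle empty cells", {
  pv <- predictive_values(15 / 18, 18 / 22, 18, 22)
  expect_equal(pv$ppv[["estimate"]], 100 * 15 / 19, tolerance = 1e-9)
  expect_equal(pv$npv[["estimate"]], 100 * 18 / 21, tolerance = 1e-9)
  # perfect specificity forces PPV = 100%
  pv2 <- predictive_values(0.5, 1, 10, 10)
  expect_equal(pv2$ppv[["estimate"]], 100)
  # nothing called positive: PPV undefined, reported as missing
  pv3 <- predictive_values(0, 1, 10, 10)
  expect_true(is.na(pv3$ppv[["estimate"]]))
})

test_that("sample-size search reproduces its worked value and is monotone", {
  res <- sample_size_auc(0.8, 0.5, alpha = 0.05, power = 0.9)
  expect_equal(res$n_pos, 17)
  expect_equal(res$total, 34)
  # larger effect needs fewer patients
  sizes <- vapply(c(0.7, 0.75, 0.8, 0.85, 0.9),
                  function(a) sample_size_auc(a)$total, numeric(1))
  expect_true(all(diff(sizes) < 0))
  expect_error(sample_size_auc(0.5), "no finite")
  # one-sided at the same settings needs fewer patients
  expect_lt(sample_size_auc(0.8, sided = 1)$total, res$total)
})
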