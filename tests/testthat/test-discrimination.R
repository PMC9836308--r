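test_that("empirical AUC equals exhaustive pair counting, including ties", {
  # the worked tie case: 6 strict wins + 2 ties counted half = 7/9
  expect_equal(brute_auc(c(1, 2, 3), c(2, 3, 4)), 7 / 9)
  expect_equal(empirical_roc(c(1, 2, 3), c(2, 3, 4))$auc, 7 / 9)

  # randomized oracle equivalence on tie-heavy integer scores
  set.seed(77)
  for (k in 1:12) {
    cases <- sample(0:30, sample(3:100, 1), replace = TRUE)
    controls <- sample(5:35, sample(3:100, 1), replace = TRUE)
    expect_equal(empirical_roc(cases, controls)$auc,
                 brute_auc(cases, controls))
  }
})

test_that("ROC handles separation, exchangeability, and orientation swaps", {
  r <- empirical_roc(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  same <- c(4, 5, 6, 7)
  expect_equal(empirical_roc(same, same)$auc, 0.5)

  set.seed(9)
  a <- rnorm(40, 0)
  b <- rnorm(50, 1)
  expect_equal(empirical_roc(a, b)$auc, 1 - empirical_roc(b, a)$auc)
  ss <- sens_spec_at_cutoff(a, b, 0.5)
  ss_swapped <- sens_spec_at_cutoff(b, a, 0.5)
  # swapping roles exchanges the error structure around the same cutoff
  expect_equal(ss[["sensitivity"]], mean(a <= 0.5))
  expect_equal(ss_swapped[["specificity"]], mean(a > 0.5))

  # AUC is invariant under strictly monotone transforms
  expect_equal(empirical_roc(exp(a), exp(b))$auc, empirical_roc(a, b)$auc)
  expect_equal(empirical_roc(3 * a - 2, 3 * b - 2)$auc,
               empirical_roc(a, b)$auc)

  # curve is monotone: sensitivity non-decreasing with the threshold
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_true(all(diff(empirical_roc(a, b)$curve$sensitivity) >= 0))

  expect_error(empirical_roc(numeric(0), 1:3), "non-empty")
})

test_that("Youden cutoffs use the tie rule and integer pair rendering", {
  # integers: label rendered as floor/floor+1
  cases <- c(30, 35, 38)
  controls <- c(45, 48, 50)
  r <- empirical_roc(cases, controls)
  expect_equal(r$optimal_cutoff, 38)
  expect_equal(r$cutoff_label, "38/39")

  expect_equal(r$youden_j, 1)

  # tied Youden maxima: cases (1,2) vs controls (2,3) give J = 0.5 at
  # both t = 1 and t = 2; the lower cutoff (higher specificity) wins
  tie <- empirical_roc(c(1, 2), c(2, 3))
  js <- tie$curve$sensitivity + tie$curve$specificity - 1
  expect_gt(sum(js == max(js)), 1)
  expect_equal(tie$optimal_cutoff, 1)
  expect_equal(tie$specificity, 1)

  expect_equal(sens_spec_at_cutoff(cases, controls, 20),
               c(sensitivity = 0, specificity = 1))
  expect_equal(sens_spec_at_cutoff(cases, controls, 60),
               c(sensitivity = 1, specificity = 0))
  expect_equal(sens_spec_at_cutoff(c(30, 35), c(45, 50), 40),
               c(sensitivity = 1, specificity = 1))
})

test_that("binormal AUC matches the closed form and its degenerate limits", {
  expect_equal(binormal_auc(10, 2, 10, 3), 0.5)
  expect_equal(binormal_auc(0, 1, sqrt(2), 1), pnorm(1))
  expect_equal(binormal_auc(1, 0, 2, 0), 1)
  expect_equal(binormal_auc(1, 0, 1, 0), 0.5)
  # Monte-Carlo empirical AUC converges to the binormal value
  set.seed(15)
  cases <- rnorm(20000, 38.94, 10.53)
  controls <- rnorm(20000, 48.47, 6.58)
  expect_equal(empirical_roc(cases, controls)$auc,
               binormal_auc(38.94, 10.53, 48.47, 6.58), tolerance = 0.01)
})

test_that("AUC, CI and DeLong test agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(23)
  n <- 120
  is_case <- rep(c(TRUE, FALSE), each = n)
  latent <- rnorm(2 * n) + ifelse(is_case, -1, 0)
  a <- latent + rnorm(2 * n, sd = 0.8)
  b <- latent + rnorm(2 * n, sd = 1.4)

  r <- empirical_roc(a[is_case], a[!is_case])
  pr <- pROC::roc(response = is_case, predictor = a, quiet = TRUE,
                  direction = ">") # cases below controls
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- pROC::ci.auc(pr, method = "delong")
  expect_equal(auc_confidence_interval(r),
               c(lower = ci[1], upper = ci[3]), tolerance = 1e-8)

  d <- delong_paired_test(a, b, is_case)
  pr_b <- pROC::roc(response = is_case, predictor = b, quiet = TRUE,
                    direction = ">")
  ref <- pROC::roc.test(pr, pr_b, method = "delong", paired = TRUE)
  expect_equal(d$p_value, ref$p.value, tolerance = 1e-8)
  expect_equal(d$auc_a - d$auc_b,
               as.numeric(ref$estimate[1] - ref$estimate[2]))
  expect_equal(d$chi2, d$z^2)
})

test_that("DeLong self-comparison is null and the test has power for real gaps", {
  set.seed(31)
  is_case <- rep(c(TRUE, FALSE), each = 60)
  x <- rnorm(120) - is_case
  d <- delong_paired_test(x, x, is_case)
  expect_equal(d$auc_diff, 0)
  expect_equal(d$p_value, 1)

  expect_error(delong_paired_test(x, x, rep(TRUE, 120)), "at least 2")
  expect_error(delong_paired_test(x[1:5], x, is_case), "per subject")

  # power: true AUC gap ~0.10 at n = 400/400 rejects well over half the
  # time at alpha = 0.05
  set.seed(99)
  # scores have SD sqrt(2); a case shift of 2 * qnorm(auc) gives the
  # target binormal AUC
  delta_a <- 2 * qnorm(0.85)
  delta_b <- 2 * qnorm(0.75)
  rejections <- vapply(1:300, function(i) {
    is_case <- rep(c(TRUE, FALSE), each = 400)
    latent <- rnorm(800)
    a <- latent + rnorm(800) - is_case * delta_a
    b <- latent + rnorm(800) - is_case * delta_b
    delong_paired_test(a, b, is_case)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.5)
})

test_that("the DeLong variance agrees with a bootstrap oracle", {
  set.seed(41)
  cases <- rnorm(100, -0.8)
  controls <- rnorm(100)
  r <- empirical_roc(cases, controls)
  boot <- vapply(1:400, function(i) {
    empirical_roc(sample(cases, replace = TRUE),
                  sample(controls, replace = TRUE))$auc
  }, numeric(1))
  expect_equal(r$auc_se^2, var(boot), tolerance = 0.2)
})

test_that("AUC confidence intervals clip at the boundary and shrink with n", {
  r1 <- empirical_roc(1:50, 101:150)
  expect_equal(r1$auc, 1)
  expect_equal(r1$ci_upper, 1)
  expect_lte(r1$ci_upper - r1$ci_lower, 1e-8) # degenerate placements

  set.seed(51)
  cases <- rnorm(150, -1)
  controls <- rnorm(150)
  small <- empirical_roc(cases, controls)
  big <- empirical_roc(rep(cases, 2), rep(controls, 2))
  width <- function(r) r$ci_upper - r$ci_lower
  # exact duplication leaves placement variance unchanged, halves n
  expect_equal(width(big) / width(small), 1 / sqrt(2), tolerance = 0.02)
})
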