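test_that("Cronbach's alpha matches its defining cases and invariances", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_equal(cronbach_alpha(x), 1)

  # five uncorrelated equal-variance items: expected alpha 0
  set.seed(101)
  u <- matrix(rnorm(5000 * 5), ncol = 5)
  expect_lt(abs(cronbach_alpha(u)), 0.05)

  # invariant under adding a constant to any item
  set.seed(5)
  m <- matrix(rnorm(50 * 4), ncol = 4) + rnorm(50)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 100
  expect_equal(cronbach_alpha(m), cronbach_alpha(shifted))

  expect_error(cronbach_alpha(matrix(1, 10, 3)), "zero")
  expect_error(cronbach_alpha(matrix(1:10, ncol = 1)), "at least 2")
})

test_that("KMO agrees with a regression-based partial-correlation oracle", {
  # two-block structure: r = 0.8 within blocks, 0 between
  r <- diag(1, 4)
  r[1, 2] <- r[2, 1] <- 0.8
  r[3, 4] <- r[4, 3] <- 0.8
  m <- exact_correlation_sample(400, r, seed = 11)
  res <- kmo(m)
  expect_equal(res$kmo_overall, brute_kmo(m), tolerance = 1e-10)

  # near-identity correlations: raw and partial r are almost equal,
  # so the index sits at one half
  r2 <- matrix(0.01, 4, 4)
  diag(r2) <- 1
  m2 <- exact_correlation_sample(400, r2, seed = 12)
  expect_lt(abs(kmo(m2)$kmo_overall - 0.5), 0.02)
  expect_equal(kmo(m2)$kmo_overall, brute_kmo(m2), tolerance = 1e-10)

  # per-item rescaling leaves the correlation-based index unchanged
  m3 <- m
  m3[, 1] <- m3[, 1] * 50
  expect_equal(kmo(m3)$kmo_overall, res$kmo_overall)

  dup <- cbind(m, m[, 1])
  expect_error(kmo(dup), "singular")
})

test_that("Bartlett's sphericity matches the determinant closed form", {
  # exactly orthogonal columns: ln det = 0, chi2 = 0, p = 1
  m <- exact_correlation_sample(100, diag(1, 4), seed = 3)
  b0 <- bartlett_sphericity(m)
  expect_equal(b0$chi2, 0, tolerance = 1e-8)
  expect_equal(b0$p_value, 1)

  # equicorrelation r = 0.5, p = 3: det = (1 - r)^2 (1 + 2r)
  r <- matrix(0.5, 3, 3)
  diag(r) <- 1
  m2 <- exact_correlation_sample(100, r, seed = 4)
  b <- bartlett_sphericity(m2)
  expect_equal(b$df, 3)
  expect_equal(b$chi2,
               -(100 - 1 - (2 * 3 + 5) / 6) * log((1 - 0.5)^2 * (1 + 2 * 0.5)),
               tolerance = 1e-8)

  # the five-item battery has 10 degrees of freedom
  items <- score_haisac(simulate_item_cohort(seed = 2))[
    c("cnocd", "ml", "rfo", "cd", "fd")]
  expect_equal(bartlett_sphericity(items)$df, 10)
  expect_error(bartlett_sphericity(m[1:3, ]), "more subjects")
})

test_that("principal-axis factoring recovers constructed factor models", {
  # rank-1 model: loadings recovered to numerical precision
  lam <- c(0.9, 0.8, 0.7)
  r <- lam %*% t(lam) + diag(1 - lam^2)
  paf <- principal_axis_factoring(r, 1, tol = 1e-10)
  expect_equal(as.numeric(paf$loadings), lam, tolerance = 1e-6)

  # identity: no shared variance, loadings collapse to zero
  paf0 <- principal_axis_factoring(diag(1, 4), 1)
  expect_lt(max(abs(paf0$loadings)), 1e-6)

  # orthogonal two-block model recovered up to column order/sign
  l <- cbind(c(0.9, 0.8, 0.7, 0, 0, 0), c(0, 0, 0, 0.85, 0.75, 0.65))
  r2 <- l %*% t(l) + diag(1 - rowSums(l^2))
  paf2 <- principal_axis_factoring(r2, 2)
  vm <- stats::varimax(paf2$loadings, normalize = FALSE)$loadings
  recovered <- abs(vm[, order(-colSums(vm^2)), drop = FALSE])
  expect_equal(unclass(recovered), unclass(abs(l)), tolerance = 1e-4,
               ignore_attr = TRUE)

  # converged solution fits the off-diagonal at least as well as the
  # SMC start
  fit_residual <- function(loads, r) {
    d <- r - loads %*% t(loads)
    sum(d[row(d) != col(d)]^2)
  }
  smc_start <- 1 - 1 / diag(solve(r2))
  e <- eigen(`diag<-`(r2, smc_start), symmetric = TRUE)
  l_start <- e$vectors[, 1:2] %*% diag(sqrt(pmax(e$values[1:2], 0)))
  expect_lte(fit_residual(paf2$loadings, r2), fit_residual(l_start, r2))

  expect_error(principal_axis_factoring(r, 3), "n_factors")
})

test_that("promax rotation fixes simple structure and matches the reference", {
  # perfect simple structure is (up to sign) a fixed point
  l <- cbind(c(0.8, 0.7, 0.6, 0, 0), c(0, 0, 0, 0.75, 0.8))
  rot <- promax_rotation(l)
  expect_equal(abs(rot$pattern), abs(l), tolerance = 0.02)
  expect_equal(abs(rot$phi[1, 2]), 0, tolerance = 0.05)

  # agrees with the stock promax implementation up to column sign
  set.seed(21)
  theta <- 0.4
  rotmix <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  l2 <- l %*% rotmix
  mine <- promax_rotation(l2)
  ref <- stats::promax(l2, m = 4)
  ref_pattern <- unclass(ref$loadings)
  for (j in 1:2) {
    s <- sign(sum(mine$pattern[, j] * ref_pattern[, j]))
    expect_equal(mine$pattern[, j], s * ref_pattern[, j],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }

  # oblique rotation preserves the model-implied common variance
  implied_mine <- mine$pattern %*% mine$phi %*% t(mine$pattern)
  expect_equal(implied_mine, l2 %*% t(l2), tolerance = 1e-8,
               ignore_attr = TRUE)

  expect_error(promax_rotation(l[, 1, drop = FALSE]), "at least 2")
})

test_that("the EFA pipeline selects and orients factors on constructed data", {
  # strong orthogonal two-block battery: two factors selected, near-zero
  # factor correlation, blocks land on separate factors
  l <- cbind(c(0.9, 0.85, 0.8, 0, 0, 0), c(0, 0, 0, 0.8, 0.75, 0.7))
  r <- l %*% t(l) + diag(1 - rowSums(l^2))
  m <- exact_correlation_sample(600, r, seed = 33)
  colnames(m) <- paste0("it", 1:6)
  res <- efa(m)
  expect_equal(res$n_factors, 2)
  expect_lt(abs(res$phi[1, 2]), 0.1)
  f1 <- which.max(abs(res$pattern[1, ]))
  f2 <- setdiff(1:2, f1)
  expect_true(all(abs(res$pattern[1:3, f1]) > 0.6))
  expect_true(all(abs(res$pattern[4:6, f2]) > 0.55))
  # factors ordered by variance explained, sign convention positive
  expect_gte(res$variance_explained[1], res$variance_explained[2])
  expect_gt(max(res$pattern[, 1]), 0)
  expect_gt(max(res$pattern[, 2]), 0)
  expect_s3_class(autoplot(res), "ggplot")
  td <- tidy(res)
  expect_true(all(c("item", "factor", "loading", "interpretable") %in%
                    names(td)))
  expect_equal(nrow(td), 12)
})

test_that("the default battery's first factor explains roughly 55% of variance", {
  items <- score_haisac(simulate_item_cohort(seed = 3))[
    c("cnocd", "ml", "rfo", "cd", "fd")]
  res <- suppressWarnings(efa(items))
  expect_lt(abs(res$variance_explained[[1]] - 55.23), 5)
  expect_gt(res$adequacy$kmo, 0.6)
  expect_lt(res$adequacy$bartlett$p_value, 0.001)
})

test_that("weighted-sum factor scores follow the loading-times-score rule", {
  m <- cbind(a = c(10, 1), b = c(6, 2))
  expect_equal(factor_scores(m, diag(1, 2))[[1]], c(10, 1))
  expect_equal(as.matrix(factor_scores(m, matrix(0, 2, 2))),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(factor_scores(m, matrix(c(0.5, 0.5), 2, 1))[[1]], c(8, 1.5))
  expect_error(factor_scores(m, matrix(1, 3, 1)), "not match")
})

test_that("sample EFA converges to the population promax solution at large n", {
  # the identifiable estimand is the promax representation of the
  # generating model, computed from the exact implied correlation matrix
  spec <- factor_spec()
  pop <- efa_population <- principal_axis_factoring(
    stats::cov2cor(spec$sigma), 2, max_iter = 10000)
  pop_pat <- promax_rotation(pop$loadings)$pattern

  ic <- simulate_item_cohort(single_group_config("MCI", 5000L), spec,
                             seed = 11)
  res <- efa(attr(ic, "latent_scores"), n_factors = 2, adequacy = "none")
  # align columns by maximal absolute congruence
  congruence <- abs(crossprod(pop_pat, res$pattern)) /
    sqrt(outer(colSums(pop_pat^2), colSums(res$pattern^2)))
  ord <- apply(congruence, 1, which.max)
  est <- res$pattern[, ord]
  for (j in 1:2) {
    if (sum(est[, j] * pop_pat[, j]) < 0) est[, j] <- -est[, j]
  }
  expect_lt(max(abs(est - pop_pat)), 0.10)
})

test_that("dichotomizing an item attenuates its correlations by the biserial factor", {
  # correlation between a thresholded normal and a continuous normal is
  # the latent correlation times dnorm(tau) / sqrt(p (1 - p))
  set.seed(61)
  n <- 200000
  rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  tau <- qnorm(0.7) # binary with p = 0.3
  b <- as.numeric(y > tau)
  p <- mean(b)
  attenuation <- dnorm(tau) / sqrt(p * (1 - p))
  expect_equal(cor(x, b), rho * attenuation, tolerance = 0.01)
  # the factor never exceeds dnorm(0)/0.5 ~ 0.798, which bounds how much
  # of a binary item's loading any correlation-based EFA can see
  expect_lt(attenuation, dnorm(0) / 0.5 + 1e-12)
})
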