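test_that("cohort reproduces configured group sizes and is seed-deterministic", {
  cfg <- cohort_config()
  a <- simulate_cohort(cfg, seed = 7)
  b <- simulate_cohort(cfg, seed = 7)
  c2 <- simulate_cohort(cfg, seed = 8)
  expect_equal(nrow(a), 761)
  expect_equal(as.vector(table(a$group)), c(133, 231, 397))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$haisac_total, c2$haisac_total))
  expect_equal(attr(a, "seed"), 7)
})

test_that("degenerate and invalid configurations are handled", {
  params <- default_group_params()
  params$sd <- 0
  cfg <- cohort_config(params = params)
  co <- simulate_cohort(cfg, seed = 1)
  cu <- co[co$group == "CU", ]
  expect_true(all(cu$haisac_total == 48.47))
  expect_true(all(cu$age == 72.15))

  sizes <- default_group_sizes()
  sizes$n[1] <- 0L
  expect_error(cohort_config(sizes = sizes), "positive")
  expect_error(cohort_config(mode = "other"), "arg")
  expect_error(cohort_config(within_group_correlation = 1), "\\[0, 1\\)")
  bad <- default_group_params()
  bad$variable[1] <- "unknown_var"
  expect_error(cohort_config(params = bad), "unknown_var")
})

test_that("untruncated group means converge to the calibration targets", {
  cfg <- single_group_config("CU", n = 20000L)
  co <- simulate_cohort(cfg, seed = 123)
  se <- 6.58 / sqrt(20000)
  expect_lt(abs(mean(co$haisac_total) - 48.47), 3 * se)
  expect_lt(abs(sd(co$haisac_total) - 6.58), 0.15)
})

test_that("bounded mode respects instrument maxima and score grids", {
  co <- simulate_cohort(cohort_config(mode = "bounded"), seed = 5)
  expect_true(all(co$cd %in% c(0, 8)))
  expect_true(all(co$fd %in% c(0, 12)))
  expect_true(all(co$ml %in% c(0, 2, 4, 6, 8, 10, 12)))
  expect_true(all(co$cdr_sb %% 0.5 == 0 & co$cdr_sb >= 0 & co$cdr_sb <= 18))
  for (v in c("casi", "mmse", "moca", "haisac_total", "haisac3",
              "haisaci", "cnocd", "rfo", "iadl", "npi_sb")) {
    expect_true(all(co[[v]] == round(co[[v]])), label = paste(v, "integer"))
    expect_true(all(co[[v]] >= 0), label = paste(v, "non-negative"))
  }
  expect_true(all(co$haisac_total <= 60) && all(co$casi <= 100) &&
                all(co$iadl <= 8))
  # binary items land near the mean/maximum calibration probabilities
  cu <- co[co$group == "CU", ]
  expect_lt(abs(mean(cu$cd == 8) - 2.71 / 8), 0.15)
})

test_that("moment_check flags constructed deviations and rejects empty cohorts", {
  cfg <- cohort_config()
  co <- simulate_cohort(cfg, seed = 2)
  mc <- moment_check(co, cfg)
  expect_equal(nrow(mc), 3 * 16)
  expect_true(mean(mc$flag) < 0.05) # 4-SE flags should be rare

  shifted <- co
  shifted$casi <- shifted$casi + 25
  mc2 <- moment_check(shifted, cfg)
  expect_true(all(mc2$flag[mc2$variable == "casi"]))

  expect_error(moment_check(co[0, ], cfg), "empty")
  expect_error(moment_check(co[, 1:3], cfg), "lacks")
})

test_that("item cohorts re-score consistently with their continuous targets", {
  ic <- simulate_item_cohort(seed = 31)
  expect_equal(nrow(ic), 761)
  sc <- score_haisac(ic)
  lat <- attr(ic, "latent_scores")
  # discretization is faithful for the finely graded objective subtests
  expect_gt(cor(lat$cnocd, sc$cnocd), 0.95)
  expect_gt(cor(lat$rfo, sc$rfo), 0.95)
  expect_gt(cor(lat$ml, sc$ml), 0.9)
  # binary informant items agree with their thresholded targets exactly
  expect_equal(sc$cd, ifelse(lat$cd > 4, 8, 0))
  expect_equal(sc$fd, ifelse(lat$fd > 6, 12, 0))
  # determinism
  expect_identical(as.data.frame(simulate_item_cohort(seed = 31)),
                   as.data.frame(ic))
})

test_that("a rank-1 noiseless factor spec makes all standardized items identical", {
  l <- matrix(c(rep(1, 5), rep(0, 5)), ncol = 2,
              dimnames = list(c("cnocd", "rfo", "ml", "cd", "fd"),
                              c("SMCB", "INF")))
  spec <- factor_spec(l, factor_correlation = 0, uniquenesses = rep(0, 5))
  ic <- simulate_item_cohort(single_group_config("MCI", 200L), spec,
                             seed = 9)
  lat <- attr(ic, "latent_scores")
  z <- scale(as.matrix(lat))
  expect_lt(max(abs(z - z[, 1])), 1e-8)
})

test_that("the implied covariance orders inter-item correlations as specified", {
  spec <- factor_spec()
  r <- stats::cov2cor(spec$sigma)
  # CD loads on the informant factor: closer to FD than to ML
  expect_gt(r["cd", "fd"], r["cd", "ml"])
  # and the empirical latent scores agree at large n
  ic <- simulate_item_cohort(single_group_config("MCI", 4000L), spec,
                             seed = 17)
  lat <- as.matrix(attr(ic, "latent_scores"))
  expect_gt(cor(lat[, "cd"], lat[, "fd"]), cor(lat[, "cd"], lat[, "ml"]))
})

test_that("inadmissible factor specs are rejected", {
  l <- matrix(c(0.9, 0, 0.9, 0, 0.9, 0, 0, 0.9, 0.9, 0.9), ncol = 2,
              byrow = TRUE,
              dimnames = list(c("cnocd", "rfo", "ml", "cd", "fd"), NULL))
  # fd communality with high correlation exceeds 1
  expect_error(factor_spec(l, factor_correlation = 0.9), "communal")
  expect_error(factor_spec(matrix(1.2, 5, 2)), "exceed 1")
})
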