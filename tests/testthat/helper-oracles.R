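# Independent oracles and fixture builders used across the suite.

# exhaustive Mann-Whitney pair counting (ties count one half)
brute_auc <- function(cases, controls) {
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (x < y) + 0.5 * (x == y)
    }
  }
  total / (length(cases) * length(controls))
}

# partial correlation of columns i, j given all others, via regression
# residuals (independent of the inverse-correlation-matrix route)
brute_partial_cor <- function(m, i, j) {
  others <- setdiff(seq_len(ncol(m)), c(i, j))
  if (!length(others)) return(cor(m[, i], m[, j]))
  ri <- stats::residuals(stats::lm(m[, i] ~ m[, others]))
  rj <- stats::residuals(stats::lm(m[, j] ~ m[, others]))
  cor(ri, rj)
}

# KMO recomputed from scratch with regression-based partials
brute_kmo <- function(m) {
  r <- cor(m)
  p <- diag(1, ncol(m))
  for (i in seq_len(ncol(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      p[i, j] <- p[j, i] <- brute_partial_cor(m, i, j)
    }
  }
  off <- row(r) != col(r)
  sum(r[off]^2) / (sum(r[off]^2) + sum(p[off]^2))
}

# sample with EXACT mean and sd (n-1 denominator)
exact_moment_sample <- function(n, mean, sd, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- as.numeric(scale(rnorm(n)))
  mean + sd * z
}

# data whose sample correlation matrix is EXACTLY `r`: orthonormalize,
# then color with the Cholesky factor
exact_correlation_sample <- function(n, r, seed = 1) {
  set.seed(seed)
  p <- ncol(r)
  z <- matrix(rnorm(n * p), n, p)
  z <- qr.Q(qr(scale(z, scale = FALSE)))[, seq_len(p)]
  z <- scale(z) # exact unit sd, zero mean, exactly orthogonal columns
  z %*% chol(r)
}

# one-row raw item record from component targets
build_item_record <- function(n_names = 6, n_colors = 6,
                              watch = "full", ml = 6L, rfo = 12L,
                              cd_neg = TRUE, fd_neg = TRUE, id = "s1") {
  rec <- perfect_item_record(id)
  rec[paste0("name_", 1:6)] <- as.list(seq_len(6) <= n_names)
  rec[paste0("color_", 1:6)] <- as.list(seq_len(6) <= n_colors)
  rec$watch_grade <- watch
  rec$ml_correct <- ml
  rec$rfo_correct <- rfo
  rec$cd_no_decline <- cd_neg
  rec$fd_no_interference <- fd_neg
  rec
}

# random valid raw item table
random_item_table <- function(n, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    build_item_record(
      n_names = sample(0:6, 1), n_colors = sample(0:6, 1),
      watch = sample(names(watch_grade_points), 1),
      ml = sample(0:6, 1), rfo = sample(0:12, 1),
      cd_neg = sample(c(TRUE, FALSE), 1),
      fd_neg = sample(c(TRUE, FALSE), 1),
      id = sprintf("r%03d", i))
  }))
}

# small single-group cohort config for focused simulations
single_group_config <- function(group = "MCI", n = 1000L,
                                mode = "untruncated") {
  all_params <- default_group_params()
  cohort_config(
    sizes = tibble::tibble(group = group, n = as.integer(n),
                           male_proportion = 0.4),
    params = all_params[all_params$group == group, ],
    mode = mode)
}
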