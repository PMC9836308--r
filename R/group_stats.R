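# Group-comparison layer: one-way ANOVA (raw or from printed summary
# statistics), Bonferroni-corrected pairwise contrasts, chi-square
# independence, Pearson correlations with strength bands, and Steiger's
# test for dependent correlations.

new_anova_result <- function(f, df_between, df_within, pairwise, groups,
                             alpha) {
  structure(list(f_statistic = f, df_between = df_between,
                 df_within = df_within,
                 p_value = pf(f, df_between, df_within, lower.tail = FALSE),
                 pairwise = pairwise, groups = groups, alpha = alpha),
            class = "haisac_anova")
}

# pooled two-sample t test from per-group summary moments
pairwise_t_from_summary <- function(ns, means, sds, labels, alpha) {
  pairs <- utils::combn(seq_along(ns), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    sp2 <- ((ns[i] - 1) * sds[i]^2 + (ns[j] - 1) * sds[j]^2) /
      (ns[i] + ns[j] - 2)
    se <- sqrt(sp2 * (1 / ns[i] + 1 / ns[j]))
    t_stat <- if (se > 0) (means[i] - means[j]) / se else NA_real_
    df <- ns[i] + ns[j] - 2
    p <- if (is.na(t_stat)) NA_real_ else 2 * pt(-abs(t_stat), df)
    tibble::tibble(group_1 = labels[i], group_2 = labels[j],
                   t = unname(t_stat), df = df, p_value = unname(p),
                   significant = !is.na(p) & p < alpha)
  })
}

#' One-way ANOVA with Bonferroni-corrected pairwise contrasts
#'
#' Classical between/within decomposition, followed by pooled-variance
#' two-sample t tests for every group pair, flagged at the corrected
#' alpha (default 0.017, i.e. 0.05 over three pairwise contrasts).
#'
#' @param values Numeric response vector.
#' @param group_labels Group membership, same length.
#' @param alpha Per-contrast significance level for the pairwise flags.
#' @return Object of class `haisac_anova` with the F statistic, degrees
#'   of freedom, p-value, per-group summary, and pairwise contrasts.
#' @examples
#' anova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
anova_oneway <- function(values, group_labels, alpha = 0.017) {
  if (length(values) != length(group_labels)) {
    abort("`values` and `group_labels` must have the same length.")
  }
  keep <- complete.cases(values, group_labels)
  values <- values[keep]
  group_labels <- as.character(group_labels)[keep]
  tab <- table(group_labels)
  if (length(tab) < 2) abort("Need at least 2 groups.")
  if (any(tab < 2)) {
    abort(paste0("Every group needs at least 2 observations; degenerate: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  labels <- names(tab)
  ns <- as.integer(tab[labels])
  means <- vapply(labels, function(g) mean(values[group_labels == g]),
                  numeric(1))
  sds <- vapply(labels, function(g) sd(values[group_labels == g]),
                numeric(1))
  anova_from_summary(ns, means, sds, labels = labels, alpha = alpha)
}

#' One-way ANOVA from per-group summary statistics
#'
#' Recovers the exact F test from group sizes, means and (sample,
#' n-1 denominator) SDs:
#' `SS_between = sum(n_i (mean_i - grand mean)^2)`,
#' `MS_within = sum((n_i - 1) sd_i^2) / (N - k)`. Identical to
#' [anova_oneway()] on any raw data with exactly these moments, which
#' makes published summary tables directly reproducible.
#'
#' @param ns Integer group sizes (each at least 2).
#' @param means Group means.
#' @param sds Group sample SDs (non-negative).
#' @param labels Optional group labels.
#' @param alpha Per-contrast level for the pairwise flags.
#' @return Object of class `haisac_anova`.
#' @examples
#' # age rows of a published three-group table
#' anova_from_summary(c(133, 231, 397), c(72.15, 74.90, 81.17),
#'                    c(7.38, 7.29, 7.81))
#' @export
anova_from_summary <- function(ns, means, sds, labels = NULL,
                               alpha = 0.017) {
  k <- length(ns)
  if (k < 2 || length(means) != k || length(sds) != k) {
    abort("`ns`, `means`, `sds` must have equal length of at least 2.")
  }
  if (any(ns < 2)) abort("Every group needs n of at least 2.")
  if (any(sds < 0)) abort("SDs must be non-negative.")
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  n_total <- sum(ns)
  grand <- sum(ns * means) / n_total
  ss_between <- sum(ns * (means - grand)^2)
  ms_within <- sum((ns - 1) * sds^2) / (n_total - k)
  if (ms_within == 0) {
    abort("All within-group variances are zero; F is undefined (0/0).")
  }
  f <- (ss_between / (k - 1)) / ms_within
  groups <- tibble::tibble(group = labels, n = as.integer(ns),
                           mean = means, sd = sds)
  pairwise <- pairwise_t_from_summary(ns, means, sds, labels, alpha)
  new_anova_result(f, k - 1L, as.integer(n_total - k), pairwise, groups,
                   alpha)
}

#' @export
print.haisac_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  sig <- dplyr::filter(x$pairwise, .data$significant)
  cat(sprintf("Pairwise contrasts significant at alpha = %.3f: %s\n",
              x$alpha,
              if (nrow(sig)) {
                paste(sig$group_1, "vs", sig$group_2, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' @method tidy haisac_anova
#' @export
tidy.haisac_anova <- function(x, ...) x$pairwise

#' @method glance haisac_anova
#' @export
glance.haisac_anova <- function(x, ...) {
  tibble::tibble(f_statistic = x$f_statistic, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value)
}

#' Chi-square test of independence
#'
#' Pearson's chi-square on a contingency table, expected counts from the
#' margins, no continuity correction (matching the usual reporting of
#' group-by-sex comparisons).
#'
#' @param contingency_table Matrix of non-negative counts, at least 2 x 2.
#' @return List with `chi2`, `df`, `p_value`, and the `expected` counts.
#' @examples
#' chi_square_independence(rbind(c(59, 74), c(89, 142), c(119, 278)))
#' @export
chi_square_independence <- function(contingency_table) {
  m <- as.matrix(contingency_table)
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least a 2 x 2 table.")
  if (any(m < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Table has a zero margin; the test is undefined.")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

# strength band by absolute value: weak < 0.4 <= moderate < 0.7 <= strong
correlation_strength <- function(r) {
  dplyr::case_when(abs(r) >= 0.7 ~ "strong",
                   abs(r) >= 0.4 ~ "moderate",
                   TRUE ~ "weak")
}

#' Pearson correlations with strength bands
#'
#' Correlates the given variable pairs (all pairs by default), reporting
#' r, the two-sided p-value, and the conventional strength band: weak
#' (|r| < 0.4), moderate (0.4 <= |r| < 0.7), strong (|r| >= 0.7).
#'
#' @param data Data frame of numeric variables.
#' @param variables Columns to correlate; defaults to every numeric
#'   column.
#' @param pairs Optional two-column data frame / matrix of variable-name
#'   pairs; overrides the all-pairs default.
#' @return Object of class `haisac_correlations` with `r_matrix`,
#'   `p_matrix`, and a tidy `table` (var_1, var_2, r, p_value, strength,
#'   n).
#' @export
pearson_correlations <- function(data, variables = NULL, pairs = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(variables)) {
    variables <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols)) {
    abort(paste0("Unknown variable(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(pairs)) {
    idx <- utils::combn(variables, 2)
    pairs <- tibble::tibble(var_1 = idx[1, ], var_2 = idx[2, ])
  } else {
    pairs <- tibble::as_tibble(as.data.frame(pairs,
                                             stringsAsFactors = FALSE))
    names(pairs) <- c("var_1", "var_2")
  }
  tab <- purrr::pmap_dfr(pairs, function(var_1, var_2) {
    x <- data[[var_1]]
    y <- data[[var_2]]
    keep <- complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 3) {
      abort(paste0("Need at least 3 complete observations for ",
                   var_1, " vs ", var_2, "."))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      abort(paste0("Zero variance in ", var_1, " or ", var_2,
                   "; correlation undefined."))
    }
    ct <- stats::cor.test(x, y)
    tibble::tibble(var_1 = var_1, var_2 = var_2,
                   r = unname(ct$estimate), p_value = ct$p.value,
                   strength = correlation_strength(unname(ct$estimate)),
                   n = length(x))
  })
  r_matrix <- diag(1, length(variables))
  p_matrix <- matrix(NA_real_, length(variables), length(variables))
  dimnames(r_matrix) <- dimnames(p_matrix) <- list(variables, variables)
  for (i in seq_len(nrow(tab))) {
    v1 <- tab$var_1[i]
    v2 <- tab$var_2[i]
    if (v1 %in% variables && v2 %in% variables) {
      r_matrix[v1, v2] <- r_matrix[v2, v1] <- tab$r[i]
      p_matrix[v1, v2] <- p_matrix[v2, v1] <- tab$p_value[i]
    }
  }
  structure(list(r_matrix = r_matrix, p_matrix = p_matrix, table = tab),
            class = "haisac_correlations")
}

#' @export
print.haisac_correlations <- function(x, digits = 2, ...) {
  cat("Pearson correlations:\n")
  print(round(x$r_matrix, digits))
  invisible(x)
}

#' @method tidy haisac_correlations
#' @export
tidy.haisac_correlations <- function(x, ...) x$table

#' Steiger's test for two dependent (overlapping) correlations
#'
#' Compares `r_jk` and `r_jh` -- two correlations sharing variable j,
#' e.g. education against two different tests measured on the same
#' subjects -- accounting for the correlation `r_kh` between the two
#' non-shared variables. Uses Fisher z transforms with the
#' back-transformed average correlation in the covariance term.
#'
#' @param r_jk,r_jh The two correlations being compared (share variable
#'   j).
#' @param r_kh Correlation between the non-shared variables k and h.
#' @param n Sample size (> 3).
#' @return List with `z` and two-sided `p_value`.
#' @examples
#' steiger_dependent_correlation_test(0.5, 0.5, 0.3, 100) # z = 0, p = 1
#' @export
steiger_dependent_correlation_test <- function(r_jk, r_jh, r_kh, n) {
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) {
    abort("Correlations must lie strictly inside (-1, 1).")
  }
  if (n <= 3) abort("Need n > 3.")
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rbar <- tanh((z1 + z2) / 2)
  num <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  cov_z <- num / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_z))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}
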