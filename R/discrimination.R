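# ROC layer. Screening orientation throughout: the impaired group scores
# LOWER, is the positive class, and a positive call is score <= threshold.

# pairwise placement values: for each case, the fraction of controls it
# scores below (ties half); and symmetrically for each control
placement_values <- function(cases, controls) {
  list(
    cases = vapply(cases, function(x) {
      mean((x < controls) + 0.5 * (x == controls))
    }, numeric(1)),
    controls = vapply(controls, function(y) {
      mean((cases < y) + 0.5 * (cases == y))
    }, numeric(1))
  )
}

#' Empirical ROC curve with Youden-index optimal cutoff
#'
#' Sweeps thresholds over the pooled unique scores, calling score <=
#' threshold positive with the impaired (lower-scoring) group as cases.
#' The AUC is the Mann-Whitney probability estimate (ties counted one
#' half); the optimal cutoff maximizes Youden's J = sensitivity +
#' specificity - 1, taking the lowest cutoff (highest specificity) on
#' ties; for integer scales it is rendered as the conventional "a/b" pair.
#'
#' @param scores_cases Scores of the impaired group.
#' @param scores_controls Scores of the reference group.
#' @param level Confidence level for the AUC interval (DeLong variance,
#'   normal approximation, clipped to `[0, 1]`).
#' @return Object of class `haisac_roc`: the `curve` (threshold,
#'   sensitivity, specificity), `auc`, `auc_se`, `ci_lower`/`ci_upper`,
#'   `optimal_cutoff`, `cutoff_label`, `youden_j`, and the sensitivity and
#'   specificity achieved at the optimum.
#' @examples
#' r <- empirical_roc(c(1, 2, 3), c(2, 3, 4))
#' r$auc # 7/9: six strict wins plus two ties counted half
#' @export
empirical_roc <- function(scores_cases, scores_controls, level = 0.95) {
  if (!length(scores_cases) || !length(scores_controls)) {
    abort("Both groups must be non-empty.")
  }
  if (anyNA(scores_cases) || anyNA(scores_controls)) {
    abort("Scores must not contain missing values.")
  }
  m <- length(scores_cases)
  n <- length(scores_controls)
  thresholds <- sort(unique(c(scores_cases, scores_controls)))
  sens <- vapply(thresholds, function(t) mean(scores_cases <= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores_controls > t),
                 numeric(1))
  pl <- placement_values(scores_cases, scores_controls)
  auc <- mean(pl$cases)
  auc_se <- sqrt(var(pl$cases) / m + var(pl$controls) / n)
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # thresholds ascending: first = lowest
  cutoff <- thresholds[best]
  label <- if (all(thresholds == round(thresholds))) {
    sprintf("%d/%d", floor(cutoff), floor(cutoff) + 1)
  } else {
    sprintf("%.2f", cutoff)
  }
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    curve = tibble::tibble(threshold = thresholds, sensitivity = sens,
                           specificity = spec),
    auc = auc, auc_se = auc_se,
    ci_lower = max(0, auc - z * auc_se),
    ci_upper = min(1, auc + z * auc_se),
    conf_level = level,
    optimal_cutoff = cutoff, cutoff_label = label,
    youden_j = j[best], sensitivity = sens[best], specificity = spec[best],
    n_cases = m, n_controls = n,
    placements = pl), class = "haisac_roc")
}

#' @export
print.haisac_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (%d%% CI %.3f-%.3f), n = %d cases / %d controls\n",
    x$auc, round(100 * x$conf_level), x$ci_lower, x$ci_upper,
    x$n_cases, x$n_controls))
  cat(sprintf(
    "Optimal cutoff %s (Youden J = %.3f): sensitivity %.2f, specificity %.2f\n",
    x$cutoff_label, x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' @method tidy haisac_roc
#' @export
tidy.haisac_roc <- function(x, ...) x$curve

#' @method glance haisac_roc
#' @export
glance.haisac_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_se = x$auc_se, ci_lower = x$ci_lower,
                 ci_upper = x$ci_upper, optimal_cutoff = x$optimal_cutoff,
                 cutoff_label = x$cutoff_label, youden_j = x$youden_j,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_cases = x$n_cases, n_controls = x$n_controls)
}

#' ROC curve plot
#'
#' @param object A `haisac_roc` object.
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity with the chance
#'   diagonal and the Youden-optimal operating point marked.
#' @method autoplot haisac_roc
#' @export
autoplot.haisac_roc <- function(object, ...) {
  curve <- dplyr::arrange(object$curve, 1 - .data$specificity,
                          .data$sensitivity)
  curve <- dplyr::bind_rows(
    tibble::tibble(threshold = NA_real_, sensitivity = 0, specificity = 1),
    curve)
  ggplot2::ggplot(curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f (cutoff %s)", object$auc,
                                  object$cutoff_label)) +
    ggplot2::theme_minimal()
}

#' Analytic AUC of two normal score distributions
#'
#' `pnorm(|mean_controls - mean_cases| / sqrt(sd_cases^2 + sd_controls^2))`
#' -- the AUC implied by binormal score distributions, used to calibrate
#' the simulator against published group moments.
#'
#' @param mean_cases,sd_cases Moments of the impaired group.
#' @param mean_controls,sd_controls Moments of the reference group.
#' @return AUC in `[0.5, 1]` (degenerate zero-SD case: 1 if the means
#'   differ, else 0.5).
#' @examples
#' binormal_auc(0, 1, 1.414, 1) # ~0.841
#' @export
binormal_auc <- function(mean_cases, sd_cases, mean_controls, sd_controls) {
  if (sd_cases < 0 || sd_controls < 0) abort("SDs must be non-negative.")
  s <- sqrt(sd_cases^2 + sd_controls^2)
  if (s == 0) return(if (mean_cases != mean_controls) 1 else 0.5)
  pnorm(abs(mean_controls - mean_cases) / s)
}

#' DeLong's test for two paired AUCs
#'
#' Compares the AUCs of two tests measured on the same subjects using the
#' placement-value (structural-components) estimator of the paired AUC
#' covariance matrix, with a chi-square(1) statistic for the difference.
#'
#' @param scores_test_a,scores_test_b Score vectors of the two tests, one
#'   entry per subject, in the same subject order.
#' @param is_case Logical vector flagging the impaired (lower-scoring,
#'   positive) group.
#' @return Object of class `haisac_delong`: `auc_a`, `auc_b`,
#'   `auc_diff`, `var_diff`, `z`, `chi2` (= z^2), `df` (1), `p_value`.
#' @export
delong_paired_test <- function(scores_test_a, scores_test_b, is_case) {
  if (length(scores_test_a) != length(scores_test_b) ||
      length(scores_test_a) != length(is_case)) {
    abort("Both score vectors and `is_case` must have one entry per subject.")
  }
  is_case <- as.logical(is_case)
  if (anyNA(is_case) || anyNA(scores_test_a) || anyNA(scores_test_b)) {
    abort("Inputs must not contain missing values.")
  }
  m <- sum(is_case)
  n <- sum(!is_case)
  if (m < 2 || n < 2) abort("Need at least 2 cases and 2 controls.")
  pa <- placement_values(scores_test_a[is_case], scores_test_a[!is_case])
  pb <- placement_values(scores_test_b[is_case], scores_test_b[!is_case])
  auc_a <- mean(pa$cases)
  auc_b <- mean(pb$cases)
  v10 <- cbind(pa$cases, pb$cases)        # per-case components
  v01 <- cbind(pa$controls, pb$controls)  # per-control components
  s <- cov(v10) / m + cov(v01) / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- auc_a - auc_b
  z <- if (var_diff > 0) d / sqrt(var_diff) else 0
  chi2 <- z^2
  p <- if (var_diff > 0) pchisq(chi2, 1, lower.tail = FALSE) else 1
  structure(list(auc_a = auc_a, auc_b = auc_b, auc_diff = d,
                 var_diff = var_diff, covariance = s, z = z, chi2 = chi2,
                 df = 1L, p_value = p, n_cases = m, n_controls = n),
            class = "haisac_delong")
}

#' @export
print.haisac_delong <- function(x, ...) {
  cat(sprintf(
    "DeLong paired AUC test: %.3f vs %.3f (diff %.3f)\n  chi2(1) = %.2f, p = %.3g\n",
    x$auc_a, x$auc_b, x$auc_diff, x$chi2, x$p_value))
  invisible(x)
}

#' @method glance haisac_delong
#' @export
glance.haisac_delong <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, auc_diff = x$auc_diff,
                 z = x$z, chi2 = x$chi2, df = x$df, p_value = x$p_value)
}

#' Confidence interval for an empirical AUC
#'
#' Normal-approximation interval using the DeLong placement-value
#' variance stored in the ROC object, clipped to `[0, 1]`.
#'
#' @param roc A `haisac_roc` object.
#' @param level Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
auc_confidence_interval <- function(roc, level = 0.95) {
  stopifnot(inherits(roc, "haisac_roc"))
  z <- qnorm(1 - (1 - level) / 2)
  c(lower = max(0, roc$auc - z * roc$auc_se),
    upper = min(1, roc$auc + z * roc$auc_se))
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' Under the screening orientation: sensitivity is the fraction of cases
#' at or below the cutoff, specificity the fraction of controls above it.
#'
#' @param scores_cases,scores_controls Group score vectors.
#' @param cutoff Threshold score.
#' @return Named numeric `c(sensitivity, specificity)`.
#' @examples
#' sens_spec_at_cutoff(c(30, 35), c(45, 50), 40) # 1, 1
#' @export
sens_spec_at_cutoff <- function(scores_cases, scores_controls, cutoff) {
  c(sensitivity = mean(scores_cases <= cutoff),
    specificity = mean(scores_controls > cutoff))
}
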