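# Reliability and exploratory-factor-analysis layer: Cronbach's alpha,
# KMO sampling adequacy, Bartlett's sphericity, iterated principal-axis
# factoring and varimax-then-promax rotation.

as_item_matrix <- function(data, what = "data") {
  m <- as.matrix(data)
  if (!is.numeric(m)) abort(paste0("`", what, "` must be numeric."))
  if (anyNA(m)) abort(paste0("`", what, "` contains missing values."))
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `(k/(k-1)) * (1 - sum(item variances) / variance(item sums))`, with
#' sample (n-1 denominator) variances throughout.
#'
#' @param data Subjects x items matrix or data frame of item scores.
#' @return The alpha coefficient (scalar; can be negative, never above 1).
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
#' cronbach_alpha(x) # 1
#' @export
cronbach_alpha <- function(data) {
  m <- as_item_matrix(data)
  k <- ncol(m)
  if (k < 2 || nrow(m) < 2) abort("Need at least 2 items and 2 subjects.")
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    abort("Total-score variance is zero; alpha is undefined.")
  }
  (k / (k - 1)) * (1 - sum(apply(m, 2, var)) / total_var)
}

# partial correlations (anti-image) from the inverse correlation matrix
partial_correlations <- function(r) {
  inv <- tryCatch(solve(r), error = function(e) {
    dup <- which(abs(r - 1) < 1e-12 & row(r) != col(r), arr.ind = TRUE)
    hint <- if (nrow(dup)) {
      paste0(" (items ", paste(rownames(r)[dup[1, ]], collapse = " and "),
             " are collinear)")
    } else ""
    abort(paste0("Correlation matrix is singular", hint,
                 "; KMO is undefined."))
  })
  p <- -stats::cov2cor(inv)
  diag(p) <- 1
  p
}

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Contrasts raw and partial correlations:
#' `sum(r^2) / (sum(r^2) + sum(partial^2))` over off-diagonal entries,
#' overall and per item. Values below 0.6 indicate the data are inadequate
#' for factor analysis.
#'
#' @param data Subjects x items matrix/data frame, or a correlation matrix
#'   (square, unit diagonal).
#' @return List with `kmo_overall` and named `kmo_per_item`.
#' @export
kmo <- function(data) {
  m <- as_item_matrix(data)
  r <- if (nrow(m) == ncol(m) && all(abs(diag(m) - 1) < 1e-12)) m else cor(m)
  p <- partial_correlations(r)
  off <- row(r) != col(r)
  r2 <- r^2 * off
  p2 <- p^2 * off
  list(kmo_overall = sum(r2) / (sum(r2) + sum(p2)),
       kmo_per_item = setNames(rowSums(r2) / (rowSums(r2) + rowSums(p2)),
                               colnames(r)))
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix is an identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param data Subjects x items matrix or data frame.
#' @return List with `chi2`, `df`, `p_value`, and `n`.
#' @export
bartlett_sphericity <- function(data) {
  m <- as_item_matrix(data)
  n <- nrow(m)
  p <- ncol(m)
  if (n <= p) abort("Need more subjects than items.")
  r <- cor(m)
  d <- det(r)
  if (d <= 0) abort("Correlation matrix has non-positive determinant.")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE), n = n)
}

#' Reliability and factorability summary for an item battery
#'
#' Bundles Cronbach's alpha, the KMO index and Bartlett's sphericity test.
#'
#' @param data Subjects x items matrix or data frame.
#' @return Object of class `haisac_reliability` with fields `alpha`,
#'   `kmo_overall`, `kmo_per_item`, `bartlett_chi2`, `bartlett_df`,
#'   `bartlett_p`, `n`, `k`.
#' @export
reliability <- function(data) {
  m <- as_item_matrix(data)
  k_res <- kmo(m)
  b <- bartlett_sphericity(m)
  structure(list(alpha = cronbach_alpha(m),
                 kmo_overall = k_res$kmo_overall,
                 kmo_per_item = k_res$kmo_per_item,
                 bartlett_chi2 = b$chi2, bartlett_df = b$df,
                 bartlett_p = b$p_value, n = nrow(m), k = ncol(m)),
            class = "haisac_reliability")
}

#' @method glance haisac_reliability
#' @export
glance.haisac_reliability <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, kmo = x$kmo_overall,
                 bartlett_chi2 = x$bartlett_chi2,
                 bartlett_df = x$bartlett_df, bartlett_p = x$bartlett_p,
                 n = x$n, k = x$k)
}

#' @export
print.haisac_reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha: %.3f  (k = %d items, n = %d)\n",
              x$alpha, x$k, x$n))
  cat(sprintf("KMO overall:      %.3f\n", x$kmo_overall))
  cat(sprintf("Bartlett:         chi2(%d) = %.2f, p = %.3g\n",
              x$bartlett_df, x$bartlett_chi2, x$bartlett_p))
  invisible(x)
}

# squared multiple correlations from the inverse correlation matrix
smc <- function(r) {
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv)) return(apply(abs(r - diag(diag(r))), 1, max))
  1 - 1 / diag(inv)
}

#' Iterated principal-axis factoring
#'
#' Common-factor extraction: the correlation diagonal is replaced by
#' communality estimates (initialized at the squared multiple
#' correlations), the reduced matrix is eigendecomposed, loadings are
#' rebuilt from the leading eigenpairs, and the cycle repeats until the
#' largest communality change falls below `tol`.
#'
#' @param r Item correlation matrix.
#' @param n_factors Number of factors to extract (at least 1, fewer than
#'   the number of items).
#' @param max_iter Iteration cap (default 10000; with a weak or
#'   two-indicator trailing factor the communality iteration converges
#'   geometrically with ratio near 1 and can need several thousand
#'   cycles, each a cheap eigendecomposition); non-convergence is an
#'   error carrying the last communality change.
#' @param tol Convergence tolerance on the max-abs communality change.
#' @return List with `loadings` (items x factors), `communalities`,
#'   `iterations`, `eigenvalues` (all eigenvalues of the converged reduced
#'   matrix, descending), and `heywood` (TRUE if any communality exceeded
#'   1, also signalled as a warning).
#' @export
principal_axis_factoring <- function(r, n_factors, max_iter = 10000,
                                     tol = 1e-6) {
  r <- as.matrix(r)
  p <- ncol(r)
  if (n_factors < 1 || n_factors >= p) {
    abort("`n_factors` must be at least 1 and fewer than the item count.")
  }
  h <- smc(r)
  loadings <- NULL
  eigenvalues <- NULL
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    rh <- r
    diag(rh) <- h
    eig <- eigen(rh, symmetric = TRUE)
    keep <- seq_len(n_factors)
    loadings <- eig$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(pmax(eig$values[keep], 0)), n_factors)
    h_new <- rowSums(loadings^2)
    delta <- max(abs(h_new - h))
    h <- h_new
    eigenvalues <- eig$values
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (any(h > 1.5)) {
      abort(paste0(
        "Heywood divergence: communality of item ",
        colnames(r)[which.max(h)],
        " grows without bound; the factor model is inadmissible for ",
        "these data."))
    }
  }
  if (!converged) {
    abort(sprintf(
      "Principal-axis factoring did not converge in %d iterations (last communality change %.3g).",
      max_iter, delta))
  }
  heywood <- any(h > 1 + 1e-8)
  if (heywood) {
    warn("Heywood case: a communality exceeds 1; interpret with caution.")
  }
  # sign convention: largest-|loading| item positive in each column
  for (j in seq_len(n_factors)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- colnames(r)
  colnames(loadings) <- paste0("F", seq_len(n_factors))
  list(loadings = loadings, communalities = setNames(h, colnames(r)),
       iterations = it, eigenvalues = eigenvalues, heywood = heywood)
}

#' Promax oblique rotation
#'
#' Varimax rotation followed by the promax target procedure: an
#' element-wise power target `|loading|^(power-1) * loading` is fit by
#' least squares, the transformation columns are rescaled so the implied
#' factor correlation matrix has a unit diagonal, and the oblique pattern
#' matrix and factor correlations are returned.
#'
#' @param loadings Unrotated loading matrix with at least 2 factors.
#' @param power Promax power (kappa); classical default 4.
#' @return List with `pattern`, `phi` (factor correlation), `structure`
#'   (`pattern %*% phi`), and `rotmat`.
#' @export
promax_rotation <- function(loadings, power = 4) {
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2) {
    abort("Promax rotation needs at least 2 factors.")
  }
  vm <- stats::varimax(loadings, normalize = TRUE)
  x <- vm$loadings[, , drop = FALSE]
  class(x) <- NULL
  target <- abs(x)^(power - 1) * x
  u <- tryCatch(solve(crossprod(x), crossprod(x, target)),
                error = function(e) abort("Promax transformation is singular."))
  d <- diag(solve(crossprod(u)))
  u <- u %*% diag(sqrt(d), ncol(u))
  pattern <- x %*% u
  phi <- solve(crossprod(u))
  rotmat <- vm$rotmat %*% u
  dimnames(pattern) <- dimnames(loadings)
  dimnames(phi) <- list(colnames(loadings), colnames(loadings))
  list(pattern = pattern, phi = phi, structure = pattern %*% phi,
       rotmat = rotmat)
}

#' Exploratory factor analysis of an item battery
#'
#' The full extraction pipeline: sampling-adequacy gate (KMO and
#' Bartlett), iterated principal-axis factoring, and -- for two or more
#' factors -- varimax-then-promax oblique rotation. The default factor
#' count is the number of eigenvalues above 1 of the reduced
#' (SMC-diagonal) correlation matrix. Factors are ordered by variance
#' explained and signed so each column's largest-|loading| item is
#' positive.
#'
#' @param data Subjects x items matrix or data frame of item scores.
#' @param n_factors Number of factors; `NULL` applies the eigenvalue rule.
#' @param adequacy What to do when KMO < 0.6 or Bartlett's p > 0.05:
#'   `"warn"` (default), `"error"`, or `"none"`.
#' @param power Promax power.
#' @return Object of class `haisac_efa`: `n_factors`, `eigenvalues`
#'   (reduced-matrix eigenvalues, descending), `pattern`, `phi`,
#'   `structure`, `communalities`, `variance_explained` (per-factor
#'   percentage from sums of squared structure loadings over the item
#'   count), `heywood`, `adequacy` (KMO/Bartlett block), `n_obs`.
#' @export
efa <- function(data, n_factors = NULL, adequacy = c("warn", "error", "none"),
                power = 4) {
  adequacy <- match.arg(adequacy)
  m <- as_item_matrix(data)
  r <- cor(m)
  gate <- list(kmo = kmo(r)$kmo_overall, bartlett = bartlett_sphericity(m))
  if (adequacy != "none" &&
      (gate$kmo < 0.6 || gate$bartlett$p_value > 0.05)) {
    msg <- sprintf(
      "Data look inadequate for EFA (KMO = %.2f, Bartlett p = %.3g).",
      gate$kmo, gate$bartlett$p_value)
    if (adequacy == "error") abort(msg) else warn(msg)
  }
  r_reduced <- r
  diag(r_reduced) <- smc(r)
  eig_reduced <- sort(eigen(r_reduced, symmetric = TRUE,
                            only.values = TRUE)$values, decreasing = TRUE)
  if (is.null(n_factors)) n_factors <- max(1L, sum(eig_reduced > 1))
  paf <- principal_axis_factoring(r, n_factors)
  if (n_factors >= 2) {
    rot <- promax_rotation(paf$loadings, power = power)
    pattern <- rot$pattern
    phi <- rot$phi
  } else {
    pattern <- paf$loadings
    phi <- matrix(1, 1, 1)
  }
  structure_l <- pattern %*% phi
  varexp <- colSums(structure_l^2) / ncol(m) * 100
  ord <- order(varexp, decreasing = TRUE)
  pattern <- pattern[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  signs <- vapply(seq_len(ncol(pattern)), function(j) {
    if (pattern[which.max(abs(pattern[, j])), j] < 0) -1 else 1
  }, numeric(1))
  pattern <- sweep(pattern, 2, signs, "*")
  phi <- diag(signs, length(signs)) %*% phi %*% diag(signs, length(signs))
  structure_l <- pattern %*% phi
  varexp <- colSums(structure_l^2) / ncol(m) * 100
  fac_names <- paste0("F", seq_len(n_factors))
  dimnames(pattern) <- list(colnames(m), fac_names)
  dimnames(structure_l) <- dimnames(pattern)
  dimnames(phi) <- list(fac_names, fac_names)
  structure(list(n_factors = n_factors, eigenvalues = eig_reduced,
                 pattern = pattern, phi = phi, structure = structure_l,
                 communalities = paf$communalities,
                 variance_explained = setNames(varexp, fac_names),
                 heywood = paf$heywood, adequacy = gate, n_obs = nrow(m)),
            class = "haisac_efa")
}

#' @export
print.haisac_efa <- function(x, digits = 2, ...) {
  cat(sprintf("Exploratory factor analysis: %d factor(s), n = %d\n",
              x$n_factors, x$n_obs))
  cat(sprintf("KMO = %.2f; Bartlett chi2(%d) = %.2f, p = %.3g\n",
              x$adequacy$kmo, x$adequacy$bartlett$df,
              x$adequacy$bartlett$chi2, x$adequacy$bartlett$p_value))
  cat("\nPattern loadings (promax):\n")
  print(round(x$pattern, digits))
  cat("\nFactor correlations:\n")
  print(round(x$phi, digits))
  cat(sprintf("\nVariance explained (%%): %s\n",
              paste(sprintf("%s %.2f", names(x$variance_explained),
                            x$variance_explained), collapse = ", ")))
  if (x$heywood) cat("Warning: Heywood case present.\n")
  invisible(x)
}

#' @method tidy haisac_efa
#' @export
tidy.haisac_efa <- function(x, ...) {
  out <- tibble::as_tibble(x$pattern, rownames = "item")
  out <- tidyr::pivot_longer(out, -"item", names_to = "factor",
                             values_to = "loading")
  dplyr::mutate(out,
                communality = x$communalities[.data$item],
                interpretable = abs(.data$loading) >= 0.30)
}

#' @method glance haisac_efa
#' @export
glance.haisac_efa <- function(x, ...) {
  tibble::tibble(n_factors = x$n_factors,
                 total_variance_explained = sum(x$variance_explained),
                 first_factor_variance = x$variance_explained[[1]],
                 kmo = x$adequacy$kmo,
                 bartlett_p = x$adequacy$bartlett$p_value,
                 heywood = x$heywood, n_obs = x$n_obs)
}

#' Scree plot of an EFA solution
#'
#' @param object A `haisac_efa` object.
#' @param ... Unused.
#' @return A ggplot: eigenvalues of the reduced correlation matrix against
#'   factor index, with the retention line at 1.
#' @method autoplot haisac_efa
#' @export
autoplot.haisac_efa <- function(object, ...) {
  df <- tibble::tibble(factor = seq_along(object$eigenvalues),
                       eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$factor, .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Factor", y = "Eigenvalue (reduced matrix)",
                  title = "Scree plot") +
    ggplot2::theme_minimal()
}

#' Weighted-sum factor scores
#'
#' Per subject and factor, the sum over items of (pattern loading x item
#' score) -- the simple weighted-sum rule, not regression scores.
#'
#' @param data Subjects x items matrix or data frame; columns must match
#'   the loading rows (by name when both are named).
#' @param loadings Items x factors pattern-loading matrix.
#' @return Tibble of subjects x factors scores.
#' @export
factor_scores <- function(data, loadings) {
  m <- as_item_matrix(data)
  loadings <- as.matrix(loadings)
  if (!is.null(rownames(loadings)) && !is.null(colnames(m))) {
    if (!all(rownames(loadings) %in% colnames(m))) {
      abort("Loading rows do not match item columns.")
    }
    m <- m[, rownames(loadings), drop = FALSE]
  } else if (ncol(m) != nrow(loadings)) {
    abort("Item count does not match the loading matrix.")
  }
  scores <- m %*% loadings
  colnames(scores) <- colnames(loadings) %||%
    paste0("F", seq_len(ncol(loadings)))
  tibble::as_tibble(scores)
}
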