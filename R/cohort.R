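# Synthetic three-group cohort generator calibrated from the published
# per-group summary statistics (cognitively unimpaired / MCI / dementia).

cohort_variables <- c(
  "age", "education_years", "cdr_sb", "npi_sb", "iadl", "casi", "mmse",
  "moca", "haisac_total", "haisac3", "haisaci", "cnocd", "ml", "rfo",
  "cd", "fd"
)

# upper bounds used in bounded mode (NA = unbounded above)
variable_maxima <- c(
  age = NA, education_years = NA, cdr_sb = 18, npi_sb = 144, iadl = 8,
  casi = 100, mmse = 30, moca = 30, haisac_total = 60, haisac3 = 40,
  haisaci = 20, cnocd = 16, ml = 12, rfo = 12, cd = 8, fd = 12
)

#' Default per-group calibration of the synthetic cohort
#'
#' The published per-group means and SDs of the demographic, clinical and
#' test-score variables for the three diagnostic groups (CU n = 133,
#' MCI n = 231, DAT n = 397). The informant FD item is calibrated from the
#' informant-subscore identity (HAI-SAC-I = CD + FD), because the published
#' FD row duplicates the IADL row and is inconsistent with that identity;
#' its SD is the binomial SD of a 0/12 item at the implied probability.
#'
#' @return A tibble with columns `group`, `variable`, `mean`, `sd`.
#' @seealso [default_group_sizes()], [cohort_config()]
#' @export
default_group_params <- function() {
  cu <- c(age = 72.15, 7.38, education_years = 7.38, 4.76,
          cdr_sb = 0.35, 0.32, npi_sb = 2.64, 3.45, iadl = 7.79, 0.55,
          casi = 83.86, 8.64, mmse = 25.81, 3.30, moca = 21.07, 5.10,
          haisac_total = 48.47, 6.58, haisac3 = 33.95, 4.53,
          haisaci = 14.53, 4.19, cnocd = 14.85, 1.69, ml = 9.04, 3.07,
          rfo = 10.06, 1.57, cd = 2.71, 3.80,
          fd = 11.82, 12 * sqrt((11.82 / 12) * (1 - 11.82 / 12)))
  mci <- c(age = 74.90, 7.29, education_years = 5.78, 4.43,
           cdr_sb = 1.96, 2.16, npi_sb = 4.42, 6.06, iadl = 6.58, 2.03,
           casi = 73.12, 15.93, mmse = 22.24, 5.20, moca = 15.99, 6.33,
           haisac_total = 38.94, 10.53, haisac3 = 29.77, 6.94,
           haisaci = 9.18, 6.36, cnocd = 13.88, 2.32, ml = 6.83, 4.17,
           rfo = 9.06, 2.07, cd = 0.76, 2.35,
           fd = 8.42, 12 * sqrt((8.42 / 12) * (1 - 8.42 / 12)))
  dat <- c(age = 81.17, 7.81, education_years = 4.27, 4.53,
           cdr_sb = 7.17, 4.58, npi_sb = 6.16, 9.18, iadl = 2.20, 2.53,
           casi = 44.83, 22.70, mmse = 13.98, 6.55, moca = 7.21, 5.40,
           haisac_total = 21.51, 11.29, haisac3 = 19.42, 9.27,
           haisaci = 2.09, 4.71, cnocd = 10.54, 4.37, ml = 2.51, 3.55,
           rfo = 6.37, 3.29, cd = 0.12, 0.98,
           fd = 1.97, 12 * sqrt((1.97 / 12) * (1 - 1.97 / 12)))
  unpack <- function(x, group) {
    m <- matrix(x, ncol = 2, byrow = TRUE)
    tibble::tibble(group = group, variable = cohort_variables,
                   mean = m[, 1], sd = m[, 2])
  }
  dplyr::bind_rows(unpack(cu, "CU"), unpack(mci, "MCI"), unpack(dat, "DAT"))
}

#' Default group sizes and sex composition
#'
#' @return Tibble with columns `group`, `n`, `male_proportion`
#'   (published counts: 59/133, 89/231, 119/397 males).
#' @export
default_group_sizes <- function() {
  tibble::tibble(group = c("CU", "MCI", "DAT"),
                 n = c(133L, 231L, 397L),
                 male_proportion = c(59 / 133, 89 / 231, 119 / 397))
}

#' Assemble a cohort-simulation configuration
#'
#' @param sizes Tibble of `group`, `n`, `male_proportion`; defaults to the
#'   published group sizes.
#' @param params Long tibble of `group`, `variable`, `mean`, `sd`; defaults
#'   to the published calibration.
#' @param mode `"untruncated"` draws plain group-conditional normals
#'   (the calibration used for AUC reproduction); `"bounded"` additionally
#'   clips draws to the instrument ranges and snaps them to each score grid.
#' @param within_group_correlation Weight in `[0, 1)` of a shared
#'   standard-normal subject factor mixed into every standardized variable,
#'   inducing a common within-group correlation of that value; 0 draws
#'   variables independently.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(sizes = default_group_sizes(),
                          params = default_group_params(),
                          mode = c("untruncated", "bounded"),
                          within_group_correlation = 0) {
  mode <- match.arg(mode)
  sizes <- tibble::as_tibble(sizes)
  params <- tibble::as_tibble(params)
  stopifnot(all(c("group", "n", "male_proportion") %in% names(sizes)),
            all(c("group", "variable", "mean", "sd") %in% names(params)))
  if (any(sizes$n <= 0)) abort("Group sizes must be positive.")
  if (any(params$sd < 0)) abort("SDs must be non-negative.")
  if (any(sizes$male_proportion < 0 | sizes$male_proportion > 1)) {
    abort("male_proportion must lie in [0, 1].")
  }
  if (within_group_correlation < 0 || within_group_correlation >= 1) {
    abort("within_group_correlation must lie in [0, 1).")
  }
  unknown <- setdiff(unique(params$variable), cohort_variables)
  if (length(unknown)) {
    abort(paste0("Unknown variable(s) in params: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(list(sizes = sizes, params = params, mode = mode,
                 within_group_correlation = within_group_correlation),
            class = "cohort_config")
}

# run code with a deterministic RNG state, restoring the caller's state
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# entropy-derived seed when the caller supplies none; always recorded
draw_entropy_seed <- function() {
  as.integer(Sys.time()) %% 1000000L * 1000L +
    (Sys.getpid() %% 1000L)
}

# snap a numeric vector to a variable's score grid and bounds
snap_to_grid <- function(x, variable) {
  max_v <- variable_maxima[[variable]]
  if (variable == "cd") return(ifelse(x > 4, 8, 0))
  if (variable == "fd") return(ifelse(x > 6, 12, 0))
  if (variable == "ml") {
    count <- pmax(0, pmin(6, round(x / 2)))
    return(pmin(2 * count, 10) + 2 * (count == 6))
  }
  step <- if (variable == "cdr_sb") 0.5 else 1
  x <- round(x / step) * step
  x <- pmax(x, 0)
  if (!is.na(max_v)) x <- pmin(x, max_v)
  x
}

#' Simulate a scale-level synthetic cohort
#'
#' Draws one row per subject with group-conditional normal scores at the
#' configured means and SDs. In `untruncated` mode the draws are left as-is
#' (this is the calibration under which the published AUCs are reproduced);
#' in `bounded` mode each draw is clipped to the instrument range and
#' snapped to its score grid (CD to \{0, 8\}, FD to \{0, 12\}, ML to even
#' scores with the 12-point perfect bonus, CDR-SB to half points, integers
#' elsewhere). Sex is Bernoulli at the group's male proportion.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; if `NULL` one is drawn from the clock and
#'   recorded. The seed used is always stored in `attr(, "seed")`.
#' @return Tibble with columns `subject_id`, `group` (factor CU/MCI/DAT),
#'   `sex`, and one column per configured variable.
#' @examples
#' cohort <- simulate_cohort(cohort_config(), seed = 1)
#' nrow(cohort) # 761
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) seed <- draw_entropy_seed()
  w <- config$within_group_correlation
  cohort <- with_rng_seed(seed, {
    purrr::pmap_dfr(config$sizes, function(group, n, male_proportion) {
      pars <- dplyr::filter(config$params, .data$group == !!group)
      z_shared <- rnorm(n)
      cols <- purrr::pmap(pars[c("variable", "mean", "sd")],
        function(variable, mean, sd) {
          z <- if (w > 0) {
            sqrt(w) * z_shared + sqrt(1 - w) * rnorm(n)
          } else {
            rnorm(n)
          }
          x <- mean + sd * z
          if (config$mode == "bounded") x <- snap_to_grid(x, variable)
          x
        })
      names(cols) <- pars$variable
      tibble::tibble(group = group,
                     sex = ifelse(rbinom(n, 1, male_proportion) == 1,
                                  "M", "F"),
                     !!!cols)
    })
  })
  cohort <- dplyr::mutate(
    cohort,
    subject_id = sprintf("S%04d", dplyr::row_number()),
    group = factor(.data$group, levels = c("CU", "MCI", "DAT")),
    .before = 1)
  attr(cohort, "seed") <- seed
  attr(cohort, "mode") <- config$mode
  cohort
}

#' Two-factor latent specification for the item-level generator
#'
#' The five scored items load on two correlated factors: the objective
#' subtests (naming, location memory, function recall) on a semantic-
#' memory/contextual-binding factor (SMCB) and the informant items on an
#' informant factor (INF), with the functional-decline item cross-loading
#' on both. Defaults are the published pattern loadings; the inter-factor
#' correlation defaults to 0.5, consistent with the published
#' informant-vs-cognitive-test correlations.
#'
#' @param loadings 5 x 2 matrix, rows `cnocd`, `rfo`, `ml`, `cd`, `fd`,
#'   columns `SMCB`, `INF`.
#' @param factor_correlation Scalar correlation between the two factors.
#' @param uniquenesses Per-item unique variances; default `1 - communality`
#'   so standardized items have unit variance.
#' @return Object of class `factor_spec`.
#' @export
factor_spec <- function(loadings = NULL, factor_correlation = 0.5,
                        uniquenesses = NULL) {
  if (is.null(loadings)) {
    loadings <- matrix(c(0.95, 0, 0.96, 0, 0.55, 0, 0, 0.97, 0.48, 0.45),
                       ncol = 2, byrow = TRUE,
                       dimnames = list(c("cnocd", "rfo", "ml", "cd", "fd"),
                                       c("SMCB", "INF")))
  }
  loadings <- as.matrix(loadings)
  if (ncol(loadings) != 2 || nrow(loadings) != 5) {
    abort("`loadings` must be a 5 x 2 matrix over (cnocd, rfo, ml, cd, fd).")
  }
  if (any(abs(loadings) > 1)) abort("|loading| must not exceed 1.")
  if (abs(factor_correlation) >= 1) {
    abort("Factor correlation must lie strictly inside (-1, 1).")
  }
  phi <- matrix(c(1, factor_correlation, factor_correlation, 1), 2)
  communality <- rowSums((loadings %*% phi) * loadings)
  if (is.null(uniquenesses)) uniquenesses <- 1 - communality
  if (any(uniquenesses < 0)) {
    abort("Implied communalities exceed 1; reduce loadings or correlation.")
  }
  sigma <- loadings %*% phi %*% t(loadings) + diag(as.numeric(uniquenesses))
  if (any(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort("Implied item covariance is not positive definite.")
  }
  structure(list(loadings = loadings, factor_correlation = factor_correlation,
                 uniquenesses = as.numeric(uniquenesses), sigma = sigma),
            class = "factor_spec")
}

# invert an integer naming-subtest score into item-level responses
decompose_cnocd <- function(score) {
  score <- as.integer(score)
  a <- pmin(score, 6L)                      # naming flags
  b <- pmin(score - a, 6L)                  # color flags
  rem <- score - a - b                      # watch points, must be 0/1/2/4
  fix <- rem == 3L
  b[fix] <- b[fix] - 1L
  rem[fix] <- 4L
  grade <- c("none", "min_only", "hour_min", NA, "full")[rem + 1L]
  list(naming = a, color = b, watch_grade = grade)
}

#' Simulate an item-level synthetic cohort with a two-factor structure
#'
#' Per subject, two correlated latent factors are drawn; each standardized
#' item is `loading . factor + uniqueness noise`, rescaled to the group's
#' item mean and SD, and then discretized into a valid raw item-response
#' record (naming/color flags and watch grade for the naming subtest,
#' placement and recall counts, informant booleans by mid-scale threshold).
#' Re-scoring the records through [score_haisac()] reproduces the
#' continuous targets up to discretization error; the continuous targets
#' themselves are kept in `attr(, "latent_scores")` (columns
#' `cnocd`, `rfo`, `ml`, `cd`, `fd` on the group mean/SD scale).
#'
#' @param config A [cohort_config()]; only the group sizes and the five
#'   item rows of the calibration are used.
#' @param spec A [factor_spec()].
#' @param seed Integer seed; `NULL` draws one from the clock.
#' @return Tibble in the [score_haisac()] item schema, plus `group`, with
#'   the generating seed and continuous targets as attributes.
#' @export
simulate_item_cohort <- function(config = cohort_config(),
                                 spec = factor_spec(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "factor_spec"))
  if (is.null(seed)) seed <- draw_entropy_seed()
  items <- rownames(spec$loadings)
  phi <- matrix(c(1, spec$factor_correlation, spec$factor_correlation, 1), 2)
  chol_phi <- chol(phi)
  item_sd_latent <- sqrt(rowSums((spec$loadings %*% phi) * spec$loadings) +
                           spec$uniquenesses)
  out <- with_rng_seed(seed, {
    purrr::pmap(config$sizes[c("group", "n")], function(group, n) {
      pars <- dplyr::filter(config$params, .data$group == !!group,
                            .data$variable %in% items)
      pars <- pars[match(items, pars$variable), ]
      if (anyNA(pars$mean)) {
        abort(paste0("Calibration for group ", group,
                     " is missing item rows."))
      }
      f <- matrix(rnorm(n * 2), ncol = 2) %*% chol_phi
      e <- matrix(rnorm(n * length(items)), ncol = length(items))
      z <- f %*% t(spec$loadings) +
        e * matrix(sqrt(spec$uniquenesses), n, length(items), byrow = TRUE)
      z <- sweep(z, 2, item_sd_latent, "/")   # unit-variance standardized
      x <- sweep(sweep(z, 2, pars$sd, "*"), 2, pars$mean, "+")
      colnames(x) <- items
      latent <- tibble::as_tibble(x)
      cn <- decompose_cnocd(pmax(0, pmin(16, round(x[, "cnocd"]))))
      ml_count <- pmax(0L, pmin(6L, as.integer(round(x[, "ml"] / 2))))
      rec <- tibble::tibble(
        group = group,
        !!!setNames(purrr::map(1:6, function(j) cn$naming >= j),
                    paste0("name_", 1:6)),
        !!!setNames(purrr::map(1:6, function(j) cn$color >= j),
                    paste0("color_", 1:6)),
        watch_grade = cn$watch_grade,
        ml_correct = ml_count,
        rfo_correct = pmax(0L, pmin(12L, as.integer(round(x[, "rfo"])))),
        cd_no_decline = x[, "cd"] > 4,
        fd_no_interference = x[, "fd"] > 6)
      list(rec = rec, latent = latent)
    })
  })
  cohort <- dplyr::bind_rows(purrr::map(out, "rec"))
  cohort <- dplyr::mutate(
    cohort,
    subject_id = sprintf("S%04d", dplyr::row_number()),
    group = factor(.data$group, levels = unique(config$sizes$group)),
    .before = 1)
  attr(cohort, "latent_scores") <- dplyr::bind_rows(purrr::map(out, "latent"))
  attr(cohort, "seed") <- seed
  cohort
}

#' Compare a simulated cohort's moments with its calibration targets
#'
#' For every group and variable, reports the target and sample mean and SD
#' and flags any sample mean further than four standard errors from its
#' target. Intended for untruncated cohorts, where the targets are exact.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param config The [cohort_config()] it was generated from.
#' @return Tibble with columns `group`, `variable`, `target_mean`,
#'   `sample_mean`, `target_sd`, `sample_sd`, `flag`.
#' @export
moment_check <- function(cohort, config = cohort_config()) {
  if (nrow(cohort) == 0) abort("Cohort is empty.")
  unknown <- setdiff(unique(config$params$variable), names(cohort))
  if (length(unknown)) {
    abort(paste0("Cohort lacks configured variable(s): ",
                 paste(unknown, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "group",
                  dplyr::all_of(unique(config$params$variable))),
    -"group", names_to = "variable", values_to = "value")
  obs <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$variable),
    sample_mean = mean(.data$value), sample_sd = sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  obs$group <- as.character(obs$group)
  res <- dplyr::inner_join(
    dplyr::rename(config$params, target_mean = "mean", target_sd = "sd"),
    obs, by = c("group", "variable"))
  dplyr::mutate(
    dplyr::select(res, "group", "variable", "target_mean", "sample_mean",
                  "target_sd", "sample_sd", "n"),
    flag = abs(.data$sample_mean - .data$target_mean) >
      4 * .data$target_sd / sqrt(.data$n))
}
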