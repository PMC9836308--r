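# Orchestration: simulate cohorts to files, score item CSVs, and run the
# full validation pipeline into a structured, deterministic report.

test_score_columns <- c(haisac = "haisac_total", haisac3 = "haisac3",
                        haisaci = "haisaci", casi = "casi", mmse = "mmse",
                        moca = "moca")

# severity order of the diagnostic groups; the later group is the case
group_severity <- c("CU", "MCI", "DAT")

# tiny polynomial rolling hash for deterministic config digests
poly_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

config_digest <- function(config) {
  poly_hash(jsonlite::toJSON(list(
    sizes = config$sizes, params = config$params, mode = config$mode,
    w = config$within_group_correlation), digits = 10))
}

#' Read a cohort configuration from YAML
#'
#' The YAML mirrors the per-group calibration: a `groups` map with, per
#' group, `n`, `male_proportion`, and `means`/`sds` maps keyed by
#' variable, plus optional top-level `mode` and
#' `within_group_correlation`. A packaged default with the published
#' calibration ships at
#' `system.file("extdata", "default_cohort_params.yaml", package =
#' "haisac")`.
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("Cannot parse YAML config: ", conditionMessage(e)))
  })
  if (is.null(raw$groups)) abort("Config is missing the `groups` field.")
  sizes <- purrr::imap_dfr(raw$groups, function(g, label) {
    for (field in c("n", "male_proportion", "means", "sds")) {
      if (is.null(g[[field]])) {
        abort(paste0("Group ", label, " is missing field `", field, "`."))
      }
    }
    tibble::tibble(group = label, n = as.integer(g$n),
                   male_proportion = g$male_proportion)
  })
  params <- purrr::imap_dfr(raw$groups, function(g, label) {
    vars <- names(g$means)
    if (!setequal(vars, names(g$sds))) {
      abort(paste0("Group ", label, ": `means` and `sds` list different ",
                   "variables."))
    }
    tibble::tibble(group = label, variable = vars,
                   mean = as.numeric(unlist(g$means[vars])),
                   sd = as.numeric(unlist(g$sds[vars])))
  })
  cohort_config(sizes = sizes, params = params,
                mode = raw$mode %||% "untruncated",
                within_group_correlation =
                  raw$within_group_correlation %||% 0)
}

#' Write a cohort configuration to YAML
#'
#' @param config A [cohort_config()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  groups <- setNames(
    purrr::pmap(config$sizes, function(group, n, male_proportion) {
      pars <- dplyr::filter(config$params, .data$group == !!group)
      list(n = n, male_proportion = male_proportion,
           means = setNames(as.list(pars$mean), pars$variable),
           sds = setNames(as.list(pars$sd), pars$variable))
    }),
    config$sizes$group)
  yaml::write_yaml(list(mode = config$mode,
                        within_group_correlation =
                          config$within_group_correlation,
                        groups = groups), path)
  invisible(path)
}

#' Simulate a cohort and write it to CSV with metadata
#'
#' File-level wrapper around [simulate_cohort()]: reads an optional YAML
#' configuration, simulates, writes the cohort CSV and a metadata JSON
#' (seed, mode, config digest) next to it. Re-running with identical
#' arguments reproduces the files byte for byte.
#'
#' @param out_path Destination CSV.
#' @param config_path Optional YAML config; `NULL` uses the packaged
#'   defaults.
#' @param seed Integer seed (required here, unlike the library call, so
#'   that the file is reproducible by construction).
#' @param mode Overrides the config's simulation mode if given.
#' @return The cohort tibble, invisibly.
#' @export
simulate_cohort_file <- function(out_path, config_path = NULL, seed,
                                 mode = NULL) {
  config <- if (is.null(config_path)) {
    cohort_config()
  } else {
    read_cohort_config(config_path)
  }
  if (!is.null(mode)) {
    config <- cohort_config(config$sizes, config$params, mode = mode,
                            within_group_correlation =
                              config$within_group_correlation)
  }
  cohort <- simulate_cohort(config, seed = seed)
  readr::write_csv(cohort, out_path)
  meta <- list(seed = seed, mode = config$mode,
               n_subjects = nrow(cohort),
               config_digest = config_digest(config))
  jsonlite::write_json(meta, paste0(out_path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cohort)
}

#' Score an item-response CSV
#'
#' Reads a CSV in the raw item schema (see [score_haisac()]), validates
#' it, appends the component and total scores, and writes the result.
#'
#' @param items_path Input CSV of raw item responses.
#' @param out_path Destination CSV.
#' @return The scored tibble, invisibly.
#' @export
score_items_file <- function(items_path, out_path) {
  items <- readr::read_csv(items_path, show_col_types = FALSE)
  scored <- score_haisac(items)
  readr::write_csv(scored, out_path)
  invisible(scored)
}

skip_block <- function(reason) list(skipped = TRUE, reason = reason)

#' Run the full validation pipeline on a cohort table
#'
#' Executes every stage of the screening-test validation on a cohort in
#' the standard schema (`group` plus scale scores; item component columns
#' `cnocd`, `ml`, `rfo`, `cd`, `fd` when available):
#' * reliability and EFA of the five-item battery, with weighted-sum
#'   factor scores;
#' * Pearson correlations of the total score and factor scores against
#'   the comparison tests, with strength bands;
#' * one-way ANOVAs across diagnostic groups (Bonferroni-corrected
#'   pairwise contrasts) and a chi-square test of the sex ratio;
#' * the full discrimination grid: per contrast and test, the empirical
#'   ROC with AUC, confidence interval, Youden-optimal cutoff,
#'   sensitivity and specificity, plus DeLong paired AUC comparisons
#'   between all test pairs within each contrast.
#'
#' Stages whose required columns are absent are marked skipped with a
#' reason instead of failing.
#'
#' @param cohort Cohort data frame (e.g. from [simulate_cohort()] or a
#'   scored item CSV joined to scale scores).
#' @param contrasts Character vector of `"control:case"` group pairs; the
#'   second (more impaired) group is treated as cases.
#' @param tests Tests to enter the discrimination grid, a subset of
#'   `c("haisac", "haisac3", "haisaci", "casi", "mmse", "moca")`.
#' @param anova_vars Variables to compare across groups; defaults to
#'   every configured cohort variable present.
#' @return Object of class `haisac_validation` with blocks `metadata`,
#'   `reliability`, `efa`, `factor_scores`, `correlations`,
#'   `group_comparisons`, and `discrimination`.
#' @export
validate_cohort <- function(cohort,
                            contrasts = c("CU:MCI", "MCI:DAT", "CU:DAT"),
                            tests = names(test_score_columns),
                            anova_vars = NULL) {
  cohort <- tibble::as_tibble(cohort)
  if (!"group" %in% names(cohort)) {
    abort("Cohort must contain a `group` column.")
  }
  tests <- match.arg(tests, names(test_score_columns), several.ok = TRUE)
  item_cols <- c("cnocd", "ml", "rfo", "cd", "fd")

  # --- reliability + EFA on the five-item battery -----------------------
  have_items <- all(item_cols %in% names(cohort))
  if (have_items) {
    items <- cohort[item_cols]
    rel <- reliability(items)
    efa_res <- tryCatch(efa(items, adequacy = "warn"),
                        error = function(e) skip_block(conditionMessage(e)))
    fscores <- if (inherits(efa_res, "haisac_efa")) {
      fs <- factor_scores(items, efa_res$pattern)
      # name factors by content: objective subtests vs informant items
      names(fs) <- vapply(seq_len(ncol(fs)), function(j) {
        top <- rownames(efa_res$pattern)[
          which.max(abs(efa_res$pattern[, j]))]
        if (top %in% c("cd", "fd")) "INF" else "SMCB"
      }, character(1))
      fs
    } else {
      NULL
    }
  } else {
    rel <- skip_block("item component columns (cnocd..fd) not present")
    efa_res <- skip_block("item component columns (cnocd..fd) not present")
    fscores <- NULL
  }

  # --- correlation block (mirrors the published correlation table) ------
  comparison_vars <- intersect(c("mmse", "casi", "moca", "cdr_sb",
                                 "npi_sb", "iadl"), names(cohort))
  cor_data <- cohort[intersect(c("haisac_total", comparison_vars),
                               names(cohort))]
  if (!is.null(fscores) && !anyNA(names(fscores)) &&
      length(unique(names(fscores))) == ncol(fscores)) {
    cor_data <- dplyr::bind_cols(cor_data, fscores)
  }
  correlations <- if (ncol(cor_data) >= 2) {
    lead_vars <- intersect(c("haisac_total", "SMCB", "INF"),
                           names(cor_data))
    pairs <- tidyr::expand_grid(var_1 = lead_vars, var_2 = comparison_vars)
    if (nrow(pairs)) {
      pearson_correlations(cor_data, variables = names(cor_data),
                           pairs = pairs)
    } else {
      pearson_correlations(cor_data)
    }
  } else {
    skip_block("fewer than two score columns available")
  }

  # --- group comparisons ------------------------------------------------
  if (is.null(anova_vars)) {
    anova_vars <- intersect(cohort_variables, names(cohort))
  }
  anovas <- purrr::map(setNames(anova_vars, anova_vars), function(v) {
    tryCatch(anova_oneway(cohort[[v]], cohort$group),
             error = function(e) skip_block(conditionMessage(e)))
  })
  sex_test <- if ("sex" %in% names(cohort)) {
    chi_square_independence(table(cohort$group, cohort$sex))
  } else {
    skip_block("no `sex` column")
  }

  # --- discrimination grid ----------------------------------------------
  score_cols <- test_score_columns[tests]
  discrimination <- purrr::map(setNames(contrasts, contrasts),
                               function(contrast) {
    parts <- strsplit(contrast, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      return(skip_block(paste0("malformed contrast `", contrast, "`")))
    }
    ctrl <- parts[1]
    case <- parts[2]
    in_ctrl <- cohort$group == ctrl
    in_case <- cohort$group == case
    if (!any(in_ctrl) || !any(in_case)) {
      return(skip_block(paste0("group(s) absent for ", contrast)))
    }
    rocs <- purrr::map(score_cols, function(col) {
      if (!col %in% names(cohort)) {
        return(skip_block(paste0("column `", col, "` not present")))
      }
      empirical_roc(cohort[[col]][in_case], cohort[[col]][in_ctrl])
    })
    sub <- cohort[in_ctrl | in_case, ]
    is_case <- sub$group == case
    pair_idx <- if (length(tests) >= 2) utils::combn(tests, 2) else NULL
    delong <- if (is.null(pair_idx)) {
      list()
    } else {
      purrr::map(seq_len(ncol(pair_idx)), function(k) {
        a <- pair_idx[1, k]
        b <- pair_idx[2, k]
        ca <- test_score_columns[[a]]
        cb <- test_score_columns[[b]]
        if (!all(c(ca, cb) %in% names(sub))) {
          return(skip_block("score column missing"))
        }
        res <- delong_paired_test(sub[[ca]], sub[[cb]], is_case)
        res$test_a <- a
        res$test_b <- b
        res
      })
    }
    list(rocs = rocs, delong = delong)
  })

  structure(list(
    metadata = list(seed = attr(cohort, "seed"),
                    n_subjects = nrow(cohort),
                    groups = as.list(table(cohort$group)),
                    contrasts = contrasts, tests = tests),
    reliability = rel, efa = efa_res, factor_scores = fscores,
    correlations = correlations,
    group_comparisons = list(anova = anovas, sex_chi_square = sex_test),
    discrimination = discrimination), class = "haisac_validation")
}

is_skipped <- function(x) is.list(x) && isTRUE(x$skipped)

#' Discrimination grid of a validation report as a tibble
#'
#' One row per contrast and test: AUC, confidence interval, optimal
#' cutoff, sensitivity and specificity -- the shape of a published
#' AUC/cutoff table.
#'
#' @param report A `haisac_validation` object.
#' @return Tibble with one row per (contrast, test).
#' @export
discrimination_table <- function(report) {
  stopifnot(inherits(report, "haisac_validation"))
  purrr::imap_dfr(report$discrimination, function(block, contrast) {
    if (is_skipped(block)) return(NULL)
    purrr::imap_dfr(block$rocs, function(r, test) {
      if (is_skipped(r)) return(NULL)
      dplyr::mutate(glance(r), contrast = contrast, test = test,
                    .before = 1)
    })
  })
}

#' @export
print.haisac_validation <- function(x, ...) {
  cat("=== Screening-test validation report ===\n")
  cat(sprintf("Subjects: %d (%s)\n", x$metadata$n_subjects,
              paste(names(x$metadata$groups), unlist(x$metadata$groups),
                    sep = " = ", collapse = ", ")))
  cat("\n-- Reliability --\n")
  if (is_skipped(x$reliability)) {
    cat("skipped:", x$reliability$reason, "\n")
  } else {
    print(x$reliability)
  }
  cat("\n-- Factor analysis --\n")
  if (is_skipped(x$efa)) {
    cat("skipped:", x$efa$reason, "\n")
  } else {
    print(x$efa)
  }
  cat("\n-- Correlations --\n")
  if (is_skipped(x$correlations)) {
    cat("skipped:", x$correlations$reason, "\n")
  } else {
    print(as.data.frame(tidy(x$correlations)), digits = 2)
  }
  cat("\n-- Group comparisons --\n")
  for (v in names(x$group_comparisons$anova)) {
    a <- x$group_comparisons$anova[[v]]
    if (is_skipped(a)) next
    cat(sprintf("%-15s F(%d, %d) = %8.2f, p = %.3g\n", v, a$df_between,
                a$df_within, a$f_statistic, a$p_value))
  }
  sx <- x$group_comparisons$sex_chi_square
  if (!is_skipped(sx)) {
    cat(sprintf("%-15s chi2(%d) = %.2f, p = %.3g\n", "sex ratio", sx$df,
                sx$chi2, sx$p_value))
  }
  cat("\n-- Discrimination --\n")
  print(as.data.frame(discrimination_table(x)[
    c("contrast", "test", "auc", "ci_lower", "ci_upper", "cutoff_label",
      "sensitivity", "specificity")]), digits = 3)
  invisible(x)
}

validation_to_list <- function(report) {
  block <- function(x, f) if (is_skipped(x)) x else f(x)
  list(
    metadata = report$metadata,
    reliability = block(report$reliability,
                        function(r) as.list(glance(r))),
    efa = block(report$efa, function(e) list(
      n_factors = e$n_factors, eigenvalues = e$eigenvalues,
      pattern = as.data.frame(e$pattern),
      factor_correlation = unname(e$phi),
      variance_explained = as.list(e$variance_explained),
      communalities = as.list(e$communalities), heywood = e$heywood)),
    correlations = block(report$correlations, tidy),
    group_comparisons = list(
      anova = purrr::map(report$group_comparisons$anova, function(a) {
        block(a, function(a) c(as.list(glance(a)),
                               list(pairwise = tidy(a))))
      }),
      sex_chi_square = block(report$group_comparisons$sex_chi_square,
                             function(s) s[c("chi2", "df", "p_value")])),
    discrimination = purrr::map(report$discrimination, function(b) {
      block(b, function(b) list(
        rocs = purrr::map(b$rocs, function(r) {
          block(r, function(r) as.list(glance(r)))
        }),
        auc_comparisons = purrr::map(b$delong, function(d) {
          block(d, function(d) list(
            test_a = d$test_a, test_b = d$test_b, auc_a = d$auc_a,
            auc_b = d$auc_b, chi2 = d$chi2, df = d$df,
            p_value = d$p_value))
        })))
    }))
}

#' Run the validation pipeline on a cohort CSV and write a JSON report
#'
#' Deterministic: identical inputs produce byte-identical JSON (the
#' report carries no timestamps).
#'
#' @param cohort_path Cohort CSV in the standard schema.
#' @param out_path Destination JSON.
#' @param contrasts,tests Passed to [validate_cohort()].
#' @return The `haisac_validation` object, invisibly.
#' @export
validate_cohort_file <- function(cohort_path, out_path,
                                 contrasts = c("CU:MCI", "MCI:DAT",
                                               "CU:DAT"),
                                 tests = names(test_score_columns)) {
  cohort <- readr::read_csv(cohort_path, show_col_types = FALSE)
  report <- validate_cohort(cohort, contrasts = contrasts, tests = tests)
  jsonlite::write_json(validation_to_list(report), out_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       dataframe = "rows")
  invisible(report)
}
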