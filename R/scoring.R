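#' Points awarded for each watch-time reading grade
#'
#' The watch-detail question of the naming subtest is graded on four levels:
#' a fully correct time earns 4 points, correct hour and minute (wrong second)
#' 2 points, correct minute only 1 point, and anything else 0.
#'
#' @format Named numeric vector with names `full`, `hour_min`, `min_only`,
#'   `none`.
#' @export
watch_grade_points <- c(full = 4, hour_min = 2, min_only = 1, none = 0)

# internal: check an integer-valued vector lies in [lo, hi]
check_range <- function(x, lo, hi, what, integer = TRUE) {
  if (!is.numeric(x) && !is.logical(x)) {
    abort(paste0("`", what, "` must be numeric."))
  }
  bad <- which(!is.finite(x) | x < lo | x > hi |
                 (integer & (x != round(x))))
  if (length(bad)) {
    abort(paste0(
      "`", what, "` must contain ",
      if (integer) "integers " else "values ",
      "in [", lo, ", ", hi, "]; offending positions: ",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    ))
  }
  invisible(x)
}

# internal: coerce a 6-column logical block (vector, matrix or data frame)
# to a per-record count of TRUEs
bool_block_count <- function(x, width, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != width) {
      abort(paste0("`", what, "` must have ", width, " columns, not ",
                   ncol(x), "."))
    }
  } else {
    if (length(x) != width) {
      abort(paste0("`", what, "` must have length ", width, ", not ",
                   length(x), "."))
    }
    x <- matrix(x, nrow = 1)
  }
  storage.mode(x) <- "logical"
  if (anyNA(x)) abort(paste0("`", what, "` contains missing values."))
  rowSums(x)
}

#' Score the naming subtest (objects, colors, and the watch detail)
#'
#' One point per correctly named object and per correctly named color
#' (six objects each), plus a graded 0/1/2/4-point watch-time question,
#' for a 0--16 total.
#'
#' @param naming_correct Six logicals (one record) or an n x 6 logical
#'   matrix/data frame: object named correctly.
#' @param color_correct Same shape: color named correctly.
#' @param watch_grade Character vector in
#'   `c("full", "hour_min", "min_only", "none")`.
#' @return Numeric vector of subtest scores in 0--16.
#' @examples
#' score_cnocd(rep(TRUE, 6), rep(TRUE, 6), "full") # 16
#' @export
score_cnocd <- function(naming_correct, color_correct, watch_grade) {
  n_pts <- bool_block_count(naming_correct, 6, "naming_correct")
  c_pts <- bool_block_count(color_correct, 6, "color_correct")
  watch_grade <- as.character(watch_grade)
  bad <- setdiff(unique(watch_grade), names(watch_grade_points))
  if (length(bad)) {
    abort(paste0("Unknown `watch_grade` value(s): ",
                 paste(bad, collapse = ", "),
                 ". Use full/hour_min/min_only/none."))
  }
  w_pts <- unname(watch_grade_points[watch_grade])
  if (length(n_pts) != length(c_pts) || length(n_pts) != length(w_pts)) {
    abort("naming, color and watch inputs describe different record counts.")
  }
  n_pts + c_pts + w_pts
}

#' Score the memory-for-location subtest
#'
#' Two points per correctly placed photo, with a two-point bonus for a
#' perfect six-of-six arrangement; the base score is capped at 10 so the
#' subtest maximum is 12.
#'
#' @param ml_correct_count Integer vector, number of correctly placed
#'   photos, 0--6.
#' @return Numeric vector of scores in 0--12.
#' @examples
#' score_ml(0:6) # 0 2 4 6 8 10 12
#' @export
score_ml <- function(ml_correct_count) {
  check_range(ml_correct_count, 0, 6, "ml_correct_count")
  pmin(2 * ml_correct_count, 10) + 2 * (ml_correct_count == 6)
}

#' Score the recall-of-object-functions subtest
#'
#' One point per correctly recalled function, two functions per object,
#' six objects.
#'
#' @param rfo_correct_count Integer vector, 0--12.
#' @return Numeric vector of scores in 0--12.
#' @export
score_rfo <- function(rfo_correct_count) {
  check_range(rfo_correct_count, 0, 12, "rfo_correct_count")
  as.numeric(rfo_correct_count)
}

#' Score the two informant-based questions
#'
#' The informant is asked whether the participant shows cognitive decline
#' (CD) and whether that decline interferes with daily activities (FD).
#' A *negative* report scores points: no decline earns 8, no interference
#' earns 12, so an unimpaired participant scores the informant maximum of 20.
#'
#' @param cd_no_decline Logical vector: informant reports no cognitive
#'   decline.
#' @param fd_no_interference Logical vector: informant reports no
#'   interference with daily activities.
#' @return A tibble with columns `cd` (0 or 8), `fd` (0 or 12) and
#'   `haisaci` (their sum).
#' @examples
#' score_informant(TRUE, TRUE) # 8, 12, 20
#' @export
score_informant <- function(cd_no_decline, fd_no_interference) {
  if (anyNA(cd_no_decline) || anyNA(fd_no_interference)) {
    abort("Informant responses must not be missing.")
  }
  cd <- 8 * as.numeric(as.logical(cd_no_decline))
  fd <- 12 * as.numeric(as.logical(fd_no_interference))
  tibble::tibble(cd = cd, fd = fd, haisaci = cd + fd)
}

#' Item-level column schema expected by [score_haisac()]
#' @keywords internal
item_schema_cols <- function() {
  c(paste0("name_", 1:6), paste0("color_", 1:6), "watch_grade",
    "ml_correct", "rfo_correct", "cd_no_decline", "fd_no_interference")
}

#' Score a table of raw HAI-SAC item responses
#'
#' Takes one row per subject with the raw item responses and appends the
#' component and total scores. Expected columns: `name_1..name_6` and
#' `color_1..color_6` (logical), `watch_grade`
#' (`full`/`hour_min`/`min_only`/`none`), `ml_correct` (0--6),
#' `rfo_correct` (0--12), `cd_no_decline` and `fd_no_interference`
#' (logical). Any other columns (e.g. `subject_id`) are carried through.
#'
#' @param data Data frame of item responses, one row per subject.
#' @return The input as a tibble with appended columns `cnocd`, `ml`,
#'   `rfo`, `haisac3`, `cd`, `fd`, `haisaci`, `haisac_total`.
#' @examples
#' rec <- perfect_item_record()
#' score_haisac(rec)$haisac_total # 60
#' @export
score_haisac <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(item_schema_cols(), names(data))
  if (length(missing_cols)) {
    abort(paste0("Item table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, cnocd = numeric(0), ml = numeric(0),
                         rfo = numeric(0), haisac3 = numeric(0),
                         cd = numeric(0), fd = numeric(0),
                         haisaci = numeric(0), haisac_total = numeric(0)))
  }
  cnocd <- score_cnocd(data[paste0("name_", 1:6)],
                       data[paste0("color_", 1:6)],
                       data$watch_grade)
  ml <- score_ml(data$ml_correct)
  rfo <- score_rfo(data$rfo_correct)
  inf <- score_informant(data$cd_no_decline, data$fd_no_interference)
  dplyr::mutate(data,
    cnocd = cnocd, ml = ml, rfo = rfo,
    haisac3 = cnocd + ml + rfo,
    cd = inf$cd, fd = inf$fd, haisaci = inf$haisaci,
    haisac_total = .data$haisac3 + .data$haisaci)
}

#' A perfect-score item-response record
#'
#' Convenience constructor for a one-row item table with every response
#' correct; useful in examples and tests.
#'
#' @param subject_id Identifier for the record.
#' @return One-row tibble in the [score_haisac()] schema.
#' @export
perfect_item_record <- function(subject_id = "s1") {
  rec <- c(list(subject_id = subject_id),
           setNames(rep(list(TRUE), 6), paste0("name_", 1:6)),
           setNames(rep(list(TRUE), 6), paste0("color_", 1:6)),
           list(watch_grade = "full", ml_correct = 6L, rfo_correct = 12L,
                cd_no_decline = TRUE, fd_no_interference = TRUE))
  tibble::as_tibble(rec)
}

#' CASI short-term-memory composite
#'
#' `1/2 * (short delayed recall + long delayed recall) + 0.6 * recognition`,
#' giving a 0--12 composite. Fractional values are kept exact; no rounding.
#'
#' @param short_delayed 0--9, short-delay word recall.
#' @param long_delayed 0--9, long-delay word recall.
#' @param recognition 0--5, object recognition.
#' @return Numeric composite in 0--12.
#' @examples
#' casi_short_term_memory(6, 4, 3) # 6.8
#' @export
casi_short_term_memory <- function(short_delayed, long_delayed, recognition) {
  check_range(short_delayed, 0, 9, "short_delayed", integer = FALSE)
  check_range(long_delayed, 0, 9, "long_delayed", integer = FALSE)
  check_range(recognition, 0, 5, "recognition", integer = FALSE)
  0.5 * (short_delayed + long_delayed) + 0.6 * recognition
}

#' CASI language composite
#'
#' `1/2 * (reading + writing) + 0.3 * naming + commands`, giving a 0--10
#' composite.
#'
#' @param reading 0--3, reading-comprehension task.
#' @param writing 0--5, character-writing task.
#' @param naming 0--10, confrontational naming.
#' @param commands 0--3, following commands.
#' @return Numeric composite in 0--10.
#' @examples
#' casi_language(2, 4, 5, 1) # 5.5
#' @export
casi_language <- function(reading, writing, naming, commands) {
  check_range(reading, 0, 3, "reading", integer = FALSE)
  check_range(writing, 0, 5, "writing", integer = FALSE)
  check_range(naming, 0, 10, "naming", integer = FALSE)
  check_range(commands, 0, 3, "commands", integer = FALSE)
  0.5 * (reading + writing) + 0.3 * naming + commands
}

#' Neuropsychiatric Inventory sum of boxes
#'
#' Per-item frequency (0--4) times severity (0--3), summed over the twelve
#' symptom domains, for a 0--144 burden score. Caregiver-distress ratings
#' may be supplied but do not enter the summary score.
#'
#' @param frequency 12 integers 0--4 (one record) or an n x 12 matrix.
#' @param severity 12 integers 0--3, same shape.
#' @param distress Optional distress ratings (0--5); accepted for schema
#'   completeness and ignored.
#' @return Numeric vector of NPI-SB scores in 0--144.
#' @examples
#' npi_sum_of_boxes(rep(4, 12), rep(3, 12)) # 144
#' @export
npi_sum_of_boxes <- function(frequency, severity, distress = NULL) {
  as_block <- function(x, what, hi) {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x)) {
      if (length(x) != 12) {
        abort(paste0("`", what, "` must have 12 items, not ",
                     length(x), "."))
      }
      x <- matrix(x, nrow = 1)
    }
    if (ncol(x) != 12) {
      abort(paste0("`", what, "` must have 12 columns, not ", ncol(x), "."))
    }
    check_range(as.vector(x), 0, hi, what)
    x
  }
  f <- as_block(frequency, "frequency", 4)
  s <- as_block(severity, "severity", 3)
  if (nrow(f) != nrow(s)) abort("frequency and severity row counts differ.")
  rowSums(f * s)
}

#' Instrumental-activities-of-daily-living summary score
#'
#' One point per activity (of eight) in which the participant is
#' independent: shopping, transportation, finances, telephone use,
#' medication, food preparation, household chores, laundry.
#'
#' @param independent_flags Eight logicals (one record) or an n x 8
#'   logical matrix/data frame.
#' @return Numeric vector of scores in 0--8.
#' @export
iadl_sum <- function(independent_flags) {
  bool_block_count(independent_flags, 8, "independent_flags")
}
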