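#' Synthetic cohort configuration
#'
#' Describes the simulated study design: several colleges, a fixed number of
#' students per college, grade-conditional indicator-score distributions.
#' Defaults emulate the original design — 6 colleges of 200 students each,
#' 10 indicators, four anxiety grades with mean score profiles 8.5 / 6.5 /
#' 4.5 / 2.0 and isotropic Gaussian noise (sd 0.8) clipped to `[0, 10]`.
#'
#' @param n_colleges Number of colleges.
#' @param n_per_college Students sampled per college.
#' @param indicators Indicator definitions, see [default_indicators()].
#' @param grade_proportions Length-4 vector of grade prevalences summing to 1
#'   (normal, mild, moderate, severe). The default skews toward `normal` to
#'   mimic a plausible student population.
#' @param grade_profiles 4 x d matrix of per-grade mean scores in `[0, 10]`;
#'   the default repeats one mean per grade across all indicators.
#' @param noise_sd Standard deviation of the per-indicator Gaussian noise.
#' @param seed Integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_colleges = 6L,
                          n_per_college = 200L,
                          indicators = default_indicators(),
                          grade_proportions = c(0.55, 0.25, 0.15, 0.05),
                          grade_profiles = NULL,
                          noise_sd = 0.8,
                          seed = 0L) {
  n_colleges <- check_count(n_colleges, "n_colleges", min = 1L)
  n_per_college <- check_count(n_per_college, "n_per_college", min = 1L)
  indicators <- check_indicators(indicators)
  d <- nrow(indicators)
  if (length(grade_proportions) != 4L || any(grade_proportions < 0) ||
      abs(sum(grade_proportions) - 1) > 1e-9) {
    stop_invalid("`grade_proportions` must be 4 non-negative values summing to 1")
  }
  if (is.null(grade_profiles)) {
    grade_profiles <- matrix(rep(c(8.5, 6.5, 4.5, 2.0), each = d),
                             nrow = 4L, byrow = TRUE)
  }
  grade_profiles <- as.matrix(grade_profiles)
  if (!identical(dim(grade_profiles), c(4L, d)) ||
      any(grade_profiles < 0 | grade_profiles > 10)) {
    stop_invalid("`grade_profiles` must be a 4 x %d matrix with values in [0, 10]", d)
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(
      n_colleges = n_colleges, n_per_college = n_per_college,
      indicators = indicators, grade_proportions = grade_proportions,
      grade_profiles = unname(grade_profiles), noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Generate a labeled synthetic cohort
#'
#' For every college, grade labels are drawn from `grade_proportions`; each
#' student's score vector is their grade's mean profile plus independent
#' Normal(0, `noise_sd`) noise per indicator, clipped to `[0, 10]`.
#' Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `labeled_cohort` with elements `student_id`,
#'   `college` (character vectors), `scores` (n x d matrix with indicator
#'   column names), `true_grades` (factor over [mh_grades()], possibly
#'   zero-length when labels are unknown), `indicators`, `labeled` (flag).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  d <- nrow(config$indicators)
  n <- config$n_colleges * config$n_per_college
  with_seed(config$seed, {
    college <- rep(sprintf("college_%02d", seq_len(config$n_colleges)),
                   each = config$n_per_college)
    grade_idx <- unlist(lapply(seq_len(config$n_colleges), function(cl) {
      sample.int(4L, config$n_per_college, replace = TRUE,
                 prob = config$grade_proportions)
    }))
    noise <- matrix(stats::rnorm(n * d, sd = config$noise_sd), n, d)
    scores <- config$grade_profiles[grade_idx, , drop = FALSE] + noise
    scores <- pmin(pmax(scores, 0), 10)
    colnames(scores) <- config$indicators$name
    new_labeled_cohort(
      student_id = sprintf("s%05d", seq_len(n)),
      college = college,
      scores = scores,
      true_grades = factor(mh_grades()[grade_idx], levels = mh_grades()),
      indicators = config$indicators
    )
  })
}

new_labeled_cohort <- function(student_id, college, scores, true_grades,
                               indicators) {
  labeled <- length(true_grades) > 0L
  if (labeled && length(true_grades) != nrow(scores)) {
    stop_invalid("grade labels and score rows differ in length")
  }
  if (any(scores < 0 | scores > 10)) {
    stop_invalid("cohort scores must lie in [0, 10]")
  }
  structure(
    list(student_id = student_id, college = college, scores = scores,
         true_grades = true_grades, indicators = indicators,
         labeled = labeled),
    class = "labeled_cohort"
  )
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("<labeled_cohort>\n")
  cat(sprintf("  students   : %d across %d colleges\n",
              nrow(x$scores), length(unique(x$college))))
  cat(sprintf("  indicators : %d (%s, ...)\n", ncol(x$scores),
              paste(utils::head(colnames(x$scores), 3), collapse = ", ")))
  if (x$labeled) {
    tb <- table(x$true_grades)
    cat("  grades     :", paste(sprintf("%s=%d", names(tb), tb),
                                collapse = " "), "\n")
  } else {
    cat("  grades     : unlabeled\n")
  }
  invisible(x)
}

#' Write / read a cohort CSV
#'
#' Columns: `student_id`, `college`, one column per indicator (scores written
#' with 6 decimals), and `true_grade` when labels exist. On read the
#' `true_grade` column is optional; its absence yields an unlabeled cohort.
#'
#' @param cohort A `labeled_cohort`.
#' @param path File path.
#' @param indicators Indicator definitions expected in the file; defaults to
#'   [default_indicators()]. Every indicator name must appear as a column.
#' @return `read_cohort_csv()` returns a `labeled_cohort`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  df <- data.frame(student_id = cohort$student_id, college = cohort$college,
                   stringsAsFactors = FALSE)
  score_chr <- matrix(sprintf("%.6f", cohort$scores),
                      nrow = nrow(cohort$scores),
                      dimnames = list(NULL, colnames(cohort$scores)))
  df <- cbind(df, as.data.frame(score_chr, stringsAsFactors = FALSE))
  if (cohort$labeled) df$true_grade <- as.character(cohort$true_grades)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, indicators = default_indicators()) {
  indicators <- check_indicators(indicators)
  if (!file.exists(path)) stop_invalid("cannot open cohort CSV '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("student_id", "college")) {
    if (!col %in% names(df)) stop_invalid("missing required column '%s'", col)
  }
  missing_ind <- setdiff(indicators$name, names(df))
  if (length(missing_ind)) {
    stop_invalid("missing indicator column(s): %s",
                 paste(missing_ind, collapse = ", "))
  }
  scores <- as.matrix(df[, indicators$name, drop = FALSE])
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop_invalid("non-numeric or missing score values in indicator columns")
  }
  bad <- which(scores < 0 | scores > 10, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid("score out of [0, 10] at row %d, column '%s'",
                 bad[1L, 1L], indicators$name[bad[1L, 2L]])
  }
  grades <- factor(character(0), levels = mh_grades())
  if ("true_grade" %in% names(df)) {
    unknown <- setdiff(unique(df$true_grade), mh_grades())
    if (length(unknown)) {
      stop_invalid("unknown grade string '%s' in column true_grade", unknown[1L])
    }
    grades <- factor(df$true_grade, levels = mh_grades())
  }
  new_labeled_cohort(
    student_id = as.character(df$student_id),
    college = as.character(df$college),
    scores = scores,
    true_grades = grades,
    indicators = indicators
  )
}
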