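#' The four mental-health grades, in severity order
#'
#' @return Character vector `c("normal", "mild_anxiety", "moderate_anxiety",
#'   "severe_anxiety")`.
#' @export
mh_grades <- function() {
  c("normal", "mild_anxiety", "moderate_anxiety", "severe_anxiety")
}

#' Default evaluation-indicator definitions
#'
#' The shipped index system uses ten indicators on a 0-10 scale: nine
#' conventional psychometric dimensions plus one temporal-perception
#' indicator (scored from duration-estimation error, see
#' [quantify_temporal_perception()]). The list is configuration, not a fixed
#' taxonomy: pass your own data frame with columns `name` and `category`
#' (`"conventional"` or `"temporal_perception"`) anywhere indicators are
#' accepted.
#'
#' @return Data frame with columns `name`, `category`.
#' @export
default_indicators <- function() {
  data.frame(
    name = c("emotional_state", "interpersonal_relations", "academic_pressure",
             "sleep_quality", "self_cognition", "adaptability",
             "coping_style", "family_support", "life_satisfaction",
             "temporal_perception"),
    category = c(rep("conventional", 9L), "temporal_perception"),
    stringsAsFactors = FALSE
  )
}

check_indicators <- function(indicators) {
  if (!is.data.frame(indicators) ||
      !all(c("name", "category") %in% names(indicators))) {
    stop_invalid("`indicators` must be a data frame with columns name, category")
  }
  if (anyDuplicated(indicators$name)) {
    stop_invalid("indicator names must be unique")
  }
  if (!all(indicators$category %in% c("conventional", "temporal_perception"))) {
    stop_invalid("indicator categories must be 'conventional' or 'temporal_perception'")
  }
  indicators
}

#' Read indicator definitions from a YAML or JSON config block
#'
#' Expects a top-level `indicators` list of `{name, category}` entries (or a
#' bare list of such entries).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return Data frame with columns `name`, `category`.
#' @export
read_indicator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$indicators)) raw <- raw$indicators
  check_indicators(data.frame(
    name = vapply(raw, function(x) as.character(x$name), character(1)),
    category = vapply(raw, function(x) as.character(x$category), character(1)),
    stringsAsFactors = FALSE
  ))
}

#' Three-band indicator level of a 0-10 score
#'
#' A score of at least 8 reads as `normal`, a score below 3 as `obstacle`
#' (certain difficulties in that area), and everything in `[3, 8)` as
#' `average`. Vectorized.
#'
#' @param score Numeric vector of scores in `[0, 10]`.
#' @return Factor with levels `normal`, `average`, `obstacle`.
#' @export
indicator_level <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop_invalid("`score` must be finite numeric")
  }
  if (any(score < 0 | score > 10)) {
    stop_invalid("scores must lie in [0, 10]")
  }
  lvl <- ifelse(score >= 8, "normal", ifelse(score < 3, "obstacle", "average"))
  factor(lvl, levels = c("normal", "average", "obstacle"))
}

#' Score temporal perception from duration-estimation trials
#'
#' Temporal perception — a person's untimed sense of how long intervals last —
#' is measured by trials in which the subject estimates known durations. Each
#' trial's relative error is `|estimated - true| / true`; the trial errors are
#' aggregated by their median (robust to a single wild trial) and mapped to
#' the 0-10 indicator scale by a linear ramp:
#' `score = 10 * max(0, 1 - median_error / max_relative_error)`. A perfect
#' estimator scores 10; a median error at or beyond `max_relative_error`
#' scores 0.
#'
#' @param estimated_durations Numeric vector of estimates (seconds).
#' @param true_durations Numeric vector of true durations (seconds, > 0).
#' @param max_relative_error Median relative error at which the score
#'   saturates to 0 (default 1, i.e. a 100% misjudgment).
#' @return Scalar score in `[0, 10]`.
#' @export
quantify_temporal_perception <- function(estimated_durations, true_durations,
                                         max_relative_error = 1) {
  if (length(estimated_durations) != length(true_durations) ||
      length(true_durations) < 1L) {
    stop_invalid("estimated and true durations must have equal length >= 1")
  }
  if (any(true_durations <= 0)) {
    stop_invalid("true durations must be positive")
  }
  check_scalar_number(max_relative_error, "max_relative_error")
  if (max_relative_error <= 0) {
    stop_invalid("`max_relative_error` must be positive")
  }
  e <- abs(estimated_durations - true_durations) / true_durations
  agg <- stats::median(e)
  10 * max(0, 1 - agg / max_relative_error)
}

#' Map four clusters onto the four mental-health grades
#'
#' Higher indicator scores mean better mental health on the 0-10 convention,
#' so clusters are ordered by descending mean indicator score and assigned
#' `normal`, `mild_anxiety`, `moderate_anxiety`, `severe_anxiety` in that
#' order (ties broken by cluster index).
#'
#' @param result A `clustering_result` with exactly 4 clusters.
#' @param data The n x d score matrix the result was fitted on.
#' @return Named character vector: grade for each cluster index `1..4`.
#' @export
map_clusters_to_grades <- function(result, data) {
  stopifnot(inherits(result, "clustering_result"))
  data <- check_data_matrix(data)
  K <- nrow(result$centroids)
  if (K != 4L) {
    stop_invalid(paste0(
      "grade mapping is defined for exactly 4 clusters (got %d); ",
      "supply a custom cluster -> grade mapping for other K"), K)
  }
  means <- vapply(seq_len(K), function(k) {
    mean(data[result$assignment == k, , drop = FALSE])
  }, numeric(1))
  ord <- order(-means, seq_len(K))   # descending mean, ties by cluster index
  grades <- character(K)
  grades[ord] <- mh_grades()
  names(grades) <- as.character(seq_len(K))
  grades
}
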