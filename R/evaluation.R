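# Exact minimum-cost one-to-one assignment by dynamic programming over column
# subsets: f[mask] = cost of assigning the first popcount(mask) rows to the
# columns in mask. O(n * 2^n), exact; plenty for the <= ~16 clusters seen here.
assignment_min_cost <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop_invalid("cost matrix must be square")
  if (n > 20L) stop_invalid("assignment solver supports up to 20 rows")
  nmask <- bitwShiftL(1L, n)
  f <- rep(Inf, nmask)
  from <- integer(nmask)   # column chosen for the last row assigned
  f[1L] <- 0
  popcount <- integer(nmask)
  for (mask in seq_len(nmask - 1L)) {
    popcount[mask + 1L] <- popcount[bitwShiftR(mask, 1L) + 1L] +
      bitwAnd(mask, 1L)
  }
  for (mask in seq_len(nmask - 1L)) {
    row <- popcount[mask + 1L]
    for (col in seq_len(n)) {
      bit <- bitwShiftL(1L, col - 1L)
      if (bitwAnd(mask, bit) != 0L) {
        prev <- bitwXor(mask, bit)
        cand <- f[prev + 1L] + cost[row, col]
        if (cand < f[mask + 1L]) {
          f[mask + 1L] <- cand
          from[mask + 1L] <- col
        }
      }
    }
  }
  perm <- integer(n)
  mask <- nmask - 1L
  for (row in rev(seq_len(n))) {
    col <- from[mask + 1L]
    perm[row] <- col
    mask <- bitwXor(mask, bitwShiftL(1L, col - 1L))
  }
  list(assignment = perm, cost = f[nmask])
}

#' Hungarian-matched clustering accuracy
#'
#' External clustering accuracy: build the cluster x grade contingency table,
#' find the one-to-one cluster-to-grade matching that maximizes total
#' agreement (optimal assignment on the negated table, padding rectangular
#' tables with zero rows/columns), and divide the matched agreement by n.
#' Invariant under any bijective relabeling of clusters or grades, and never
#' below the largest true-grade share.
#'
#' @param predicted Integer vector of cluster labels.
#' @param true_labels Vector (factor or character) of ground-truth labels.
#' @return Accuracy in `[0, 1]`.
#' @export
match_accuracy <- function(predicted, true_labels) {
  if (length(predicted) != length(true_labels) || length(predicted) < 1L) {
    stop_invalid("predicted and true labels must have equal length >= 1")
  }
  tab <- table(predicted, as.character(true_labels))
  m <- max(nrow(tab), ncol(tab))
  padded <- matrix(0, m, m)
  padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  sol <- assignment_min_cost(-padded)
  -sol$cost / length(predicted)
}

#' Benchmark clustering methods on a labeled cohort
#'
#' Runs each requested method `n_seeds` times with run seeds `0..n_seeds-1`
#' on the same cohort (paired comparison) and reports per-run accuracy,
#' error rate, final loss and iteration count, plus per-method medians.
#' Methods: `kmeans_random` (K distinct random rows as initial centers),
#' `kmeans_pp` (K-means++ D-squared seeding), `fwa_kmeans` (the
#' fireworks-seeded hybrid).
#'
#' @param cohort A labeled `labeled_cohort`.
#' @param K Number of clusters.
#' @param methods Character subset of
#'   `c("kmeans_random", "kmeans_pp", "fwa_kmeans")`.
#' @param n_seeds Number of paired run seeds.
#' @param fwa_config,kmeans_config Base configurations; the run seed
#'   overrides their `seed` field each run.
#' @return An object of class `evaluation_report`: `runs` (data frame with
#'   columns method, seed, accuracy, error_rate, loss, iterations) and
#'   `summary` (per-method medians).
#' @export
benchmark <- function(cohort, K = 4L,
                      methods = c("kmeans_random", "kmeans_pp", "fwa_kmeans"),
                      n_seeds = 20L,
                      fwa_config = fireclust::fwa_config(),
                      kmeans_config = fireclust::kmeans_config()) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  if (!cohort$labeled) {
    stop_invalid("benchmark needs a labeled cohort (true_grade column)")
  }
  methods <- match.arg(methods, several.ok = TRUE)
  n_seeds <- check_count(n_seeds, "n_seeds", min = 1L)
  K <- check_count(K, "K", min = 1L)
  rows <- list()
  for (method in methods) {
    for (s in seq_len(n_seeds) - 1L) {
      res <- run_method(cohort$scores, K, method, s, fwa_config, kmeans_config)
      acc <- match_accuracy(res$assignment, cohort$true_grades)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, seed = s, accuracy = acc, error_rate = 1 - acc,
        loss = res$loss, iterations = res$iterations_run,
        stringsAsFactors = FALSE
      )
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs$method), function(g) {
    data.frame(method = g$method[1L],
               median_accuracy = stats::median(g$accuracy),
               median_error_rate = stats::median(g$error_rate),
               median_loss = stats::median(g$loss),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, K = K, n_seeds = n_seeds),
            class = "evaluation_report")
}

# Dispatch one clustering run with a given seed.
run_method <- function(scores, K, method, seed, fwa_cfg, km_cfg) {
  km_cfg$K <- K
  km_cfg$seed <- as.integer(seed)
  switch(
    method,
    kmeans_random = with_seed(seed, {
      init <- scores[sample.int(nrow(scores), K), , drop = FALSE]
      kmeans_fit(scores, km_cfg, init)
    }),
    kmeans_pp = with_seed(seed, {
      kmeans_fit(scores, km_cfg, kmeanspp_init(scores, K))
    }),
    fwa_kmeans = {
      fwa_cfg$seed <- as.integer(seed)
      fwa_kmeans(scores, K, fwa_cfg, km_cfg)
    },
    stop_invalid("unknown method '%s'", method)
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> K = %d, %d seeds per method\n",
              x$K, x$n_seeds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report
#'
#' `write_report_csv()` writes the per-run rows; `write_report_json()` writes
#' runs and per-method medians together.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  utils::write.csv(report$runs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(
    list(K = report$K, n_seeds = report$n_seeds,
         runs = report$runs, summary = report$summary),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
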