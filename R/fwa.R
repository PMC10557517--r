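#' Fireworks Algorithm configuration
#'
#' Bundles the hyperparameters of the Fireworks Algorithm (FWA). The defaults
#' reproduce the study settings: 100 iterations, 6 fireworks, explosion
#' amplitude 25, and 6 Gaussian-mutation sparks per generation.
#'
#' @param n_fireworks Number of fireworks kept per generation (the "fireworks
#'   scale" n).
#' @param spark_budget Total explosion-spark budget k shared across fireworks;
#'   fitter fireworks receive more sparks.
#' @param amplitude Maximum explosion radius; a firework's actual radius is the
#'   amplitude scaled by its fitness gap to the population best, so good
#'   fireworks search locally and poor ones explore.
#' @param clamp_low_frac,clamp_high_frac Spark counts are clamped to
#'   `[round(clamp_low_frac * k), round(clamp_high_frac * k)]` (hard minimum 1)
#'   so no firework monopolises or starves the budget.
#' @param n_mutation_sparks Number of Gaussian-mutation sparks generated per
#'   generation in total ("individual variation"); each picks a parent firework
#'   uniformly at random.
#' @param max_iterations Number of generations T.
#' @param bounds D x 2 matrix of per-dimension `[lo, hi]` search bounds. May be
#'   `NULL` here and supplied by the caller of [fwa_minimize()].
#' @param mutation_mode `"canonical"` multiplies chosen coordinates by
#'   Normal(1, 1) draws (the standard FWA mutation); `"as_printed"` multiplies
#'   by Normal(0, 1), which destroys position information in expectation and is
#'   kept only for fidelity to the original formula.
#' @param seed Integer seed; all randomness in [fwa_minimize()] flows from it.
#'
#' @return An object of class `fwa_config`.
#' @export
fwa_config <- function(n_fireworks = 6L,
                       spark_budget = 6L,
                       amplitude = 25,
                       clamp_low_frac = 0.1,
                       clamp_high_frac = 0.5,
                       n_mutation_sparks = 6L,
                       max_iterations = 100L,
                       bounds = NULL,
                       mutation_mode = c("canonical", "as_printed"),
                       seed = 0L) {
  mutation_mode <- match.arg(mutation_mode)
  n_fireworks <- check_count(n_fireworks, "n_fireworks", min = 1L)
  spark_budget <- check_count(spark_budget, "spark_budget", min = 1L)
  check_scalar_number(amplitude, "amplitude")
  if (amplitude <= 0) stop_invalid("`amplitude` must be positive")
  check_scalar_number(clamp_low_frac, "clamp_low_frac")
  check_scalar_number(clamp_high_frac, "clamp_high_frac")
  if (clamp_low_frac <= 0 || clamp_high_frac > 1 ||
      clamp_low_frac >= clamp_high_frac) {
    stop_invalid("need 0 < clamp_low_frac < clamp_high_frac <= 1")
  }
  n_mutation_sparks <- check_count(n_mutation_sparks, "n_mutation_sparks")
  max_iterations <- check_count(max_iterations, "max_iterations", min = 1L)
  if (!is.null(bounds)) bounds <- check_bounds(bounds)
  structure(
    list(
      n_fireworks = n_fireworks,
      spark_budget = spark_budget,
      amplitude = amplitude,
      clamp_low_frac = clamp_low_frac,
      clamp_high_frac = clamp_high_frac,
      n_mutation_sparks = n_mutation_sparks,
      max_iterations = max_iterations,
      bounds = bounds,
      mutation_mode = mutation_mode,
      seed = as.integer(seed)
    ),
    class = "fwa_config"
  )
}

#' @export
print.fwa_config <- function(x, ...) {
  cat("<fwa_config>\n")
  cat(sprintf("  fireworks scale n       : %d\n", x$n_fireworks))
  cat(sprintf("  spark budget k          : %d\n", x$spark_budget))
  cat(sprintf("  explosion amplitude     : %g\n", x$amplitude))
  cat(sprintf("  spark-count clamps      : [%g k, %g k]\n",
              x$clamp_low_frac, x$clamp_high_frac))
  cat(sprintf("  mutation sparks / gen   : %d (%s)\n",
              x$n_mutation_sparks, x$mutation_mode))
  cat(sprintf("  max iterations T        : %d\n", x$max_iterations))
  cat(sprintf("  seed                    : %d\n", x$seed))
  invisible(x)
}

#' Read or write an FWA configuration as YAML or JSON
#'
#' The file format is picked from the extension (`.yaml`/`.yml` vs `.json`).
#' Keys mirror the hyperparameter names (`max_iterations`, `n_mutation_sparks`,
#' `amplitude`, `n_fireworks`, ...); absent keys take the defaults of
#' [fwa_config()].
#'
#' @param path File path.
#' @param config For writing, an `fwa_config` object.
#' @return `read_fwa_config()` returns an `fwa_config`;
#'   `write_fwa_config()` returns `path` invisibly.
#' @export
read_fwa_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(fwa_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop_invalid("unknown FWA config keys: %s",
                                  paste(extra, collapse = ", "))
  if (!is.null(raw$bounds) && !is.matrix(raw$bounds)) {
    raw$bounds <- matrix(unlist(raw$bounds), ncol = 2L, byrow = TRUE)
  }
  do.call(fwa_config, raw)
}

#' @rdname read_fwa_config
#' @export
write_fwa_config <- function(config, path) {
  stopifnot(inherits(config, "fwa_config"))
  out <- unclass(config)
  if (!is.null(out$bounds)) {
    out$bounds <- lapply(seq_len(nrow(out$bounds)),
                         function(i) out$bounds[i, ])
  } else {
    out$bounds <- NULL
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Explosion radii from fitness values
#'
#' Each firework's explosion radius is the amplitude scaled by its fitness gap
#' to the population minimum: `r_i = (f_i - f_min) / sum_j (f_j - f_min) * A`.
#' Under minimization the best firework gets the smallest radius (local
#' search), the worst the largest (exploration). A floor of `1e-8 * amplitude`
#' keeps the best firework's radius strictly positive; if all fitnesses are
#' equal the budget is split evenly as `amplitude / n`.
#'
#' @param fitnesses Numeric vector of objective values (minimization).
#' @param amplitude Positive scalar, the maximum radius.
#' @return Numeric vector of radii, same length as `fitnesses`.
#' @export
explosion_radii <- function(fitnesses, amplitude) {
  if (length(fitnesses) == 0L || !is.numeric(fitnesses)) {
    stop_invalid("`fitnesses` must be a non-empty numeric vector")
  }
  if (!all(is.finite(fitnesses))) stop_invalid("`fitnesses` must be finite")
  check_scalar_number(amplitude, "amplitude")
  if (amplitude <= 0) stop_invalid("`amplitude` must be positive")
  gaps <- fitnesses - min(fitnesses)
  denom <- sum(gaps)
  if (denom <= .Machine$double.eps * max(1, abs(max(fitnesses)))) {
    return(rep(amplitude / length(fitnesses), length(fitnesses)))
  }
  pmax(gaps / denom * amplitude, 1e-8 * amplitude)
}

#' Spark counts from fitness values
#'
#' Allocates the spark budget k across fireworks in proportion to how good
#' each one is: `s_i = (f_max - f_i) / sum_j (f_max - f_j) * k`, rounded, then
#' clamped to `[round(low * k), round(high * k)]` with a hard minimum of one
#' spark. Equal fitnesses split the budget as `round(k / n)` each.
#'
#' @inheritParams explosion_radii
#' @param spark_budget Total spark budget k (positive integer).
#' @param clamp_low_frac,clamp_high_frac Clamp fractions of k.
#' @return Integer vector of per-firework spark counts.
#' @export
spark_counts <- function(fitnesses, spark_budget,
                         clamp_low_frac = 0.1, clamp_high_frac = 0.5) {
  if (length(fitnesses) == 0L || !is.numeric(fitnesses)) {
    stop_invalid("`fitnesses` must be a non-empty numeric vector")
  }
  if (!all(is.finite(fitnesses))) stop_invalid("`fitnesses` must be finite")
  k <- check_count(spark_budget, "spark_budget", min = 1L)
  lo <- max(1L, as.integer(round(clamp_low_frac * k)))
  hi <- max(lo, as.integer(round(clamp_high_frac * k)))
  gaps <- max(fitnesses) - fitnesses
  denom <- sum(gaps)
  if (denom <= .Machine$double.eps * max(1, abs(max(fitnesses)))) {
    return(rep(max(1L, as.integer(round(k / length(fitnesses)))),
               length(fitnesses)))
  }
  raw <- as.integer(round(gaps / denom * k))
  pmin(pmax(raw, lo), hi)
}

#' Map a position into box bounds by modular reflection
#'
#' Coordinates inside their `[lo, hi]` interval are untouched; an out-of-bound
#' coordinate x is wrapped to `lo + (|x - lo| mod (hi - lo))`.
#'
#' @param position Numeric vector of length D.
#' @param bounds D x 2 matrix of `[lo, hi]` rows.
#' @return Numeric vector inside the box.
#' @export
map_to_bounds <- function(position, bounds) {
  bounds <- check_bounds(bounds)
  if (length(position) != nrow(bounds)) {
    stop_invalid("position length %d does not match %d bound rows",
                 length(position), nrow(bounds))
  }
  lo <- bounds[, 1L]
  hi <- bounds[, 2L]
  out <- position < lo | position > hi
  if (any(out)) {
    position[out] <- lo[out] +
      (abs(position[out] - lo[out]) %% (hi[out] - lo[out]))
  }
  position
}

#' Explosion sparks around a parent firework
#'
#' Each spark perturbs a uniformly chosen subset of z ~ UniformInteger(1, D)
#' dimensions by `radius * Uniform(-1, 1)` (fresh draw per dimension) and
#' copies the parent elsewhere, then is mapped back into the bounds.
#' Consumes the current RNG stream; seed at the entry point.
#'
#' @param parent Numeric position vector of length D.
#' @param radius Non-negative explosion radius.
#' @param count Number of sparks to generate.
#' @param bounds D x 2 bounds matrix.
#' @return List of `count` position vectors.
#' @export
generate_explosion_sparks <- function(parent, radius, count, bounds) {
  check_scalar_number(radius, "radius", lower = 0)
  count <- check_count(count, "count")
  bounds <- check_bounds(bounds)
  d <- length(parent)
  lapply(seq_len(count), function(i) {
    z <- sample.int(d, 1L)
    dims <- sample.int(d, z)
    spark <- parent
    spark[dims] <- spark[dims] + radius * stats::runif(z, -1, 1)
    map_to_bounds(spark, bounds)
  })
}

#' Gaussian mutation sparks
#'
#' Diversity-injecting sparks: on a uniformly chosen subset of dimensions the
#' parent coordinate is multiplied by a Gaussian draw — Normal(1, 1) in
#' `"canonical"` mode (a perturbation around the identity) or Normal(0, 1) in
#' `"as_printed"` mode (the literal published formula, which recentres
#' coordinates at zero in expectation). Consumes the current RNG stream.
#'
#' @inheritParams generate_explosion_sparks
#' @param mode `"canonical"` or `"as_printed"`.
#' @return List of `count` position vectors.
#' @export
gaussian_sparks <- function(parent, count, mode = c("canonical", "as_printed"),
                            bounds) {
  mode <- match.arg(mode)
  count <- check_count(count, "count")
  bounds <- check_bounds(bounds)
  mu <- if (mode == "canonical") 1 else 0
  d <- length(parent)
  lapply(seq_len(count), function(i) {
    z <- sample.int(d, 1L)
    dims <- sample.int(d, z)
    spark <- parent
    spark[dims] <- spark[dims] * stats::rnorm(z, mean = mu, sd = 1)
    map_to_bounds(spark, bounds)
  })
}

#' Select the next generation of fireworks
#'
#' Elitism plus crowding: the best-fitness candidate always survives (ties by
#' lowest index); the remaining `n - 1` slots are filled by sampling without
#' replacement with probability proportional to each candidate's summed
#' Euclidean distance to all other candidates, which favours isolated
#' candidates and preserves diversity. If fewer than n candidates exist, all
#' are kept and the shortfall is filled by uniform re-draws.
#'
#' @param candidates List of lists with elements `position` and `fitness`.
#' @param n Number of fireworks to retain.
#' @return List of `n` candidates.
#' @export
select_next_generation <- function(candidates, n) {
  if (length(candidates) == 0L) stop_invalid("`candidates` must be non-empty")
  n <- check_count(n, "n", min = 1L)
  m <- length(candidates)
  if (m <= n) {
    extra <- if (m < n) candidates[sample.int(m, n - m, replace = TRUE)] else list()
    return(c(candidates, extra))
  }
  fit <- vapply(candidates, `[[`, numeric(1), "fitness")
  best <- which.min(fit)            # which.min takes the lowest index on ties
  pos <- do.call(rbind, lapply(candidates, `[[`, "position"))
  dists <- as.matrix(stats::dist(pos))
  crowd <- rowSums(dists)
  rest <- setdiff(seq_len(m), best)
  w <- crowd[rest]
  if (sum(w) <= 0) w <- rep(1, length(rest))
  picked <- rest[sample.int(length(rest), n - 1L, prob = w)]
  candidates[c(best, picked)]
}

#' Minimize an objective with the Fireworks Algorithm
#'
#' Runs `max_iterations` generations of evaluate / explode / mutate / select
#' over a bounded box. Each generation every firework emits explosion sparks
#' (count and radius set by its fitness rank) and the population emits
#' `n_mutation_sparks` Gaussian sparks; the next generation is selected from
#' fireworks and sparks with elitism. Deterministic given `config$seed`.
#'
#' @param objective Function mapping a position vector to a finite scalar
#'   (minimized).
#' @param config An [fwa_config()]; its `bounds` must be set.
#' @return An object of class `fwa_result` with elements `best_position`,
#'   `best_fitness`, `history` (best fitness seen so far, per iteration, hence
#'   non-increasing) and `iterations_run`.
#' @export
fwa_minimize <- function(objective, config) {
  stopifnot(inherits(config, "fwa_config"))
  bounds <- check_bounds(config$bounds)
  d <- nrow(bounds)
  evaluate <- function(position) {
    f <- objective(position)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f)) {
      stop_invalid("objective returned a non-finite value at position (%s)",
                   paste(signif(position, 6), collapse = ", "))
    }
    f
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$n_fireworks), function(i) {
      p <- stats::runif(d, bounds[, 1L], bounds[, 2L])
      list(position = p, fitness = evaluate(p))
    })
    best <- pop[[which.min(vapply(pop, `[[`, numeric(1), "fitness"))]]
    history <- numeric(config$max_iterations)
    for (t in seq_len(config$max_iterations)) {
      fit <- vapply(pop, `[[`, numeric(1), "fitness")
      radii <- explosion_radii(fit, config$amplitude)
      counts <- spark_counts(fit, config$spark_budget,
                             config$clamp_low_frac, config$clamp_high_frac)
      sparks <- list()
      for (i in seq_along(pop)) {
        sparks <- c(sparks, generate_explosion_sparks(
          pop[[i]]$position, radii[i], counts[i], bounds))
      }
      if (config$n_mutation_sparks > 0L) {
        parents <- sample.int(length(pop), config$n_mutation_sparks,
                              replace = TRUE)
        for (i in parents) {
          sparks <- c(sparks, gaussian_sparks(
            pop[[i]]$position, 1L, config$mutation_mode, bounds))
        }
      }
      spark_states <- lapply(sparks, function(p) {
        list(position = p, fitness = evaluate(p))
      })
      candidates <- c(pop, spark_states)
      cand_fit <- vapply(candidates, `[[`, numeric(1), "fitness")
      gen_best <- candidates[[which.min(cand_fit)]]
      if (gen_best$fitness < best$fitness) best <- gen_best
      history[t] <- best$fitness
      pop <- select_next_generation(candidates, config$n_fireworks)
    }
    structure(
      list(
        best_position = best$position,
        best_fitness = best$fitness,
        history = history,
        iterations_run = config$max_iterations
      ),
      class = "fwa_result"
    )
  })
}

#' @export
print.fwa_result <- function(x, ...) {
  cat("<fwa_result>\n")
  cat(sprintf("  iterations : %d\n", x$iterations_run))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  cat(sprintf("  dimension  : %d\n", length(x$best_position)))
  invisible(x)
}
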