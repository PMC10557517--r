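# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded entry points never perturb the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_invalid("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar_number(x, name, lower = min)
  if (x != as.integer(x)) stop_invalid("`%s` must be an integer, got %s", name, x)
  as.integer(x)
}

# Validate an n x 2 bounds matrix (columns lo, hi) or a 2-column data frame.
check_bounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || nrow(bounds) < 1L || !all(is.finite(bounds))) {
    stop_invalid("`bounds` must be a D x 2 finite matrix of [lo, hi] rows")
  }
  if (any(bounds[, 1L] >= bounds[, 2L])) {
    stop_invalid("every bound must satisfy lo < hi")
  }
  unname(bounds)
}
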