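#' K-means configuration
#'
#' @param K Number of clusters.
#' @param max_iterations Maximum assign/update iterations.
#' @param loss_tolerance Relative loss-change threshold; the loop stops when
#'   `|L_prev - L| / max(L_prev, eps) < loss_tolerance`.
#' @param seed Integer seed, used only by stochastic initializers
#'   ([kmeanspp_init()], random-row init); Lloyd iteration itself is
#'   deterministic.
#' @return An object of class `kmeans_config`.
#' @export
kmeans_config <- function(K = 4L, max_iterations = 100L,
                          loss_tolerance = 1e-6, seed = 0L) {
  K <- check_count(K, "K", min = 1L)
  max_iterations <- check_count(max_iterations, "max_iterations", min = 1L)
  check_scalar_number(loss_tolerance, "loss_tolerance", lower = 0)
  structure(
    list(K = K, max_iterations = max_iterations,
         loss_tolerance = loss_tolerance, seed = as.integer(seed)),
    class = "kmeans_config"
  )
}

check_data_matrix <- function(data) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L) {
    stop_invalid("`data` must be a non-empty numeric matrix")
  }
  if (!all(is.finite(data))) stop_invalid("`data` contains non-finite values")
  unname(data)
}

#' Euclidean distance between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`.
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) {
    stop_invalid("length mismatch: %d vs %d", length(x), length(y))
  }
  sqrt(sum((x - y)^2))
}

# n x K matrix of squared distances from every row of `data` to every center.
squared_distances <- function(data, centers) {
  cross <- data %*% t(centers)
  outer(rowSums(data^2), rep(1, nrow(centers))) -
    2 * cross +
    outer(rep(1, nrow(data)), rowSums(centers^2))
}

#' Assign samples to their nearest centroid
#'
#' Exact distance ties are broken by the lowest centroid index.
#'
#' @param data n x d numeric matrix (rows = samples).
#' @param centroids K x d numeric matrix.
#' @return Integer vector of 1-based cluster labels, length n.
#' @export
assign_points <- function(data, centroids) {
  data <- check_data_matrix(data)
  centroids <- check_data_matrix(centroids)
  if (ncol(data) != ncol(centroids)) {
    stop_invalid("data has %d columns but centroids have %d",
                 ncol(data), ncol(centroids))
  }
  d2 <- squared_distances(data, centroids)
  max.col(-d2, ties.method = "first")
}

#' Update centroids as within-cluster means
#'
#' An empty cluster is repaired by re-seeding it with the single sample
#' currently farthest from its own centroid (removed from its donor cluster),
#' after which the means are recomputed. This keeps K fixed.
#'
#' @param data n x d numeric matrix.
#' @param assignment Integer labels in `1..K`.
#' @param K Number of clusters.
#' @return K x d matrix of centroids.
#' @export
update_centroids <- function(data, assignment, K) {
  data <- check_data_matrix(data)
  K <- check_count(K, "K", min = 1L)
  if (length(assignment) != nrow(data)) {
    stop_invalid("assignment length %d does not match %d samples",
                 length(assignment), nrow(data))
  }
  if (any(assignment < 1L | assignment > K)) {
    stop_invalid("labels must lie in 1..K")
  }
  if (nrow(data) < K) stop_invalid("cannot form %d clusters from %d samples",
                                   K, nrow(data))
  assignment <- as.integer(assignment)
  repeat {
    sizes <- tabulate(assignment, nbins = K)
    empty <- which(sizes == 0L)
    if (length(empty) == 0L) break
    # farthest-from-own-centroid sample among clusters with > 1 member
    means <- cluster_means(data, assignment, K, sizes)
    resid <- rowSums((data - means[assignment, , drop = FALSE])^2)
    resid[sizes[assignment] <= 1L] <- -Inf
    donor <- which.max(resid)
    if (!is.finite(resid[donor])) {
      stop_invalid("cannot repair empty cluster: all donor clusters are singletons")
    }
    assignment[donor] <- empty[1L]
  }
  cluster_means(data, assignment, K, tabulate(assignment, nbins = K))
}

cluster_means <- function(data, assignment, K, sizes) {
  sums <- matrix(0, K, ncol(data))
  present <- rowsum(data, group = assignment)
  sums[as.integer(rownames(present)), ] <- present
  sums / pmax(sizes, 1L)
}

#' Sum-of-squared-errors clustering loss
#'
#' `L = sum_i sum_{x in cluster i} ||x - c_i||^2`, the objective both the
#' Fireworks Algorithm and K-means minimize here.
#'
#' @inheritParams update_centroids
#' @param centroids K x d matrix.
#' @return Non-negative scalar.
#' @export
sse_loss <- function(data, centroids, assignment) {
  data <- check_data_matrix(data)
  centroids <- check_data_matrix(centroids)
  sum(rowSums((data - centroids[assignment, , drop = FALSE])^2))
}

#' Lloyd's K-means from explicit initial centroids
#'
#' Alternates nearest-centroid assignment and mean updates until the relative
#' loss change falls below `config$loss_tolerance` or `config$max_iterations`
#' is reached. The per-iteration loss sequence is non-increasing.
#'
#' @param data n x d numeric matrix.
#' @param config A [kmeans_config()].
#' @param initial_centroids K x d matrix of starting centers.
#' @return An object of class `clustering_result`: `centroids`, `assignment`
#'   (1-based labels), `loss`, `loss_history`, `iterations_run`, `converged`.
#' @export
kmeans_fit <- function(data, config, initial_centroids) {
  data <- check_data_matrix(data)
  stopifnot(inherits(config, "kmeans_config"))
  centroids <- check_data_matrix(initial_centroids)
  K <- nrow(centroids)
  if (K != config$K) {
    stop_invalid("initial centroids have %d rows but config$K = %d",
                 K, config$K)
  }
  if (K > nrow(data)) stop_invalid("K = %d exceeds n = %d", K, nrow(data))
  labels <- assign_points(data, centroids)
  loss_prev <- Inf
  loss_history <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(config$max_iterations)) {
    centroids <- update_centroids(data, labels, K)
    labels <- assign_points(data, centroids)
    loss <- sse_loss(data, centroids, labels)
    loss_history <- c(loss_history, loss)
    iterations <- t
    if (is.finite(loss_prev) &&
        abs(loss_prev - loss) / max(loss_prev, .Machine$double.eps) <
          config$loss_tolerance) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }
  # report the loss of the returned (centroids, labels) pair
  centroids <- update_centroids(data, labels, K)
  labels <- assign_points(data, centroids)
  structure(
    list(
      centroids = centroids,
      assignment = labels,
      loss = sse_loss(data, centroids, labels),
      loss_history = loss_history,
      iterations_run = iterations,
      converged = converged
    ),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat("<clustering_result>\n")
  cat(sprintf("  K          : %d\n", nrow(x$centroids)))
  cat(sprintf("  n          : %d\n", length(x$assignment)))
  cat(sprintf("  loss (SSE) : %.6g\n", x$loss))
  cat(sprintf("  iterations : %d (%s)\n", x$iterations_run,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' K-means++ initialization
#'
#' First center drawn uniformly from the samples; each subsequent center drawn
#' with probability proportional to its squared distance to the nearest center
#' already chosen (D-squared weighting). Consumes the current RNG stream.
#'
#' @param data n x d numeric matrix.
#' @param K Number of centers.
#' @return K x d matrix of centers (rows of `data`).
#' @export
kmeanspp_init <- function(data, K) {
  data <- check_data_matrix(data)
  K <- check_count(K, "K", min = 1L)
  if (K > nrow(data)) stop_invalid("K = %d exceeds n = %d", K, nrow(data))
  idx <- integer(K)
  idx[1L] <- sample.int(nrow(data), 1L)
  if (K > 1L) {
    d2 <- rowSums((data - matrix(data[idx[1L], ], nrow(data), ncol(data),
                                 byrow = TRUE))^2)
    for (j in 2L:K) {
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(nrow(data), 1L)
      } else {
        idx[j] <- sample.int(nrow(data), 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((data - matrix(data[idx[j], ], nrow(data),
                                            ncol(data), byrow = TRUE))^2))
    }
  }
  data[idx, , drop = FALSE]
}

#' Decode a flat position vector into a centroid matrix
#'
#' Row-major reshape: the first d entries are center 1, the next d center 2,
#' and so on. Inverse of `as.vector(t(centers))`.
#'
#' @param position Numeric vector of length `K * d`.
#' @param K,d Number of centers and dimensions.
#' @return K x d matrix.
#' @export
decode_centroids <- function(position, K, d) {
  if (length(position) != K * d) {
    stop_invalid("position length %d != K * d = %d", length(position), K * d)
  }
  matrix(position, nrow = K, ncol = d, byrow = TRUE)
}

#' Clustering objective and search bounds for the Fireworks Algorithm
#'
#' Returns the map from a flat centroid encoding to the SSE loss of the
#' nearest-centroid assignment it induces, together with the search box:
#' per-dimension data min/max repeated K times (centers outside the data hull
#' are never optimal).
#'
#' @param data n x d numeric matrix.
#' @param K Number of clusters.
#' @return List with `objective` (function position -> loss) and `bounds`
#'   (`K*d` x 2 matrix).
#' @export
clustering_objective <- function(data, K) {
  data <- check_data_matrix(data)
  K <- check_count(K, "K", min = 1L)
  if (K > nrow(data)) stop_invalid("K = %d exceeds n = %d", K, nrow(data))
  d <- ncol(data)
  sq_norms <- rowSums(data^2)
  objective <- function(position) {
    centers <- decode_centroids(position, K, d)
    d2 <- sq_norms - 2 * (data %*% t(centers)) +
      outer(rep(1, nrow(data)), rowSums(centers^2))
    sum(pmax(apply(d2, 1L, min), 0))
  }
  lo <- apply(data, 2L, min)
  hi <- apply(data, 2L, max)
  # degenerate constant columns would give lo = hi; widen minimally
  flat <- hi - lo <= 0
  hi[flat] <- lo[flat] + 1e-8
  bounds <- cbind(rep(lo, times = K), rep(hi, times = K))
  list(objective = objective, bounds = bounds)
}

#' Hybrid clustering: Fireworks-Algorithm-seeded K-means
#'
#' Runs the Fireworks Algorithm on the flat-centroid SSE objective, decodes
#' the best firework into K initial centers, and refines with Lloyd's
#' K-means. The final loss never exceeds the best FWA fitness, because Lloyd
#' iteration from that start is monotone.
#'
#' @param data n x d numeric matrix.
#' @param K Number of clusters.
#' @param fwa_config An [fwa_config()] (its `bounds` are overwritten with the
#'   data-derived search box).
#' @param kmeans_config A [kmeans_config()]; its `K` is overridden by `K`.
#' @return A `clustering_result` with an extra element `fwa` (the
#'   `fwa_result` of the seeding stage).
#' @export
fwa_kmeans <- function(data, K,
                       fwa_config = fireclust::fwa_config(),
                       kmeans_config = fireclust::kmeans_config()) {
  data <- check_data_matrix(data)
  K <- check_count(K, "K", min = 1L)
  obj <- clustering_objective(data, K)
  fwa_config$bounds <- obj$bounds
  fwa_res <- fwa_minimize(obj$objective, fwa_config)
  init <- decode_centroids(fwa_res$best_position, K, ncol(data))
  kmeans_config$K <- K
  res <- kmeans_fit(data, kmeans_config, init)
  res$fwa <- fwa_res
  res
}

#' Exhaustive optimal partition (test oracle)
#'
#' Enumerates every partition of the samples into at most K non-empty blocks
#' (restricted growth strings), scores each by the SSE loss with centroids at
#' block means, and returns the minimum. Refuses instances with more than
#' 1e5 partitions.
#'
#' @param data n x d numeric matrix (small n).
#' @param K Maximum number of blocks.
#' @return List with `assignment` (1-based labels of the optimal partition)
#'   and `loss`.
#' @export
exhaustive_optimal_partition <- function(data, K) {
  data <- check_data_matrix(data)
  K <- check_count(K, "K", min = 1L)
  n <- nrow(data)
  if (stirling_partitions(n, K) > 1e5) {
    stop_invalid("instance too large: > 1e5 partitions of %d samples into <= %d blocks",
                 n, K)
  }
  best_loss <- Inf
  best_labels <- NULL
  labels <- integer(n)
  recurse <- function(i, used) {
    if (i > n) {
      means <- cluster_means(data, labels, used, tabulate(labels, nbins = used))
      loss <- sse_loss(data, means, labels)
      if (loss < best_loss) {
        best_loss <<- loss
        best_labels <<- labels
      }
      return(invisible(NULL))
    }
    for (b in seq_len(min(used + 1L, K))) {
      labels[i] <<- b
      recurse(i + 1L, max(used, b))
    }
  }
  recurse(1L, 0L)
  list(assignment = best_labels, loss = best_loss)
}

# number of set partitions of n elements into at most K non-empty blocks
stirling_partitions <- function(n, K) {
  # S(i, j) via the triangle recurrence, summed over j = 1..K
  S <- matrix(0, n + 1L, K + 1L)
  S[1L, 1L] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, K))) {
      S[i + 1L, j + 1L] <- S[i, j] + j * S[i, j + 1L]
    }
  }
  sum(S[n + 1L, -1L])
}
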