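test_that("euclidean distance matches hand values and is symmetric", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_equal(euclidean_distance(c(1, 2), c(5, 7)),
               euclidean_distance(c(5, 7), c(1, 2)))
  expect_error(euclidean_distance(1:2, 1:3), "mismatch")
})

test_that("assignment picks the nearest centroid with low-index tie-break", {
  data <- rbind(0, 10)
  centroids <- rbind(1, 9)
  expect_identical(assign_points(data, centroids), c(1L, 2L))
  # equidistant sample goes to the lower centroid index
  expect_identical(assign_points(rbind(5), rbind(0, 10)), 1L)
  # planted points around two distant centers, checked against a brute-force
  # distance table
  pl <- planted_blobs(n_per = 3, centers = rbind(c(0, 0), c(50, 50)), seed = 1)
  lab <- assign_points(pl$data, pl$centers)
  brute <- apply(pl$data, 1, function(x) {
    which.min(apply(pl$centers, 1, function(c) euclidean_distance(x, c)))
  })
  expect_identical(lab, as.integer(brute))
  expect_identical(lab, pl$labels)
})

test_that("centroid update averages members and repairs empty clusters", {
  expect_equal(update_centroids(rbind(c(0, 0), c(2, 2)), c(1L, 1L), 1L),
               rbind(c(1, 1)))
  # singletons reproduce the samples
  data <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(update_centroids(data, 1:3, 3L), data)
  # empty cluster 2 is re-seeded with the farthest-from-centroid sample
  data <- rbind(c(0, 0), c(1, 1), c(9, 9))
  cents <- update_centroids(data, c(1L, 1L, 1L), 2L)
  expect_true(any(apply(cents, 1, function(c) all(c == c(9, 9)))))
  expect_equal(nrow(cents), 2L)
  expect_error(update_centroids(rbind(c(0, 0)), 1L, 2L), "clusters")
  expect_error(update_centroids(data, c(1L, 5L, 1L), 2L), "1..K")
})

test_that("SSE loss matches hand arithmetic and nearest-assignment optimality", {
  data <- rbind(c(1, 1), c(2, 2))
  expect_equal(sse_loss(data, data, 1:2), 0)
  expect_equal(sse_loss(rbind(0, 2), rbind(1), c(1L, 1L)), 2)
  # nearest assignment minimizes the loss over labelings of fixed centroids
  set.seed(14)
  data <- matrix(rnorm(20), 10, 2)
  cents <- matrix(rnorm(6), 3, 2)
  best <- sse_loss(data, cents, assign_points(data, cents))
  for (i in 1:20) {
    other <- sample.int(3, 10, replace = TRUE)
    expect_gte(sse_loss(data, cents, other) + 1e-12, best)
  }
})

test_that("kmeans_fit converges on separable data and reports a consistent loss", {
  # two tight 1-D pairs: the unique stable partition has centers 0.05, 10.05
  data <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  res <- kmeans_fit(data, kmeans_config(K = 2L), rbind(1, 9))
  expect_equal(sort(res$centroids[, 1]), c(0.05, 10.05))
  expect_equal(res$loss, 0.01)
  expect_true(res$converged)
  # a fixed point converges immediately
  res2 <- kmeans_fit(data, kmeans_config(K = 2L), res$centroids)
  expect_lte(res2$iterations_run, 2L)
  expect_identical(res2$assignment, res$assignment)
  # reported loss always equals the loss recomputed from the returned pieces
  expect_equal(res$loss, sse_loss(data, res$centroids, res$assignment),
               tolerance = 1e-12)
})

test_that("kmeans per-iteration loss is non-increasing on random data", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    d <- sample(1:4, 1)
    K <- sample(2:4, 1)
    data <- matrix(runif(n * d, 0, 10), n, d)
    init <- data[sample.int(n, K), , drop = FALSE]
    res <- kmeans_fit(data, kmeans_config(K = K), init)
    expect_true(all(diff(res$loss_history) <= 1e-12))
    expect_equal(res$loss, sse_loss(data, res$centroids, res$assignment),
                 tolerance = 1e-12)
  }
})

test_that("permuting initial centroids permutes labels but not the loss", {
  pl <- planted_blobs(n_per = 6, seed = 2)
  init <- pl$centers + 0.5
  res1 <- kmeans_fit(pl$data, kmeans_config(K = 4L), init)
  perm <- c(3L, 1L, 4L, 2L)
  res2 <- kmeans_fit(pl$data, kmeans_config(K = 4L), init[perm, ])
  expect_equal(res1$loss, res2$loss, tolerance = 1e-12)
  # same partition up to relabeling
  expect_equal(match_accuracy(res2$assignment, res1$assignment), 1)
})

test_that("kmeans_fit agrees with the reference Lloyd implementation", {
  means <- rbind(c(0, 0), c(6, 0), c(0, 6))
  for (s in 1:10) {
    set.seed(100 + s)
    grp <- sample.int(3, 60, replace = TRUE)
    data <- means[grp, ] + matrix(rnorm(60 * 2), 60, 2)
    set.seed(200 + s)
    init <- kmeanspp_init(data, 3L)
    mine <- kmeans_fit(data, kmeans_config(K = 3L, loss_tolerance = 0), init)
    ref <- suppressWarnings(
      stats::kmeans(data, centers = init, iter.max = 100, algorithm = "Lloyd")
    )
    expect_equal(mine$loss, ref$tot.withinss, tolerance = 1e-8)
  }
})

test_that("kmeans++ seeding spreads centers by squared distance", {
  data <- matrix(c(1, 2, 3, 4), ncol = 1)
  set.seed(41)
  c1 <- kmeanspp_init(data, 1L)
  expect_true(c1[1, 1] %in% data[, 1])
  # with K = n and no duplicates, the centers are a permutation of the rows
  set.seed(42)
  cK <- kmeanspp_init(data, 4L)
  expect_equal(sort(cK[, 1]), data[, 1])
  # two far blobs: the second center lands in the opposite blob almost always
  blobs <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                 matrix(rnorm(20, 50, 0.1), 10, 2))
  set.seed(43)
  opposite <- 0L
  for (i in 1:200) {
    cc <- kmeanspp_init(blobs, 2L)
    if (abs(cc[1, 1] - cc[2, 1]) > 25) opposite <- opposite + 1L
  }
  expect_gte(opposite, 190L)
})

test_that("centroid encoding decodes row-major and round-trips", {
  expect_equal(decode_centroids(c(1, 2, 3, 4), 2, 2), rbind(c(1, 2), c(3, 4)))
  C <- matrix(rnorm(12), 4, 3)
  expect_equal(decode_centroids(as.vector(t(C)), 4, 3), C)
  expect_equal(decode_centroids(rep(0, 6), 3, 2), matrix(0, 3, 2))
  expect_error(decode_centroids(1:5, 2, 2), "length")
})

test_that("the clustering objective scores encoded centroid sets correctly", {
  data <- matrix(c(0, 4), ncol = 1)
  obj <- clustering_objective(data, 2L)
  # both centers stacked on one sample
  expect_equal(obj$objective(c(0, 0)), 16)
  # centers on the two samples: perfect fit
  expect_equal(obj$objective(c(0, 4)), 0)
  # label symmetry: permuting center blocks leaves the objective unchanged
  pl <- planted_blobs(n_per = 2, seed = 3)
  obj2 <- clustering_objective(pl$data, 2L)
  pos <- c(1, 2, 7, 8)
  expect_equal(obj2$objective(pos), obj2$objective(c(7, 8, 1, 2)))
  # bounds are the data box repeated K times
  expect_equal(obj2$bounds[, 1], rep(apply(pl$data, 2, min), 2))
  # optimal-partition encoding attains the exhaustive optimum
  tiny <- matrix(c(0, 1, 10, 11, 0, 0, 0, 0), ncol = 2)
  oracle <- exhaustive_optimal_partition(tiny, 2L)
  means <- rbind(colMeans(tiny[1:2, ]), colMeans(tiny[3:4, ]))
  obj3 <- clustering_objective(tiny, 2L)
  expect_equal(obj3$objective(as.vector(t(means))), oracle$loss)
})

test_that("exhaustive oracle matches hand-scored tiny partitions", {
  expect_equal(exhaustive_optimal_partition(matrix(c(0, 10), ncol = 1), 2L)$loss, 0)
  o <- exhaustive_optimal_partition(matrix(c(0, 1, 10), ncol = 1), 2L)
  expect_equal(o$loss, 0.5)
  expect_identical(o$assignment[1], o$assignment[2])
  expect_false(o$assignment[1] == o$assignment[3])
  # K = 1 gives the total sum of squared deviations from the grand mean
  x <- matrix(c(1, 2, 6), ncol = 1)
  expect_equal(exhaustive_optimal_partition(x, 1L)$loss,
               sum((x - mean(x))^2))
  expect_error(exhaustive_optimal_partition(matrix(rnorm(40), ncol = 2), 10L),
               "too large")
})

test_that("the hybrid refines the FWA seed and nails planted partitions", {
  pl <- planted_blobs(n_per = 5, sd = 0.05, seed = 4)
  res <- fwa_kmeans(pl$data, 4L,
                    fwa_config(max_iterations = 40L, seed = 0),
                    kmeans_config())
  planted_means <- update_centroids(pl$data, pl$labels, 4L)
  planted_loss <- sse_loss(pl$data, planted_means, pl$labels)
  expect_equal(res$loss, planted_loss, tolerance = 1e-9)
  expect_lte(res$loss, res$fwa$best_fitness + 1e-12)
  # n = K: every sample its own cluster, zero loss
  tiny <- matrix(c(0, 5, 10), ncol = 1)
  res0 <- fwa_kmeans(tiny, 3L, fwa_config(max_iterations = 10L, seed = 1))
  expect_equal(res0$loss, 0)
  expect_equal(sort(res0$assignment), 1:3)
  # determinism
  res_a <- fwa_kmeans(pl$data, 4L, fwa_config(max_iterations = 15L, seed = 7))
  res_b <- fwa_kmeans(pl$data, 4L, fwa_config(max_iterations = 15L, seed = 7))
  expect_identical(res_a, res_b)
})

test_that("hybrid attains the exhaustive optimum on tiny instances", {
  hits <- 0L
  sep_hits <- 0L
  sep_total <- 0L
  for (s in 1:30) {
    set.seed(s)
    n <- sample(4:8, 1)
    sep <- s %% 2 == 0   # alternate well-separated and overlapping designs
    offset <- if (sep) 10 else 1.5
    data <- matrix(rnorm(n * 2, sd = 0.5), n, 2)
    data[seq_len(n %/% 2), ] <- data[seq_len(n %/% 2), ] + offset
    oracle <- exhaustive_optimal_partition(data, 2L)
    res <- fwa_kmeans(data, 2L, fwa_config(max_iterations = 30L, seed = s))
    hit <- res$loss <= oracle$loss + 1e-9
    hits <- hits + hit
    if (sep) {
      sep_total <- sep_total + 1L
      sep_hits <- sep_hits + hit
    }
  }
  expect_gte(hits, 24L)          # >= 80% of all instances
  expect_identical(sep_hits, sep_total)  # 100% of well-separated instances
})
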