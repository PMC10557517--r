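# Shared fixtures and independent oracles, built in code at test time.

# Four well-separated planted blobs in d dimensions.
planted_blobs <- function(n_per = 5L, d = 2L, centers = NULL, sd = 0.05,
                          seed = 42L) {
  if (is.null(centers)) {
    centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2L, byrow = TRUE)
    centers <- centers[, rep(seq_len(2L), length.out = d), drop = FALSE]
  }
  K <- nrow(centers)
  set.seed(seed)
  data <- do.call(rbind, lapply(seq_len(K), function(k) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[k, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(data = data, labels = rep(seq_len(K), each = n_per), centers = centers)
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Brute-force matched accuracy: maximize agreement over every bijection
# between (padded) clusters and grades. Independent of the package's DP.
brute_force_accuracy <- function(predicted, true_labels) {
  tab <- table(predicted, as.character(true_labels))
  m <- max(dim(tab))
  padded <- matrix(0, m, m)
  padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (p in all_permutations(m)) {
    best <- max(best, sum(padded[cbind(seq_len(m), p)]))
  }
  best / length(predicted)
}

# Brute-force minimum assignment cost over all permutations.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  for (p in all_permutations(n)) {
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  }
  best
}

sphere_bounds <- function(d = 5L, lim = 10) {
  matrix(rep(c(-lim, lim), each = d), d, 2L)
}

# Small default-style cohort for quick end-to-end tests.
small_cohort <- function(n_per_college = 20L, noise_sd = 0.8, seed = 0L) {
  generate_cohort(cohort_config(n_per_college = n_per_college,
                                noise_sd = noise_sd, seed = seed))
}
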