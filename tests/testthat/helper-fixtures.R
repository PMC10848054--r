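# Shared fixture builders. Everything is generated in code; no stored data.

tiny_spec <- function(n_hc = 2L, n_cn = 0L, n_ci = 2L, n_timepoints = 80L,
                      n_parcels = 28L, seed = 42L, ...) {
  cohort_spec(n_per_group = c(HC = n_hc, `TLE-CN` = n_cn, `TLE-CI` = n_ci),
              n_timepoints = n_timepoints, n_parcels = n_parcels,
              thal_grid = c(2L, 2L, 2L), seed = seed, ...)
}

# uniform coupling tables for controlled experiments
uniform_within <- function(value) {
  m <- matrix(value, 3L, 7L, dimnames = list(c("HC", "TLE-CN", "TLE-CI"),
                                             networks7()))
  m
}

uniform_between <- function(value) {
  one <- matrix(value, 7L, 7L, dimnames = list(networks7(), networks7()))
  diag(one) <- 0
  list(`HC` = one, `TLE-CN` = one, `TLE-CI` = one)
}

# wrap a raw adjacency matrix as a binary graph
graph_from_adj <- function(adj, partition = NULL) {
  g <- list(adjacency = adj, sparsity = NA_real_,
            achieved_sparsity = NA_real_, n_edges = sum(adj) / 2,
            partition = NULL)
  if (!is.null(partition)) {
    g$partition <- factor(as.character(partition), levels = networks7())
  }
  structure(g, class = "binary_graph")
}

rand_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# random partition over k of the 7 labels with no singleton module
rand_partition <- function(n, k = 2L) {
  k <- min(k, n %/% 2L)  # feasibility: every module needs >= 2 nodes
  repeat {
    labels <- sample(networks7()[seq_len(k)], n, replace = TRUE)
    tab <- table(labels)
    if (length(tab) == k && all(tab >= 2L)) return(labels)
  }
}

# symmetric correlation-like matrix with entries drawn from a range
rand_conn <- function(n, lo = -0.5, hi = 0.9) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, lo, hi)
  m <- m + t(m)
  diag(m) <- 1
  conn_matrix(m)
}

# brute-force oracles (independent of the package implementations)

oracle_modularity <- function(adj, labels) {
  two_e <- sum(adj)
  k <- rowSums(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + adj[i, j] - k[i] * k[j] / two_e
      }
    }
  }
  q / two_e
}

oracle_pc <- function(adj, labels, i) {
  k_i <- sum(adj[i, ])
  if (k_i == 0) return(0)
  s <- 0
  for (m in unique(labels)) {
    k_im <- sum(adj[i, labels == m])
    s <- s + (k_im / k_i)^2
  }
  1 - s
}

oracle_wmd <- function(adj, labels, i) {
  idx <- which(labels == labels[i])
  kappa <- vapply(idx, function(j) sum(adj[j, idx]), numeric(1L))
  mu <- mean(kappa)
  sd_pop <- sqrt(mean((kappa - mu)^2))
  if (sd_pop == 0) return(0)
  (sum(adj[i, idx]) - mu) / sd_pop
}

oracle_intra <- function(adj, labels, m) {
  n <- nrow(adj)
  count <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] == 1 && labels[i] == m && labels[j] == m) count <- count + 1
    }
  }
  count
}

oracle_inter <- function(adj, labels, m1, m2) {
  n <- nrow(adj)
  count <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] == 1 &&
          ((labels[i] == m1 && labels[j] == m2) ||
           (labels[i] == m2 && labels[j] == m1))) count <- count + 1
    }
  }
  count
}

# adversarial thalamocortical matrix: every bipartite entry weaker than
# every cortical and thalamo-thalamic entry
adversarial_tc <- function(n_cort = 200L, n_thal = 7L, seed = 7L) {
  set.seed(seed)
  n <- n_cort + n_thal
  m <- matrix(0, n, n)
  ci <- seq_len(n_cort)
  ti <- (n_cort + 1L):n
  cc <- matrix(0, n_cort, n_cort)
  cc[upper.tri(cc)] <- runif(n_cort * (n_cort - 1) / 2, 0.5, 0.9)
  cc <- cc + t(cc)
  tt <- matrix(0, n_thal, n_thal)
  tt[upper.tri(tt)] <- runif(n_thal * (n_thal - 1) / 2, 0.5, 0.9)
  tt <- tt + t(tt)
  bp <- matrix(runif(n_thal * n_cort, 0.05, 0.4), n_thal, n_cort)
  m[ci, ci] <- cc
  m[ti, ti] <- tt
  m[ti, ci] <- bp
  m[ci, ti] <- t(bp)
  diag(m) <- 1
  part <- c(as.character(yeo7_partition(n_cort)), networks7())
  out <- conn_matrix(m, part)
  attr(out, "n_cortical") <- n_cort
  out
}
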