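# Shared fixtures and independent oracles used across the suite.

# Adjusted Rand index between two labelings (mclust's implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small synthetic study used where the full default would be overkill.
small_config <- function(seed = 1, ...) {
  sim_config(n_genes = 400, module_sizes = c(80, 60, 40),
             n_samples_ref = 40, n_samples_test = 15,
             covariate_effect_size = 0, seed = seed, ...)
}

# A random valid signed adjacency matrix (symmetric, [0,1], unit diagonal).
random_adjacency <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * n), n)
  a <- (x + t(x)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  a
}

# O(n^3) triple-loop TOM oracle, straight from the definition.
tom_oracle <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      tom[i, j] <- tom[j, i] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

# Dynamic-programming hypergeometric upper-tail oracle: builds the overlap
# distribution by scanning universe elements one at a time (no closed-form
# binomial coefficients, no phyper).
hyper_upper_dp <- function(N, K, n, q) {
  # state: probability of having drawn d elements so far with s successes,
  # scanning elements in a fixed order; equivalently sample without
  # replacement sequentially
  # f[s+1] over s = overlap count after drawing all n
  # recursive over draws: at draw t (1..n), remaining successes K-s,
  # remaining elements N-(t-1)
  f <- c(1)  # P(s successes after 0 draws)
  for (t in seq_len(n)) {
    s_max <- length(f) - 1
    g <- numeric(min(s_max + 1, K) + 1)
    for (s in 0:s_max) {
      rem <- N - (t - 1)
      p_succ <- (K - s) / rem
      if (f[s + 1] == 0) next
      if (p_succ > 0) g[s + 2] <- g[s + 2] + f[s + 1] * p_succ
      g[s + 1] <- g[s + 1] + f[s + 1] * (1 - p_succ)
    }
    f <- g
  }
  sum(f[(q + 1):length(f)])
}

# Exhaustive subset-enumeration oracle for small universes.
hyper_upper_enum <- function(N, K, n, q) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)  # first K elements are the "set"
  mean(hits >= q)
}
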