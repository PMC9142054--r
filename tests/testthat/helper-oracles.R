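# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: distances are written out longhand, ARI is
# counted over node pairs.

oracle_dist <- function(f, g, metric) {
  if (metric == "euclidean") return(sum((f - g)^2))
  if (metric == "manhattan") return(sum(abs(f - g)))
  nf <- sqrt(sum(f^2)); ng <- sqrt(sum(g^2))
  if (nf == 0 || ng == 0) return(1)
  1 - sum(f * g) / (nf * ng)
}

# Exhaustive Minimum Distance rule: explicit double loop, ties to smallest k.
oracle_assign <- function(y, p, C, L, metric, rho = 1, xi = 1) {
  n <- nrow(y); k <- nrow(C)
  labels <- integer(n)
  for (i in seq_len(n)) {
    d <- numeric(k)
    for (kk in seq_len(k)) {
      d[kk] <- rho * oracle_dist(y[i, ], C[kk, ], metric) +
        xi * oracle_dist(p[i, ], L[kk, ], metric)
    }
    labels[i] <- which(d == min(d))[1L]
  }
  labels
}

# O(N^2) pair-counting ARI: count co-clustered pairs directly.
oracle_ari <- function(s, t) {
  n <- length(s)
  together_both <- 0; together_s <- 0; together_t <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ss <- s[i] == s[j]; tt <- t[i] == t[j]
    together_s <- together_s + ss
    together_t <- together_t + tt
    together_both <- together_both + (ss && tt)
  }
  total <- n * (n - 1) / 2
  expected <- together_s * together_t / total
  denom <- (together_s + together_t) / 2 - expected
  if (denom == 0) return(if (together_both == expected) 0 else 1)
  (together_both - expected) / denom
}

# Random small instance (preprocessed-scale matrices plus K centers).
random_instance <- function(n, k, v, seed) {
  set.seed(seed)
  y <- matrix(rnorm(n * v), n, v)
  p <- matrix(rnorm(n * n), n, n)
  C <- matrix(rnorm(k * v), k, v)
  L <- matrix(rnorm(k * n), k, n)
  list(y = y, p = p, C = C, L = L)
}

random_partition <- function(n, k, seed) {
  set.seed(seed)
  labels <- sample.int(k, n, replace = TRUE)
  labels[sample.int(n, k)] <- seq_len(k)  # ensure every cluster occupied
  labels
}
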