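# Shared fixtures and independent oracles for the test suite.

# Complete, in-range response matrix with every item at a fixed value.
constant_responses <- function(n = 3L, value = 1L,
                               instruments = builtin_instruments()) {
  cols <- unlist(lapply(instruments, function(sp) {
    paste0(sp$prefix, "_", sp$items$item_id)
  }))
  out <- as.data.frame(matrix(value, nrow = n, ncol = length(cols)))
  names(out) <- cols
  # clamp to each item's range (APGAR items are 0-2, others start at 1)
  for (sp in instruments) {
    for (i in seq_len(nrow(sp$items))) {
      cn <- paste0(sp$prefix, "_", sp$items$item_id[i])
      out[[cn]] <- pmin(pmax(value, sp$items$min[i]), sp$items$max[i])
    }
  }
  out
}

# Response matrix with every item at its minimum / maximum.
extreme_responses <- function(n = 2L, which = c("min", "max"),
                              instruments = builtin_instruments()) {
  which <- match.arg(which)
  out <- list()
  for (sp in instruments) {
    for (i in seq_len(nrow(sp$items))) {
      cn <- paste0(sp$prefix, "_", sp$items$item_id[i])
      out[[cn]] <- rep(if (which == "min") sp$items$min[i] else
        sp$items$max[i], n)
    }
  }
  as.data.frame(out)
}

# Random positive-definite correlation matrix.
rand_corr <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(p * (p + 2L)), p + 2L, p)
  stats::cov2cor(crossprod(A) + diag(0.05, p))
}

# Independent brute-force oracles for the psychometric statistics,
# written directly from their textbook definitions (element-wise loops,
# no shared code with the package implementations).
brute_kmo <- function(R) {
  p <- ncol(R)
  S <- solve(R)
  num <- 0
  den_q <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i != j) {
        num <- num + R[i, j]^2
        q_ij <- -S[i, j] / sqrt(S[i, i] * S[j, j])
        den_q <- den_q + q_ij^2
      }
    }
  }
  num / (num + den_q)
}

brute_bartlett_chi2 <- function(R, n) {
  p <- ncol(R)
  -(n - 1 - (2 * p + 5) / 6) * log(det(R))
}

# Brute-force double-loop kernel density sum.
brute_kde <- function(points, h, queries) {
  m <- nrow(queries)
  out <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(nrow(points))) {
      s <- s + stats::dnorm((queries[i, 1] - points[j, 1]) / h[1]) *
        stats::dnorm((queries[i, 2] - points[j, 2]) / h[2])
    }
    out[i] <- s / (nrow(points) * h[1] * h[2])
  }
  out
}
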