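# Independent brute-force oracles used to verify the package implementation.
# These are deliberately written with different algorithms from the package
# (explicit loops, direct enumeration) and must stay independent of it.

kd <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

# O(L * w) window means, one window at a time
oracle_profile <- function(sequence, window = 7) {
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  vapply(seq_len(L - window + 1), function(p) {
    mean(kd[res[p:(p + window - 1)]])
  }, numeric(1))
}

# maximal qualifying runs by explicit position scan
oracle_stretches <- function(values, threshold = 1, min_length = 5) {
  runs <- list()
  i <- 1
  n <- length(values)
  while (i <= n) {
    if (values[i] > threshold) {
      j <- i
      while (j < n && values[j + 1] > threshold) j <- j + 1
      if (j - i + 1 >= min_length) {
        runs[[length(runs) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# exhaustive sign-flip SAM oracle for <= 4 replicates, fixed s0, no missing
# values: enumerates every sign pattern and computes the FDR ratio by
# direct double-loop counting.
oracle_sam <- function(X, s0) {
  n <- nrow(X)
  R <- ncol(X)
  dstat <- function(M) {
    vapply(seq_len(nrow(M)), function(i) {
      x <- M[i, ][!is.na(M[i, ])]
      mean(x) / (sd(x) / sqrt(length(x)) + s0)
    }, numeric(1))
  }
  d <- dstat(X)
  signs <- expand.grid(rep(list(c(1, -1)), R))
  null_d <- matrix(NA_real_, n, nrow(signs))
  for (b in seq_len(nrow(signs))) {
    Xb <- X
    for (j in seq_len(R)) Xb[, j] <- X[, j] * signs[b, j]
    null_d[, b] <- dstat(Xb)
  }
  q <- numeric(n)
  for (i in seq_len(n)) {
    obs <- sum(abs(d) >= abs(d[i]))
    counts <- vapply(seq_len(ncol(null_d)), function(b) {
      sum(abs(null_d[, b]) >= abs(d[i]))
    }, numeric(1))
    q[i] <- min(100 * median(counts) / obs, 100)
  }
  # monotonize exactly as stated: cumulative minimum up the |d| ranking
  ord <- order(abs(d), rownames(X))
  q[ord] <- cummin(q[ord])
  list(d = d, q = q)
}

# hypergeometric tail by direct combinatorial enumeration over the support
oracle_hyper <- function(k, K, n, N, direction = "over") {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  js <- if (direction == "over") {
    if (k > hi) integer(0) else max(k, lo):hi
  } else {
    if (k < lo) integer(0) else lo:min(k, hi)
  }
  if (length(js) == 0) {
    return(0)
  }
  sum(vapply(js, function(j) {
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, numeric(1)))
}

# brute-force UPGMA: recompute the unweighted average inter-cluster
# distance from the original matrix at every step
oracle_upgma <- function(D) {
  ids <- rownames(D)
  clusters <- as.list(ids)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- mean(D[clusters[[a]], clusters[[b]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# tiny deterministic random amino-acid sequence over the full alphabet
random_sequence <- function(length, residues = names(kd)) {
  paste(sample(residues, length, replace = TRUE), collapse = "")
}
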