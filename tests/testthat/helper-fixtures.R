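# Small in-code fixtures shared across test files.

# labeled matrix with given missing entries (linear indices)
toy_response <- function(m = 6, n = 4, missing = integer(0), seed = 42) {
  set.seed(seed)
  R <- matrix(rnorm(m * n, mean = 3), m, n,
              dimnames = list(sprintf("CL%02d", 1:m), sprintf("DR%02d", 1:n)))
  R[missing] <- NA_real_
  R
}

# brute-force pairwise PCC over the explicit overlap index set
pairwise_pcc_oracle <- function(X) {
  p <- ncol(X)
  S <- diag(1, p)
  N <- matrix(0L, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      ok <- which(is.finite(X[, i]) & is.finite(X[, j]))
      N[i, j] <- length(ok)
      if (i == j) next
      if (length(ok) >= 2 && sd(X[ok, i]) > 0 && sd(X[ok, j]) > 0) {
        S[i, j] <- cor(X[ok, i], X[ok, j])
      } else {
        S[i, j] <- 0
      }
    }
  }
  list(values = S, support = N)
}

# independent double-loop construction of the shrunk weight system
# (drug orientation), following the normal-equation definitions directly
weight_system_oracle <- function(u, i, neighbors, R, beta) {
  K <- length(neighbors)
  A_bar <- matrix(0, K, K)
  n_A <- matrix(0, K, K)
  for (a in seq_len(K)) {
    for (b in seq_len(K)) {
      j <- neighbors[a]; k <- neighbors[b]
      vs <- setdiff(which(is.finite(R[, j]) & is.finite(R[, k])), u)
      n_A[a, b] <- length(vs)
      if (length(vs)) A_bar[a, b] <- sum(R[vs, j] * R[vs, k]) / length(vs)
    }
  }
  b_bar <- numeric(K); n_b <- numeric(K)
  for (a in seq_len(K)) {
    j <- neighbors[a]
    vs <- setdiff(which(is.finite(R[, j]) & is.finite(R[, i])), u)
    n_b[a] <- length(vs)
    if (length(vs)) b_bar[a] <- sum(R[vs, j] * R[vs, i]) / length(vs)
  }
  avg <- if (any(n_A > 0)) mean(A_bar[n_A > 0]) else 0
  A_hat <- (n_A * A_bar + beta * avg) / (n_A + beta)
  b_hat <- (n_b * b_bar + beta * avg) / (n_b + beta)
  if (beta == 0) {
    A_hat[n_A == 0] <- 0
    b_hat[n_b == 0] <- 0
  }
  list(A_bar = A_bar, b_bar = b_bar, A_hat = A_hat, b_hat = b_hat, avg = avg)
}

# exhaustive active-set enumeration for small non-negative quadratic
# programs: tries every subset of coordinates as the free set
nnqp_enumeration_oracle <- function(A, b) {
  K <- length(b)
  best <- numeric(K)
  best_obj <- 0
  for (mask in seq_len(2^K) - 1L) {
    free <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0)
    w <- numeric(K)
    if (length(free)) {
      z <- tryCatch(solve(A[free, free, drop = FALSE], b[free]),
                    error = function(e) NULL)
      if (is.null(z) || any(!is.finite(z)) || any(z < 0)) next
      w[free] <- z
    }
    obj <- drop(t(w) %*% A %*% w - 2 * sum(b * w))
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- w
    }
  }
  list(w = best, objective = best_obj)
}

nnqp_objective <- function(A, b, w) drop(t(w) %*% A %*% w - 2 * sum(b * w))
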