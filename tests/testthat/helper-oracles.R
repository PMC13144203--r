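# Independent reference implementations used as oracles.  These are written
# as plainly as possible (dense double loops, generic first-order solvers)
# and deliberately share no code with the package internals they check.

# Dense double-loop Poisson NMF objective: sum_ij lambda - x log lambda.
dense_pnmf_objective <- function(X, H, W) {
  X <- as.matrix(X)
  total <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X))) {
      lam <- sum(H[i, ] * W[j, ])
      total <- total + lam
      if (X[i, j] > 0)
        total <- total - X[i, j] * log(lam)
    }
  total
}

dense_mtm_objective <- function(X, L, F) {
  X <- as.matrix(X)
  total <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      if (X[i, j] > 0)
        total <- total - X[i, j] * log(sum(L[i, ] * F[j, ]))
  total
}

dense_poisreg_nll <- function(A, y, b) {
  total <- 0
  for (i in seq_along(y)) {
    mu <- sum(A[i, ] * b)
    total <- total + mu
    if (y[i] > 0)
      total <- total - y[i] * log(mu)
  }
  total
}

# Projected-gradient solver for the non-negative Poisson regression, with
# Armijo backtracking, run to a tight stationarity tolerance.  Serves as the
# ground-truth optimizer for the inner subproblem.
pg_poisreg <- function(A, y, b0 = NULL, tol = 1e-10, maxiter = 50000) {
  K <- ncol(A)
  if (is.null(b0))
    b0 <- rep(mean(y) / max(mean(rowSums(A)), 1e-12), K)
  b <- pmax(b0, 1e-12)
  nll <- function(b) {
    mu <- drop(A %*% b)
    sum(mu) - sum(y[y > 0] * log(mu[y > 0]))
  }
  grad <- function(b) {
    mu <- drop(A %*% b)
    r <- ifelse(mu > 0, y / mu, 0)
    colSums(A) - drop(crossprod(A, r))
  }
  f <- nll(b)
  step <- 1
  for (it in seq_len(maxiter)) {
    g <- grad(b)
    # projected-gradient stationarity measure
    pg <- ifelse(b > 1e-10, abs(g), pmax(0, -g))
    if (max(pg) < tol)
      break
    repeat {
      b_new <- pmax(b - step * g, 0)
      f_new <- nll(b_new)
      if (is.finite(f_new) &&
          f_new <= f - 1e-4 * sum(g * (b - b_new)))
        break
      step <- step / 2
      if (step < 1e-18)
        break
    }
    if (step < 1e-18)
      break
    b <- b_new
    f <- f_new
    step <- min(step * 2, 1e4)
  }
  list(b = b, value = f)
}

# All permutations of 1..K, generated recursively (oracle for topic
# matching; independent of the package's enumeration).
perms_oracle <- function(K) {
  if (K == 1)
    return(matrix(1L, 1, 1))
  sub <- perms_oracle(K - 1)
  out <- NULL
  for (r in seq_len(nrow(sub)))
    for (pos in seq_len(K)) {
      p <- append(sub[r, ], K, after = pos - 1)
      out <- rbind(out, p)
    }
  out
}

# Best-permutation cosine matching by exhaustive search.
brute_match <- function(F_est, F_true) {
  K <- ncol(F_true)
  cs <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  P <- perms_oracle(K)
  best <- -Inf
  best_p <- NULL
  for (r in seq_len(nrow(P))) {
    p <- P[r, ]
    sc <- sum(vapply(seq_len(K),
                     function(k) cs(F_true[, k], F_est[, p[k]]),
                     numeric(1)))
    if (sc > best) {
      best <- sc
      best_p <- p
    }
  }
  list(perm = best_p,
       similarity = vapply(seq_len(K),
                           function(k) cs(F_true[, k], F_est[, best_p[k]]),
                           numeric(1)))
}

# Random strictly-positive factor pair for identity/property tests.
random_hw <- function(n, m, K, seed) {
  set.seed(seed)
  list(H = matrix(runif(n * K) + 0.05, n, K),
       W = matrix(runif(m * K) + 0.05, m, K))
}

# Random well-conditioned Poisson regression problem (strictly positive
# design, counts generated from the model).
random_poisreg <- function(n = 20, K = 3, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * K, 0.5, 1.5), n, K)
  b_true <- runif(K, 0.5, 1.5)
  y <- rpois(n, drop(A %*% b_true))
  list(A = A, y = y, b_true = b_true)
}
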