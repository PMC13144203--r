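# Synthetic-data generators with known ground truth for both generative
# models, and topic matching for recovery tests.  The topic-model generator
# builds identifiability-friendly truth: each topic gets a disjoint set of
# "anchor" terms carrying elevated mass, with the separation parameter
# controlling both the number of anchors and the fraction of each topic's
# mass concentrated on them.

rdirichlet1 <- function(d) {
  g <- stats::rgamma(d, shape = 1)
  g / sum(g)
}

#' Simulate counts from the multinomial topic model
#'
#' Draws ground-truth parameters and counts from the generative model: each
#' topic distribution (column of F) is a mixture of a Dirichlet(1) draw over
#' all \code{m} terms and a Dirichlet(1) draw over that topic's disjoint
#' anchor set of \code{ceiling(separation * m / K)} terms, with mixture
#' weight \code{separation} on the anchors (so \code{separation = 0} gives
#' unstructured topics and \code{separation = 1} gives disjoint supports);
#' topic proportions (rows of L) are Dirichlet(1); each document's counts
#' are multinomial with size \code{doc_size} and probabilities
#' \eqn{(LF^T)_i}.
#'
#' @param n Number of documents (rows), at least K.
#' @param m Number of terms (columns), at least K.
#' @param K Number of topics, at least 2.
#' @param doc_size Document size(s): a single integer or a length-n vector
#'   of row totals, all at least 1.
#' @param separation Topic separation in [0, 1].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#'
#' @return A list with components \code{X} (sparse count matrix, row sums
#'   equal to \code{doc_size} exactly), \code{L} (n x K true topic
#'   proportions) and \code{F} (m x K true topic distributions).
#'
#' @importFrom stats rgamma rmultinom
#' @export
simulate_topic_data <- function(n, m, K, doc_size = 100, separation = 0.8,
                                seed = 1) {
  stopifnot(K >= 2, n >= K, m >= K, separation >= 0, separation <= 1)
  doc_size <- rep_len(doc_size, n)
  if (any(doc_size < 1))
    stop("all document sizes must be at least 1")
  set.seed(seed)
  n_anchor <- ceiling(separation * m / K)
  if (n_anchor * K > m)
    n_anchor <- floor(m / K)
  F <- matrix(0, m, K)
  for (k in seq_len(K)) {
    base <- rdirichlet1(m)
    if (n_anchor > 0) {
      anchors <- ((k - 1) * n_anchor + 1):(k * n_anchor)
      spike <- numeric(m)
      spike[anchors] <- rdirichlet1(n_anchor)
      F[, k] <- (1 - separation) * base + separation * spike
    } else
      F[, k] <- base
  }
  L <- t(vapply(seq_len(n), function(i) rdirichlet1(K), numeric(K)))
  Pi <- L %*% t(F)
  X <- vapply(seq_len(n),
              function(i) drop(rmultinom(1, doc_size[i], Pi[i, ])),
              numeric(m))
  X <- as_count_matrix(t(X))
  list(X = X, L = L, F = F)
}

#' Simulate counts from the Poisson NMF model
#'
#' Draws loadings and factors elementwise from a standard exponential
#' (gamma with shape 1), rescales both so that the mean Poisson rate equals
#' \code{scale}, and draws each count \eqn{x_{ij} \sim
#' \mathrm{Pois}((HW^T)_{ij})}.
#'
#' @inheritParams simulate_topic_data
#' @param scale Target mean of the Poisson rates, strictly positive.
#'
#' @return A list with components \code{X} (sparse count matrix), \code{H}
#'   (n x K) and \code{W} (m x K).
#'
#' @importFrom stats rpois
#' @export
simulate_pnmf_data <- function(n, m, K, scale = 1, seed = 1) {
  stopifnot(K >= 2, n >= K, m >= K)
  if (scale <= 0)
    stop("scale must be strictly positive")
  set.seed(seed)
  H <- matrix(rgamma(n * K, shape = 1), n, K)
  W <- matrix(rgamma(m * K, shape = 1), m, K)
  # E[lambda] = K E[h] E[w] = K for unit-scale draws
  sc <- sqrt(scale / K)
  H <- H * sc
  W <- W * sc
  lam <- H %*% t(W)
  X <- matrix(rpois(n * m, lam), n, m)
  if (all(X == 0))
    stop("simulated matrix is all zero; increase scale or dimensions")
  list(X = as_count_matrix(X), H = H, W = W)
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    return(0)
  sum(x * y) / (nx * ny)
}

#' Match estimated topics to ground truth
#'
#' Topic order is not identifiable, so recovery is assessed after matching
#' estimated topic distributions to the truth. For K up to 8 the assignment
#' maximizing total column-wise cosine similarity is found by enumerating
#' all permutations; beyond that a greedy best-pair-first assignment is
#' used.
#'
#' @param F_est,F_true m x K matrices of estimated and true topic
#'   distributions (same shape).
#'
#' @return A list with components \code{perm} (permutation such that column
#'   \code{perm[k]} of \code{F_est} matches column k of \code{F_true}) and
#'   \code{similarity} (the K matched cosine similarities, in true-topic
#'   order).
#'
#' @export
match_topics <- function(F_est, F_true) {
  F_est <- as.matrix(F_est)
  F_true <- as.matrix(F_true)
  if (!all(dim(F_est) == dim(F_true)))
    stop("estimated and true factor matrices must have the same shape")
  K <- ncol(F_true)
  S <- matrix(0, K, K)     # S[k_true, k_est]
  for (a in seq_len(K))
    for (b in seq_len(K))
      S[a, b] <- cosine_sim(F_true[, a], F_est[, b])
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- vapply(perms,
                     function(p) sum(S[cbind(seq_len(K), p)]), numeric(1))
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    Sw <- S
    for (rep in seq_len(K)) {
      idx <- arrayInd(which.max(Sw), dim(Sw))
      perm[idx[1]] <- idx[2]
      Sw[idx[1], ] <- -Inf
      Sw[, idx[2]] <- -Inf
    }
  }
  list(perm = perm, similarity = S[cbind(seq_len(K), perm)])
}

all_permutations <- function(K) {
  if (K == 1)
    return(list(1L))
  sub <- all_permutations(K - 1)
  out <- vector("list", K * length(sub))
  idx <- 1
  for (p in sub)
    for (pos in seq_len(K)) {
      out[[idx]] <- append(p, K, after = pos - 1)
      idx <- idx + 1
    }
  out
}
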