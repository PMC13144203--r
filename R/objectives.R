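# Objective functions and log-likelihoods for the two equivalent models:
#
#   Poisson NMF:      x_ij ~ Pois(lambda_ij),  Lambda = H W'
#   multinomial:      row i ~ Multin(t_i; pi_i),  Pi = L F'
#
# The fitted objective is the negative Poisson log-likelihood without
# constants, l(X;H,W) = sum_ij lambda_ij - x_ij log lambda_ij.  All
# evaluations cost O(nnz(X) + (n+m)K): the linear term is the dot product of
# column sums of H and W, and logs are taken only at stored nonzeros.

# Numerical floor applied to all fitted parameters; prevents log(0) and
# division by zero while perturbing objectives at the 1e-15 level.
eps_floor <- 1e-15

# lambda (or pi) evaluated at the stored nonzeros of X only.
lambda_at_nonzeros <- function(trip, H, W) {
  rowSums(H[trip$i, , drop = FALSE] * W[trip$j, , drop = FALSE])
}

check_positive_rates <- function(trip, lam, what = "lambda") {
  bad <- which(lam <= 0 & trip$x > 0)
  if (length(bad) > 0)
    stop(sprintf("%s is zero at nonzero count (%d, %d): objective is infinite",
                 what, trip$i[bad[1]], trip$j[bad[1]]))
}

#' Poisson NMF objective
#'
#' The negative Poisson log-likelihood without constants,
#' \deqn{\ell(X; H, W) = \sum_{ij} \lambda_{ij} - x_{ij} \log \lambda_{ij},
#'   \quad \Lambda = HW^T,}
#' the quantity minimized by \code{\link{fit_poisson_nmf}}. Cost is
#' proportional to the number of nonzeros of \code{X}.
#'
#' @param X Count matrix (n x m).
#' @param H Non-negative n x K loadings matrix.
#' @param W Non-negative m x K factors matrix.
#'
#' @return The objective value (a single number).
#'
#' @examples
#' X <- as_count_matrix(matrix(2))
#' pnmf_objective(X, matrix(1, 1, 2), matrix(1, 1, 2))  # 2 - 2 log 2
#'
#' @export
pnmf_objective <- function(X, H, W) {
  X <- as_count_matrix(X)
  trip <- count_triplets(X)
  lam <- lambda_at_nonzeros(trip, H, W)
  check_positive_rates(trip, lam)
  sum(colSums(H) * colSums(W)) - sum(trip$x * log(lam))
}

#' Multinomial topic model objective
#'
#' The negative multinomial log-likelihood without constants,
#' \eqn{\phi(X; L, F) = -\sum_{ij} x_{ij} \log \pi_{ij}} with
#' \eqn{\Pi = LF^T}.
#'
#' @param X Count matrix.
#' @param L Row-stochastic n x K topic-proportions matrix.
#' @param F Column-stochastic m x K topic-distributions matrix.
#'
#' @return The objective value.
#'
#' @export
mtm_objective <- function(X, L, F) {
  X <- as_count_matrix(X)
  trip <- count_triplets(X)
  pi_v <- lambda_at_nonzeros(trip, L, F)
  check_positive_rates(trip, pi_v, "pi")
  -sum(trip$x * log(pi_v))
}

#' Augmented topic model objective
#'
#' Adds to \code{\link{mtm_objective}} the document-scale term
#' \eqn{\psi(X; s) = \sum_i s_i - t_i \log s_i}, which is uniquely minimized
#' at \eqn{s = t} (the observed row sums). Minimizing the augmented
#' objective over (L, F, s) is the exact simplex-parameterized twin of the
#' Poisson NMF problem.
#'
#' @param X Count matrix.
#' @inheritParams mtm_objective
#' @param s Positive vector of document scales, length n.
#'
#' @return The augmented objective value.
#'
#' @export
augmented_objective <- function(X, L, F, s) {
  X <- as_count_matrix(X)
  if (any(s <= 0))
    stop("all document scales s must be positive")
  t <- Matrix::rowSums(X)
  mtm_objective(X, L, F) + sum(s) - sum(t * log(s))
}

#' Full log-likelihoods for both models
#'
#' Unlike the objectives, these include all constant terms: the Poisson
#' log-likelihood sums the Poisson log pmf over every cell (zero cells
#' contribute \eqn{-\lambda_{ij}}, aggregated in closed form), and the
#' multinomial log-likelihood includes the per-row multinomial coefficient.
#' They satisfy the exact identity tested by
#' \code{\link{lemma_identity_gap}}.
#'
#' @inheritParams pnmf_objective
#'
#' @return The log-likelihood (a single number).
#'
#' @export
pnmf_loglik <- function(X, H, W) {
  X <- as_count_matrix(X)
  trip <- count_triplets(X)
  lam <- lambda_at_nonzeros(trip, H, W)
  check_positive_rates(trip, lam)
  sum(trip$x * log(lam)) - sum(colSums(H) * colSums(W)) -
    sum(lgamma(trip$x + 1))
}

#' @rdname pnmf_loglik
#' @inheritParams mtm_objective
#' @export
mtm_loglik <- function(X, L, F) {
  X <- as_count_matrix(X)
  trip <- count_triplets(X)
  pi_v <- lambda_at_nonzeros(trip, L, F)
  check_positive_rates(trip, pi_v, "pi")
  t <- Matrix::rowSums(X)
  sum(lgamma(t + 1)) - sum(lgamma(trip$x + 1)) + sum(trip$x * log(pi_v))
}

#' Residual of the Poisson-multinomial likelihood identity
#'
#' For any strictly positive (H, W) and the corresponding topic-model
#' parameters (L, F, s, u) obtained from \code{\link{pnmf_to_mtm}}, the
#' Poisson NMF likelihood factorizes exactly as the multinomial likelihood
#' times independent Poisson likelihoods for the row totals:
#' \deqn{\log p_{PNMF}(X | H, W) = \log p_{MTM}(X | L, F) +
#'       \sum_i \log \mathrm{Pois}(t_i; s_i).}
#' This function returns the numerical residual of that identity, which
#' should be zero up to floating-point error.
#'
#' @inheritParams pnmf_objective
#'
#' @return The residual (signed).
#'
#' @importFrom stats dpois
#' @export
lemma_identity_gap <- function(X, H, W) {
  X <- as_count_matrix(X)
  map <- pnmf_to_mtm(H, W)
  t <- Matrix::rowSums(X)
  pnmf_loglik(X, H, W) - mtm_loglik(X, map$L, map$F) -
    sum(dpois(t, map$s, log = TRUE))
}

#' Penalty hyperparameters for MAP estimation
#'
#' Builds the penalty parameters for the penalized (MAP) objectives: a
#' Dirichlet-type shape matrix \code{a} (m x K, entries >= 1) acting on the
#' factors F (equivalently W) and a gamma-type rate vector \code{b}
#' (length K, entries >= 0) acting on W. Scalars are broadcast.
#' \code{a = 1, b = 0} recovers the unpenalized objectives exactly.
#'
#' @param a Scalar or m x K matrix of shape parameters, all >= 1.
#' @param b Scalar or length-K vector of rate parameters, all >= 0.
#' @param m,K Dimensions used to broadcast scalar inputs.
#'
#' @return An object of class \code{"penalty_params"}.
#'
#' @export
penalty_params <- function(a = 1, b = 0, m, K) {
  if (length(a) == 1)
    a <- matrix(a, m, K)
  if (length(b) == 1)
    b <- rep(b, K)
  a <- as.matrix(a)
  stopifnot(nrow(a) == m, ncol(a) == K, length(b) == K)
  if (any(a < 1))
    stop("all shape parameters a must be >= 1")
  if (any(b < 0))
    stop("all rate parameters b must be >= 0")
  structure(list(a = a, b = b), class = "penalty_params")
}

# Penalty restricted to one factor row j (a K-vector problem), as used by the
# inner Poisson regression solvers. Returns NULL when pen is NULL.
penalty_for_row <- function(pen, j) {
  if (is.null(pen))
    return(NULL)
  list(a = pen$a[j, ], b = pen$b)
}

rho_pnmf <- function(W, pen) {
  am1 <- pen$a - 1
  logs <- sum(am1[am1 > 0] * log(W)[am1 > 0])
  if (any(am1 > 0 & W <= 0))
    stop("zero factor entry with shape parameter a > 1: penalty is infinite")
  -logs + sum(sweep(W, 2, pen$b, "*"))
}

rho_mtm <- function(F, pen) {
  am1 <- pen$a - 1
  if (any(am1 > 0 & F <= 0))
    stop("zero factor entry with shape parameter a > 1: penalty is infinite")
  -sum(am1[am1 > 0] * log(F)[am1 > 0])
}

#' Penalized (MAP) objectives
#'
#' The penalized Poisson NMF objective is
#' \eqn{\ell^* = \ell - \sum_{jk} (a_{jk}-1)\log w_{jk} + \sum_{jk} b_k w_{jk}}
#' and the penalized topic model objective is
#' \eqn{\phi^* = \phi - \sum_{jk} (a_{jk}-1)\log f_{jk}}. Minimizing them
#' corresponds to MAP estimation with gamma priors on W (resp. Dirichlet
#' priors on the columns of F) and uniform priors on the loadings; the two
#' penalized problems are equivalent under the same change of variables as
#' the unpenalized ones.
#'
#' @inheritParams pnmf_objective
#' @inheritParams mtm_objective
#' @param pen A \code{\link{penalty_params}} object, or \code{NULL} for no
#'   penalty.
#'
#' @return The penalized objective value.
#'
#' @export
penalized_pnmf_objective <- function(X, H, W, pen) {
  val <- pnmf_objective(X, H, W)
  if (is.null(pen))
    return(val)
  val + rho_pnmf(W, pen)
}

#' @rdname penalized_pnmf_objective
#' @export
penalized_mtm_objective <- function(X, L, F, pen) {
  val <- mtm_objective(X, L, F)
  if (is.null(pen))
    return(val)
  val + rho_mtm(F, pen)
}
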