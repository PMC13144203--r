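# Block updates for the alternating driver.  Updating the whole factors
# block W given H consists of m independent Poisson regressions (one per
# column of X) sharing the design H; by symmetry, updating H given W is the
# same computation on the transposed data.  Because the subproblems are
# independent, both inner solvers vectorize across subproblems: one EM step
# for every subproblem at once is a multiplicative update of the block, and
# a CD sweep updates coordinate k of every subproblem simultaneously.  All
# per-entry work touches only the stored nonzeros of X.

#' @importFrom Matrix sparseMatrix crossprod
NULL

# Sum vals within groups given by j (1..m), returning a dense length-m
# vector with zeros for empty groups.
group_sum <- function(vals, j, m) {
  out <- numeric(m)
  tt <- rowsum(vals, j)
  out[as.integer(rownames(tt))] <- tt
  out
}

# One or more EM steps applied to every subproblem of a block.  trip holds
# the triplets of X oriented so that subproblems are indexed by trip$j and
# the design D (n x K) by trip$i; Tmat (m x K) is the block being updated.
block_em <- function(trip, D, Tmat, inner_iter, pen = NULL) {
  dc <- colSums(D)
  den <- if (is.null(pen)) dc else dc + pen$b
  for (it in seq_len(inner_iter)) {
    lam <- lambda_at_nonzeros(trip, D, Tmat)
    check_positive_rates(trip, lam)
    P <- sparseMatrix(i = trip$i, j = trip$j, x = trip$x / lam,
                      dims = c(trip$n, trip$m))
    num <- Tmat * as.matrix(crossprod(P, D))
    if (!is.null(pen))
      num <- num + (pen$a - 1)
    upd <- sweep(num, 2, den, "/")
    if (any(den <= 0))           # dead topic: no support in the design
      upd[, den <= 0] <- eps_floor
    Tmat <- pmax(upd, eps_floor)
  }
  Tmat
}

# Cyclic CD sweeps applied to every subproblem of a block, coordinate k of
# all subproblems at once, with mu (lambda at the nonzeros) updated
# incrementally after each coordinate.
block_cd <- function(trip, D, Tmat, inner_iter, pen = NULL) {
  K <- ncol(Tmat)
  dc <- colSums(D)
  lam <- lambda_at_nonzeros(trip, D, Tmat)
  check_positive_rates(trip, lam)
  flat <- 0L
  for (it in seq_len(inner_iter)) {
    for (k in seq_len(K)) {
      dk <- D[trip$i, k]
      g <- dc[k] - group_sum(dk * trip$x / lam, trip$j, trip$m)
      q <- group_sum(trip$x * dk^2 / lam^2, trip$j, trip$m)
      wk <- Tmat[, k]
      if (!is.null(pen)) {
        am1 <- pen$a[, k] - 1
        g <- g + pen$b[k] - am1 / wk
        q <- q + am1 / wk^2
      }
      degen <- q < 1e-300
      new_k <- wk
      ok <- !degen
      new_k[ok] <- pmax(eps_floor, wk[ok] - g[ok] / q[ok])
      if (any(degen)) {
        # flat or boundary-optimal coordinates: with non-negative gradient
        # the floor maximizes the likelihood (a dead topic is parked there);
        # a negative gradient with no curvature is left alone
        up <- degen & g >= 0
        new_k[up] <- eps_floor
        flat <- flat + sum(degen & g < 0)
      }
      lam <- lam + dk * (new_k - wk)[trip$j]
      Tmat[, k] <- new_k
    }
  }
  if (flat > 0)
    warning(flat, " coordinate(s) had vanishing curvature and non-positive ",
            "gradient; left unchanged")
  Tmat
}

#' Update one factor block of a Poisson NMF fit
#'
#' Solves, from their current values, the independent additive Poisson
#' regressions that make up one block update: with \code{which = "factors"}
#' each column of \code{X} yields one subproblem with design \code{H} and the
#' corresponding row of \code{W} as coefficients; with
#' \code{which = "loadings"} the roles are transposed. The subproblems are
#' independent, so the result does not depend on the order in which they are
#' solved.
#'
#' @inheritParams pnmf_objective
#' @param which Which block to update, \code{"factors"} (W) or
#'   \code{"loadings"} (H).
#' @param method Inner solver, \code{"cd"} or \code{"em"}.
#' @param inner_iter Number of inner updates (EM steps or CD sweeps) applied
#'   to each subproblem.
#' @param pen Optional \code{\link{penalty_params}}; applies to the factors
#'   block only (uniform prior on the loadings).
#'
#' @return The updated block (same shape as the block selected by
#'   \code{which}).
#'
#' @export
update_block <- function(X, H, W, which = c("factors", "loadings"),
                         method = c("cd", "em"), inner_iter = 4,
                         pen = NULL) {
  which <- match.arg(which)
  method <- match.arg(method)
  X <- as_count_matrix(X)
  step <- if (method == "em") block_em else block_cd
  if (which == "factors") {
    trip <- count_triplets(X)
    step(trip, as.matrix(H), as.matrix(W), inner_iter, pen)
  } else {
    trip <- count_triplets(Matrix::t(X))
    step(trip, as.matrix(W), as.matrix(H), inner_iter, pen = NULL)
  }
}

#' Multiplicative updates for Poisson NMF (dense reference)
#'
#' One round of the classic multiplicative updates:
#' \deqn{h_{ik} \leftarrow h_{ik}
#'   \frac{\sum_j x_{ij} w_{jk}/\lambda_{ij}}{\sum_j w_{jk}}}
#' using the current W, then the symmetric update of W using the updated H.
#' This is a deliberately plain dense implementation kept as an independent
#' reference: one EM outer iteration of \code{\link{fit_poisson_nmf}} with
#' \code{inner_iter = 1} reproduces it elementwise.
#'
#' @inheritParams pnmf_objective
#'
#' @return A list with the updated matrices \code{H} and \code{W}.
#'
#' @export
multiplicative_update <- function(X, H, W) {
  Xd <- as.matrix(as_count_matrix(X))
  H <- as.matrix(H)
  W <- as.matrix(W)
  ratio <- function(Lam) {
    if (any(Lam <= 0 & Xd > 0))
      stop("lambda is zero at a nonzero count")
    ifelse(Lam > 0, Xd / Lam, 0)
  }
  R <- ratio(H %*% t(W))
  H <- pmax(H * (R %*% W) / rep(colSums(W), each = nrow(H)), eps_floor)
  R <- ratio(H %*% t(W))
  W <- pmax(W * (t(R) %*% H) / rep(colSums(H), each = nrow(W)), eps_floor)
  list(H = H, W = W)
}

#' Extrapolated candidate point
#'
#' The momentum step used by the acceleration scheme: elementwise
#' \code{max(1e-15, current + beta * (current - previous))}.
#'
#' @param current,previous Conformable parameter matrices.
#' @param beta Extrapolation step size in \code{[0, 1)}.
#'
#' @return The candidate matrix.
#'
#' @export
extrapolated_iterate <- function(current, previous, beta) {
  stopifnot(beta >= 0, beta < 1 + 1e-12)
  pmax(current + beta * (current - previous), eps_floor)
}

#' First-order optimality residual of a Poisson NMF fit
#'
#' Computes the KKT residual of the (optionally penalized) Poisson NMF
#' objective over all entries of H and W: at interior entries the gradient
#' must vanish, at floored entries it must be non-negative; the residual is
#' the largest violation.
#'
#' @inheritParams pnmf_objective
#' @param pen Optional \code{\link{penalty_params}} (applies to W).
#'
#' @return The residual (a single non-negative number).
#'
#' @export
pnmf_kkt_residual <- function(X, H, W, pen = NULL) {
  X <- as_count_matrix(X)
  trip <- count_triplets(X)
  H <- as.matrix(H)
  W <- as.matrix(W)
  lam <- lambda_at_nonzeros(trip, H, W)
  check_positive_rates(trip, lam)
  P <- sparseMatrix(i = trip$i, j = trip$j, x = trip$x / lam,
                    dims = c(trip$n, trip$m))
  GH <- rep(colSums(W), each = nrow(H)) - as.matrix(P %*% W)
  GW <- rep(colSums(H), each = nrow(W)) - as.matrix(crossprod(P, H))
  if (!is.null(pen))
    GW <- GW + rep(pen$b, each = nrow(W)) - (pen$a - 1) / W
  resid <- function(par, g) {
    interior <- par > eps_kkt
    max(c(abs(g[interior]), pmax(0, -g[!interior]), 0))
  }
  max(resid(H, GH), resid(W, GW))
}
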