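# The change of variables between the Poisson NMF parameterization (H, W)
# and the topic-model parameterization (L, F, s, u).  Forward map: normalize
# the columns of W (giving F and topic scales u), then the rows of
# H diag(u) (giving L and document scales s).  Inverse: W = F diag(u),
# H = diag(s) L diag(u)^-1.  The map satisfies lambda_ij = s_i pi_ij
# exactly, which is the computational content of the likelihood identity.

#' Normalize the rows or columns of a non-negative matrix
#'
#' \code{normalize_rows} rescales each row of \code{A} to sum to one and
#' returns the row sums; \code{normalize_cols} does the same for columns.
#' Together they implement the two halves of the parameterization map.
#'
#' @param A A non-negative matrix; every row (resp. column) must contain at
#'   least one positive entry.
#'
#' @return A list with components \code{B} (the normalized matrix) and
#'   \code{y} (the row or column sums), so that \code{diag(y) \%*\% B}
#'   (resp. \code{B \%*\% diag(y)}) reconstructs \code{A}.
#'
#' @export
normalize_rows <- function(A) {
  A <- as.matrix(A)
  y <- rowSums(A)
  if (any(y <= 0))
    stop("row ", which(y <= 0)[1], " has no positive entries; cannot normalize")
  list(B = A / y, y = y)
}

#' @rdname normalize_rows
#' @export
normalize_cols <- function(A) {
  A <- as.matrix(A)
  y <- colSums(A)
  if (any(y <= 0))
    stop("column ", which(y <= 0)[1],
         " has no positive entries; cannot normalize")
  list(B = sweep(A, 2, y, "/"), y = y)
}

#' Convert Poisson NMF parameters to topic-model parameters
#'
#' Maps non-negative matrices (H, W) to the equivalent simplex-constrained
#' parameters: column-stochastic factors F with topic scales u (the column
#' sums of W), and row-stochastic loadings L with document scales s (the row
#' sums of \eqn{H \mathrm{diag}(u)}). The map is exact:
#' \eqn{\lambda_{ij} = s_i \pi_{ij}} with \eqn{\Lambda = HW^T},
#' \eqn{\Pi = LF^T}.
#'
#' @param H Non-negative n x K loadings matrix; every row of
#'   \eqn{H \mathrm{diag}(u)} must have a positive entry.
#' @param W Non-negative m x K factors matrix; every column must have a
#'   positive entry.
#'
#' @return A list with components \code{L}, \code{F}, \code{s}, \code{u}.
#'
#' @seealso \code{\link{mtm_to_pnmf}} for the inverse.
#'
#' @examples
#' p <- pnmf_to_mtm(H = matrix(c(1, 2), 1, 2), W = diag(c(2, 4)))
#' p$s * p$L %*% t(p$F)   # equals H %*% t(W)
#'
#' @export
pnmf_to_mtm <- function(H, W) {
  nc <- normalize_cols(W)
  nr <- normalize_rows(sweep(as.matrix(H), 2, nc$y, "*"))
  list(L = nr$B, F = nc$B, s = nr$y, u = nc$y)
}

#' Convert topic-model parameters to Poisson NMF parameters
#'
#' The inverse of \code{\link{pnmf_to_mtm}}:
#' \eqn{W = F \mathrm{diag}(u)}, \eqn{H = \mathrm{diag}(s) L \mathrm{diag}(u)^{-1}}.
#'
#' @param L Row-stochastic n x K matrix.
#' @param F Column-stochastic m x K matrix.
#' @param s Positive length-n vector of document scales.
#' @param u Positive length-K vector of topic scales.
#'
#' @return A list with components \code{H} and \code{W}.
#'
#' @export
mtm_to_pnmf <- function(L, F, s, u) {
  if (any(s <= 0) || any(u <= 0))
    stop("scales s and u must be strictly positive")
  list(H = sweep(as.matrix(L) * s, 2, u, "/"),
       W = sweep(as.matrix(F), 2, u, "*"))
}
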