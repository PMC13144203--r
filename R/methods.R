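# S3 methods for the two fit classes.

#' @export
print.poisson_nmf_fit <- function(x, ...) {
  cat(sprintf("Poisson NMF fit (k = %d, %s solver%s)\n", x$k, x$method,
              if (isTRUE(x$extrapolate)) ", extrapolated" else ""))
  cat(sprintf("  loadings H: %d x %d, factors W: %d x %d\n",
              nrow(x$H), ncol(x$H), nrow(x$W), ncol(x$W)))
  cat(sprintf("  objective: %.8g   log-likelihood: %.8g\n",
              x$objective, x$loglik))
  cat(sprintf("  KKT residual: %.3g   outer iterations: %d\n",
              x$kkt, max(x$trace$iter)))
  invisible(x)
}

#' @export
print.topic_model_fit <- function(x, ...) {
  cat(sprintf("Multinomial topic model fit (k = %d)\n", x$k))
  cat(sprintf("  topic proportions L: %d x %d, topic distributions F: %d x %d\n",
              nrow(x$L), ncol(x$L), nrow(x$F), ncol(x$F)))
  cat(sprintf("  objective: %.8g   log-likelihood: %.8g\n",
              x$objective, x$loglik))
  invisible(x)
}

#' @export
summary.poisson_nmf_fit <- function(object, ...) {
  print(object)
  tr <- progress_report(object)
  cat(sprintf("  objective decrease over trace: %.6g\n",
              tr$objective[1] - min(tr$objective)))
  if (any(tr$extrapolated))
    cat(sprintf("  extrapolated iterations: %d (final beta %.3g)\n",
                sum(tr$extrapolated), tr$beta[nrow(tr)]))
  invisible(object)
}

#' @export
summary.topic_model_fit <- function(object, ...) {
  print(object)
  top <- apply(object$L, 1, which.max)
  cat("  documents per dominant topic:",
      paste(tabulate(top, object$k), collapse = " "), "\n")
  cat(sprintf("  document scales s: range [%.4g, %.4g]\n",
              min(object$s), max(object$s)))
  invisible(object)
}

#' @export
coef.poisson_nmf_fit <- function(object, ...) object$W

#' @export
coef.topic_model_fit <- function(object, ...) object$F

#' @export
logLik.poisson_nmf_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- length(object$H) + length(object$W)
  class(val) <- "logLik"
  val
}

#' @export
logLik.topic_model_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- (nrow(object$L) - 1) * (ncol(object$L)) +
    (nrow(object$F) - 1) * ncol(object$F)
  class(val) <- "logLik"
  val
}

#' @export
fitted.poisson_nmf_fit <- function(object, ...)
  object$H %*% t(object$W)

#' @export
fitted.topic_model_fit <- function(object, ...)
  object$L %*% t(object$F)

#' Pearson residuals of a Poisson NMF fit
#'
#' @param object A \code{"poisson_nmf_fit"}.
#' @param X The count matrix the model was fitted to.
#' @param ... Unused.
#'
#' @return A dense matrix of \eqn{(x_{ij} - \lambda_{ij})/\sqrt{\lambda_{ij}}}.
#'
#' @export
residuals.poisson_nmf_fit <- function(object, X, ...) {
  lam <- fitted(object)
  (as.matrix(as_count_matrix(X)) - lam) / sqrt(pmax(lam, eps_floor))
}

#' Plot optimization progress
#'
#' Plots the distance of each outer iteration's objective from the best
#' objective in the trace, on a log scale.
#'
#' @param x A fit object with a trace.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#'
#' @importFrom graphics plot points legend
#' @export
plot.poisson_nmf_fit <- function(x, ...) {
  tr <- progress_report(x)
  d <- pmax(tr$delta, 1e-12)
  plot(tr$iter, d, log = "y", type = "l", xlab = "outer iteration",
       ylab = "objective - best objective", ...)
  if (any(tr$extrapolated))
    points(tr$iter[tr$extrapolated], d[tr$extrapolated], pch = 20)
  invisible(x)
}

#' @export
plot.topic_model_fit <- function(x, ...)
  plot.poisson_nmf_fit(list(trace = x$trace), ...)

#' Simulate counts from a fitted topic model
#'
#' Draws multinomial counts with the fitted probabilities \eqn{LF^T} and the
#' fitted document scales rounded to integers (or sizes supplied via
#' \code{doc_size}).
#'
#' @param object A \code{"topic_model_fit"}.
#' @param nsim Number of data sets to draw.
#' @param seed Integer seed.
#' @param doc_size Optional row totals; defaults to \code{round(s)}.
#' @param ... Unused.
#'
#' @return A list of \code{nsim} sparse count matrices.
#'
#' @importFrom stats simulate rmultinom
#' @export
simulate.topic_model_fit <- function(object, nsim = 1, seed = 1,
                                     doc_size = NULL, ...) {
  set.seed(seed)
  Pi <- object$L %*% t(object$F)
  sizes <- if (is.null(doc_size)) pmax(1, round(object$s))
           else rep_len(doc_size, nrow(Pi))
  replicate(nsim, {
    X <- t(vapply(seq_len(nrow(Pi)),
                  function(i) drop(rmultinom(1, sizes[i], Pi[i, ])),
                  numeric(ncol(Pi))))
    as_count_matrix(X)
  }, simplify = FALSE)
}

#' Estimate topic proportions for new documents
#'
#' Projects new count rows onto the fitted topic distributions F by solving,
#' for each new document, the non-negative additive Poisson regression with
#' design F and the document's counts as response, then normalizing.
#'
#' @param object A \code{"topic_model_fit"}.
#' @param newdata A count matrix with the same number of columns as the
#'   training data.
#' @param numiter Inner solver iterations per document.
#' @param ... Unused.
#'
#' @return A row-stochastic matrix of topic proportions, one row per new
#'   document.
#'
#' @importFrom stats predict
#' @export
predict.topic_model_fit <- function(object, newdata, numiter = 100, ...) {
  X <- as_count_matrix(newdata)
  if (ncol(X) != nrow(object$F))
    stop("newdata has ", ncol(X), " columns; expected ", nrow(object$F))
  Xd <- as.matrix(X)
  L <- t(vapply(seq_len(nrow(Xd)), function(i) {
    b <- fit_pois_reg(object$F, Xd[i, ], method = "cd", numiter = numiter)
    as.numeric(b)
  }, numeric(object$k)))
  normalize_rows(L)$B
}
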