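# The alternating Poisson regression driver.  Each outer iteration updates
# the loadings block H (with W fixed), then the factors block W (with the
# updated H fixed); each block update solves its independent Poisson
# regression subproblems with the chosen inner solver.  With the EM solver
# and inner_iter = 1 an outer iteration is exactly one round of the classic
# multiplicative updates.  Optionally, iterates are accelerated by adaptive
# extrapolation: updates are computed from a momentum-shifted point and
# accepted only when they improve the objective, with the step size grown on
# success and shrunk (restarting from the best iterate) on failure.

default_extrapolation_control <- function() {
  list(beta0 = 0.5, beta_max = 1, growth = 1.05, shrink = 1.5)
}

fit_objective <- function(X, H, W, pen)
  penalized_pnmf_objective(X, H, W, pen)

# One full outer update (H block then W block) from the given point.
outer_update <- function(X, H, W, method, inner_iter, pen) {
  H <- update_block(X, H, W, "loadings", method, inner_iter, pen = NULL)
  W <- update_block(X, H, W, "factors", method, inner_iter, pen = pen)
  list(H = H, W = W)
}

#' Fit a Poisson non-negative matrix factorization by maximum likelihood
#'
#' Computes non-negative matrices H (n x k loadings) and W (m x k factors)
#' minimizing the Poisson NMF objective
#' \eqn{\ell(X;H,W) = \sum_{ij} (HW^T)_{ij} - x_{ij}\log (HW^T)_{ij}}
#' (equivalently, maximizing the Poisson likelihood of the counts), by
#' alternating between the two blocks and solving each block's independent
#' additive Poisson regressions with either coordinate descent
#' (\code{method = "cd"}, full feasible Newton steps) or expectation
#' maximization (\code{method = "em"}, multiplicative updates). Supplying a
#' penalty turns the problem into MAP estimation with gamma priors on W.
#'
#' The returned fit is always the best iterate visited (lowest objective),
#' so the objective of the returned fit can only improve as
#' \code{numiter} grows, for every solver configuration.
#'
#' @param X Count matrix (dense or sparse); must have no all-zero rows or
#'   columns (see \code{\link{validate_counts}}).
#' @param k Number of topics/factors, at least 2.
#' @param method Inner solver: \code{"cd"} (default) or \code{"em"}.
#' @param numiter Number of outer iterations after initialization.
#' @param inner_iter Inner updates per subproblem per outer iteration.
#' @param extrapolate Logical; activate the adaptive extrapolation
#'   acceleration.
#' @param extrapolate_start Outer iteration at which extrapolation begins.
#' @param init Either \code{"random"} or a list with matrices \code{H} and
#'   \code{W} to start from (as produced by a previous fit).
#' @param init_em Number of plain EM outer updates used to polish a random
#'   initialization before the main loop (ignored when \code{init} is a
#'   list). Comparisons of solvers should branch from a common prefit; see
#'   \code{\link{compare_fits}}.
#' @param seed Integer seed making random initialization reproducible.
#' @param pen Optional \code{\link{penalty_params}} for MAP estimation.
#' @param tol Relative objective-change stopping tolerance (0 disables; the
#'   iteration cap \code{numiter} is the primary stopping rule).
#' @param control List of extrapolation constants \code{beta0},
#'   \code{beta_max}, \code{growth}, \code{shrink}.
#' @param verbose Print per-iteration progress.
#'
#' @return An object of class \code{"poisson_nmf_fit"}: a list with
#'   components \code{H}, \code{W}, \code{k}, \code{objective} (value of the
#'   fitted objective at the returned iterate), \code{loglik} (full Poisson
#'   log-likelihood), \code{kkt} (first-order optimality residual),
#'   \code{trace} (data frame with one row per outer iteration: iteration
#'   number, objective of the candidate iterate, whether the iterate was
#'   extrapolated, and the extrapolation step size), and bookkeeping fields.
#'
#' @seealso \code{\link{fit_topic_model}} to obtain the equivalent topic
#'   model parameters; \code{\link{progress_report}} for the optimization
#'   trace.
#'
#' @examples
#' sim <- simulate_topic_data(60, 40, 3, doc_size = 200, seed = 1)
#' fit <- fit_poisson_nmf(sim$X, k = 3, numiter = 40, seed = 1)
#' fit
#'
#' @importFrom stats runif
#' @export
fit_poisson_nmf <- function(X, k, method = c("cd", "em"), numiter = 100,
                            inner_iter = 4, extrapolate = FALSE,
                            extrapolate_start = 50, init = "random",
                            init_em = 10, seed = 1, pen = NULL, tol = 1e-8,
                            control = list(), verbose = FALSE) {
  method <- match.arg(method)
  X <- as_count_matrix(X)
  require_positive_margins(X)
  n <- nrow(X)
  m <- ncol(X)
  stopifnot(k >= 2, numiter >= 1, inner_iter >= 1)
  ctrl <- utils::modifyList(default_extrapolation_control(), control)
  stopifnot(ctrl$beta0 > 0, ctrl$beta0 < 1)
  if (!is.null(pen))
    stopifnot(nrow(pen$a) == m, ncol(pen$a) == k)

  # -- initialization: scale-matched uniform random start + EM prefit
  if (is.list(init)) {
    H <- as.matrix(init$H)
    W <- as.matrix(init$W)
    stopifnot(nrow(H) == n, nrow(W) == m, ncol(H) == k, ncol(W) == k)
  } else {
    set.seed(seed)
    H <- matrix(runif(n * k), n, k)
    W <- matrix(runif(m * k), m, k)
    target_mean <- sum(X) / (n * m)
    cur_mean <- sum(colSums(H) * colSums(W)) / (n * m)
    sc <- sqrt(target_mean / cur_mean)
    H <- H * sc
    W <- W * sc
    for (it in seq_len(init_em)) {
      up <- outer_update(X, H, W, "em", 1L, pen = NULL)
      H <- up$H
      W <- up$W
    }
  }
  H <- pmax(H, eps_floor)
  W <- pmax(W, eps_floor)

  # Best iterate visited (the returned fit), the current iterate of the
  # plain sequence, and -- once extrapolation activates -- the accepted and
  # extrapolated sequences of the acceleration scheme.
  obj_best <- fit_objective(X, H, W, pen)
  Hbest <- H
  Wbest <- W
  He <- We <- NULL
  beta <- ctrl$beta0
  beta_max <- ctrl$beta_max
  trace_iter <- integer(numiter + 1)
  trace_obj <- numeric(numiter + 1)
  trace_ex <- logical(numiter + 1)
  trace_beta <- numeric(numiter + 1)
  trace_obj[1] <- obj_best
  nrec <- 1L
  for (it in seq_len(numiter)) {
    use_ex <- extrapolate && it >= extrapolate_start
    if (use_ex) {
      if (is.null(He)) {       # entering the accelerated phase: start at best
        H <- Hbest
        W <- Wbest
        He <- H
        We <- W
      }
      up <- outer_update(X, He, We, method, inner_iter, pen)
      obj_new <- fit_objective(X, up$H, up$W, pen)
      if (!is.finite(obj_new))
        stop("non-finite objective at outer iteration ", it)
      if (obj_new < obj_best) {                # accept and grow the step
        He <- extrapolated_iterate(up$H, H, beta)
        We <- extrapolated_iterate(up$W, W, beta)
        H <- up$H
        W <- up$W
        Hbest <- up$H
        Wbest <- up$W
        obj_best <- obj_new
        beta <- min(beta_max, ctrl$growth * beta)
      } else {                                 # reject: restart from best
        H <- Hbest
        W <- Wbest
        He <- Hbest
        We <- Wbest
        beta_max <- beta
        beta <- beta / ctrl$shrink
      }
    } else {
      up <- outer_update(X, H, W, method, inner_iter, pen)
      obj_new <- fit_objective(X, up$H, up$W, pen)
      if (!is.finite(obj_new))
        stop("non-finite objective at outer iteration ", it)
      H <- up$H
      W <- up$W
      if (obj_new < obj_best) {
        Hbest <- H
        Wbest <- W
        obj_best <- obj_new
      }
    }
    nrec <- nrec + 1L
    trace_iter[nrec] <- it
    trace_obj[nrec] <- obj_new
    trace_ex[nrec] <- use_ex
    trace_beta[nrec] <- if (use_ex) beta else 0
    if (verbose)
      message(sprintf("iter %4d  objective %.10e", it, obj_new))
    if (tol > 0 && nrec > 2 &&
        abs(trace_obj[nrec] - trace_obj[nrec - 1]) <=
          tol * (abs(obj_best) + 1))
      break
  }
  trace <- data.frame(iter = trace_iter[seq_len(nrec)],
                      objective = trace_obj[seq_len(nrec)],
                      extrapolated = trace_ex[seq_len(nrec)],
                      beta = trace_beta[seq_len(nrec)])
  structure(list(H = Hbest, W = Wbest, k = k, objective = obj_best,
                 loglik = pnmf_loglik(X, Hbest, Wbest),
                 kkt = pnmf_kkt_residual(X, Hbest, Wbest, pen),
                 trace = trace, method = method, extrapolate = extrapolate,
                 pen = pen, seed = seed, call = match.call()),
            class = "poisson_nmf_fit")
}

#' Fit a multinomial topic model by maximum likelihood
#'
#' Fits the multinomial topic model — each row of counts multinomial with
#' probabilities \eqn{\Pi = LF^T}, L row-stochastic, F column-stochastic —
#' by solving the equivalent Poisson NMF problem with
#' \code{\link{fit_poisson_nmf}} and applying the exact change of variables
#' \code{\link{pnmf_to_mtm}}. At an exact maximum-likelihood solution the
#' recovered document scales equal the observed row totals
#' (\eqn{s = t}).
#'
#' @inheritParams fit_poisson_nmf
#' @param ... Arguments passed to \code{\link{fit_poisson_nmf}}.
#'
#' @return An object of class \code{"topic_model_fit"}: a list with
#'   components \code{L}, \code{F}, \code{s}, \code{u}, \code{k},
#'   \code{objective} (the multinomial objective \eqn{\phi}),
#'   \code{loglik} (full multinomial log-likelihood), \code{trace}, and
#'   \code{pnmf} (the underlying Poisson NMF fit).
#'
#' @examples
#' sim <- simulate_topic_data(60, 40, 3, doc_size = 200, seed = 1)
#' fit <- fit_topic_model(sim$X, k = 3, numiter = 40, seed = 1)
#' summary(fit)
#'
#' @export
fit_topic_model <- function(X, k, ...) {
  X <- as_count_matrix(X)
  pf <- fit_poisson_nmf(X, k, ...)
  map <- pnmf_to_mtm(pf$H, pf$W)
  structure(list(L = map$L, F = map$F, s = map$s, u = map$u, k = k,
                 objective = mtm_objective(X, map$L, map$F),
                 loglik = mtm_loglik(X, map$L, map$F),
                 trace = pf$trace, pnmf = pf, call = match.call()),
            class = "topic_model_fit")
}

#' Optimization progress table
#'
#' Flattens the trace of a fit into a table with, per outer iteration, the
#' candidate objective, its difference to the best objective in the trace
#' (always non-negative), and the extrapolation state.
#'
#' @param fit A \code{"poisson_nmf_fit"} or \code{"topic_model_fit"}.
#'
#' @return A data frame with columns \code{iter}, \code{objective},
#'   \code{delta} (objective minus the trace minimum), \code{extrapolated},
#'   \code{beta}.
#'
#' @export
progress_report <- function(fit) {
  tr <- fit$trace
  if (is.null(tr))
    stop("fit has no progress trace")
  data.frame(iter = tr$iter, objective = tr$objective,
             delta = tr$objective - min(tr$objective),
             extrapolated = tr$extrapolated, beta = tr$beta)
}

#' Compare solver configurations from a shared initialization
#'
#' Runs several solver configurations on the same data, all branching from a
#' single shared initialization (random start polished by \code{init_em}
#' plain EM outer updates), so that differences in the traces reflect the
#' solvers rather than their starting points.
#'
#' @inheritParams fit_poisson_nmf
#' @param methods Character vector of inner solvers, recycled against
#'   \code{extrapolate}.
#' @param extrapolate Logical vector, recycled against \code{methods}.
#'
#' @return A long-format data frame with columns \code{method},
#'   \code{extrapolated}, \code{iter}, \code{objective} and \code{delta}
#'   (objective minus the best objective across all configurations, always
#'   non-negative), plus attribute \code{"fits"} holding the fit objects.
#'
#' @export
compare_fits <- function(X, k, methods = c("em", "cd"),
                         extrapolate = FALSE, numiter = 100, inner_iter = 4,
                         init_em = 10, seed = 1, tol = 0, ...) {
  X <- as_count_matrix(X)
  n_cfg <- max(length(methods), length(extrapolate))
  methods <- rep_len(methods, n_cfg)
  extrapolate <- rep_len(extrapolate, n_cfg)
  pre <- fit_poisson_nmf(X, k, method = "em", numiter = max(1, init_em),
                         inner_iter = 1, init_em = 0, seed = seed, tol = 0)
  init <- list(H = pre$H, W = pre$W)
  fits <- vector("list", n_cfg)
  rows <- vector("list", n_cfg)
  for (cfg in seq_len(n_cfg)) {
    f <- fit_poisson_nmf(X, k, method = methods[cfg], numiter = numiter,
                         inner_iter = inner_iter,
                         extrapolate = extrapolate[cfg], init = init,
                         seed = seed, tol = tol, ...)
    fits[[cfg]] <- f
    rows[[cfg]] <- data.frame(method = methods[cfg],
                              extrapolated = extrapolate[cfg],
                              iter = f$trace$iter,
                              objective = f$trace$objective)
  }
  out <- do.call(rbind, rows)
  out$delta <- out$objective - min(out$objective)
  attr(out, "fits") <- fits
  out
}
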