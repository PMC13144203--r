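sim_small <- simulate_topic_data(60, 40, 3, doc_size = 200, seed = 1)

test_that("one EM outer iteration equals the multiplicative updates", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(8:30, 1)
    m <- sample(8:30, 1)
    K <- sample(2:4, 1)
    D <- matrix(rpois(n * m, 2), n, m)
    D[cbind(1:n, sample(m, n, replace = TRUE))] <- 1 + rpois(n, 2)
    X <- as_count_matrix(D)
    hw <- random_hw(n, m, K, seed + 50)
    mu <- multiplicative_update(X, hw$H, hw$W)
    H1 <- update_block(X, hw$H, hw$W, "loadings", "em", inner_iter = 1)
    W1 <- update_block(X, H1, hw$W, "factors", "em", inner_iter = 1)
    expect_lt(max(abs(mu$H - H1)), 1e-13 * max(mu$H))
    expect_lt(max(abs(mu$W - W1)), 1e-13 * max(mu$W))
  }
})

test_that("multiplicative updates are monotone and fix stationary points", {
  X <- sim_small$X
  hw <- random_hw(60, 40, 3, 2)
  H <- hw$H
  W <- hw$W
  objs <- numeric(200)
  for (it in 1:200) {
    up <- multiplicative_update(X, H, W)
    H <- up$H
    W <- up$W
    objs[it] <- pnmf_objective(X, H, W)
  }
  expect_true(all(diff(objs) <= 1e-10 * (abs(objs[-1]) + 1)))
  # near-stationary point: another update barely moves
  up <- multiplicative_update(X, H, W)
  expect_lt(max(abs(up$H - H) / (H + 1)), 1e-3)
})

test_that("block updates equal per-subproblem solves in any order", {
  set.seed(3)
  n <- 12; m <- 9; K <- 3
  D <- matrix(rpois(n * m, 2), n, m)
  D[1, ] <- D[1, ] + 1
  D[, colSums(D) == 0] <- 1
  X <- as_count_matrix(D)
  hw <- random_hw(n, m, K, 17)
  for (method in c("em", "cd")) {
    Wb <- update_block(X, hw$H, hw$W, "factors", method, inner_iter = 4)
    solve_one <- function(j)
      as.numeric(fit_pois_reg(hw$H, D[, j], b0 = hw$W[j, ], method = method,
                              numiter = 4))
    W_fwd <- t(vapply(1:m, solve_one, numeric(K)))
    W_rev <- t(vapply(m:1, solve_one, numeric(K)))[m:1, ]
    expect_identical(W_fwd, W_rev[seq_len(m), ])
    expect_lt(max(abs(Wb - W_fwd)), 1e-12 * max(W_fwd))
    # loadings update is the same computation on the transpose
    Hb <- update_block(X, hw$H, hw$W, "loadings", method, inner_iter = 4)
    Hb2 <- update_block(Matrix::t(X), hw$W, hw$H, "factors", method,
                        inner_iter = 4)
    expect_equal(Hb, Hb2, tolerance = 1e-13)
  }
})

test_that("a zero column in the fixed block drives its target column to the floor", {
  set.seed(5)
  D <- matrix(rpois(50, 3), 5, 10)
  D[1, ] <- D[1, ] + 1
  D[, colSums(D) == 0] <- 1
  X <- as_count_matrix(D)
  H <- cbind(runif(5) + 0.5, 0)       # topic 2 has no support
  W <- matrix(runif(20) + 0.5, 10, 2)
  Wb <- suppressWarnings(update_block(X, H, W, "factors", "cd",
                                      inner_iter = 2))
  expect_true(all(Wb[, 2] == 1e-15))
})

test_that("extrapolated candidates project onto the feasible set", {
  cur <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(extrapolated_iterate(cur, cur * 2, 0), cur)
  expect_identical(extrapolated_iterate(cur, cur, 0.7), cur)
  prev <- matrix(c(5, 2, 3, 4), 2, 2)
  cand <- extrapolated_iterate(cur, prev, 0.5)
  expect_equal(cand[1, 1], 1e-15)     # 1 + 0.5*(1-5) < 0, floored
  expect_equal(cand[2, 2], 4)
})

test_that("fits are deterministic and EM traces are monotone", {
  f1 <- fit_poisson_nmf(sim_small$X, 3, method = "cd", numiter = 25,
                        seed = 7, tol = 0)
  f2 <- fit_poisson_nmf(sim_small$X, 3, method = "cd", numiter = 25,
                        seed = 7, tol = 0)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$trace, f2$trace)
  for (seed in 1:5) {
    st <- simulate_topic_data(40, 30, 3, doc_size = 150, seed = seed)
    fe <- fit_poisson_nmf(st$X, 3, method = "em", numiter = 40, seed = seed,
                          tol = 0)
    o <- fe$trace$objective
    expect_true(all(diff(o) <= 1e-10 * (abs(o[-1]) + 1)))
    # the running best of any trace is non-increasing by construction
    fc <- fit_poisson_nmf(st$X, 3, method = "cd", numiter = 40, seed = seed,
                          tol = 0, extrapolate = TRUE, extrapolate_start = 10)
    expect_true(all(diff(cummin(fc$trace$objective)) <= 0))
    expect_lte(fc$objective, min(fc$trace$objective) + 1e-12)
  }
})

test_that("the fit refuses degenerate input and reports a finite objective", {
  D <- rbind(c(1, 0, 2), c(0, 0, 0), c(2, 1, 0))
  expect_error(fit_poisson_nmf(as_count_matrix(D), 2), "degenerate")
  f <- fit_poisson_nmf(sim_small$X, 3, numiter = 5, seed = 1)
  expect_true(is.finite(f$objective))
  expect_equal(f$objective, pnmf_objective(sim_small$X, f$H, f$W),
               tolerance = 1e-10)
})

test_that("updating X and t(X) with swapped roles gives the same objective", {
  # the objective is symmetric in (H, X) vs (W, t(X)); iterating the two
  # blocks in mirrored order on the transpose reproduces the same sequence
  X <- sim_small$X
  Xt <- Matrix::t(X)
  hw <- random_hw(nrow(X), ncol(X), 3, 31)
  H <- Ht <- hw$H
  W <- Wt <- hw$W
  for (method in c("em", "cd")) {
    for (it in 1:10) {
      H <- update_block(X, H, W, "loadings", method, inner_iter = 2)
      W <- update_block(X, H, W, "factors", method, inner_iter = 2)
      # on the transpose the roles swap: Ht plays W, Wt plays H
      Ht <- update_block(Xt, Wt, Ht, "factors", method, inner_iter = 2)
      Wt <- update_block(Xt, Wt, Ht, "loadings", method, inner_iter = 2)
    }
    o1 <- pnmf_objective(X, H, W)
    o2 <- pnmf_objective(Xt, Wt, Ht)
    expect_equal(o1, o2, tolerance = 1e-10)
  }
})

test_that("cd matches or beats em from a shared initialization", {
  tab <- compare_fits(sim_small$X, 3, methods = c("em", "cd"),
                      numiter = 60, init_em = 10, seed = 11)
  fits <- attr(tab, "fits")
  expect_lte(fits[[2]]$objective, fits[[1]]$objective + 1e-6)
  expect_true(all(tab$delta >= 0))
  expect_equal(nrow(tab), 2 * 61)
})

test_that("progress reports have non-negative deltas and round-trip via CSV", {
  f <- fit_poisson_nmf(sim_small$X, 3, numiter = 10, seed = 1, tol = 0)
  pr <- progress_report(f)
  expect_equal(nrow(pr), 11)
  expect_true(all(pr$delta >= 0))
  expect_equal(min(pr$delta), 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pr, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_equal(back$objective, pr$objective, tolerance = 1e-12)
})

test_that("topic-model fits satisfy the simplex constraints with s near t", {
  st <- simulate_topic_data(20, 30, 2, doc_size = 300, seed = 4)
  tf <- fit_topic_model(st$X, 2, method = "cd", numiter = 400, seed = 4,
                        tol = 0)
  expect_lt(max(abs(rowSums(tf$L) - 1)), 1e-12)
  expect_lt(max(abs(colSums(tf$F) - 1)), 1e-12)
  t <- Matrix::rowSums(st$X)
  expect_lt(max(abs(tf$s - t) / t), 1e-4)
  expect_equal(tf$objective, mtm_objective(st$X, tf$L, tf$F))
  # cd reaches at least em's multinomial likelihood from the same prefit
  tab <- compare_fits(st$X, 2, methods = c("em", "cd"), numiter = 100,
                      init_em = 10, seed = 4)
  fits <- attr(tab, "fits")
  me <- pnmf_to_mtm(fits[[1]]$H, fits[[1]]$W)
  mc <- pnmf_to_mtm(fits[[2]]$H, fits[[2]]$W)
  expect_gte(mtm_loglik(st$X, mc$L, mc$F),
             mtm_loglik(st$X, me$L, me$F) - 1e-6)
})
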