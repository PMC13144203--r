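test_that("objectives match closed forms on tiny instances", {
  X0 <- as_count_matrix(matrix(2))
  # all-zero matrices are rejected, so the zero-count case enters through a
  # 1x2 matrix whose second cell is empty
  X01 <- as_count_matrix(matrix(c(0, 1), 1, 2))
  expect_equal(pnmf_objective(X01, matrix(1, 1, 2),
                              rbind(c(0.5, 0.5), c(0.5, 0.5))),
               2 - log(1))
  expect_equal(pnmf_objective(X0, matrix(1, 1, 2), matrix(1, 1, 2)),
               2 - 2 * log(2))
  X11 <- as_count_matrix(matrix(c(1, 1), 1, 2))
  L <- matrix(c(0.5, 0.5), 1, 2)
  F <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(mtm_objective(X11, L, F), 2 * log(2))
  X30 <- as_count_matrix(matrix(c(3, 0), 1, 2))
  expect_equal(mtm_objective(X30, matrix(c(1, 0), 1, 2),
                             rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(augmented_objective(X11, L, F, s = 2),
               2 * log(2) + 2 - 2 * log(2))
  expect_error(augmented_objective(X11, L, F, s = -1), "positive")
})

test_that("objectives agree with dense double-loop oracles", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:50, 1)
    m <- sample(4:50, 1)
    K <- sample(2:6, 1)
    hw <- random_hw(n, m, K, seed + 100)
    D <- matrix(rpois(n * m, 1.5), n, m)
    D[1, 1] <- D[1, 1] + 1
    X <- as_count_matrix(D)
    expect_equal(pnmf_objective(X, hw$H, hw$W),
                 dense_pnmf_objective(D, hw$H, hw$W),
                 tolerance = 1e-12)
    p <- pnmf_to_mtm(hw$H, hw$W)
    expect_equal(mtm_objective(X, p$L, p$F),
                 dense_mtm_objective(D, p$L, p$F),
                 tolerance = 1e-12)
  }
})

test_that("objective errors name the offending cell when a rate is zero", {
  X <- as_count_matrix(rbind(c(2, 0), c(0, 1)))
  H <- rbind(c(1, 0), c(0, 1))
  W <- rbind(c(1, 0), c(0, 0))    # lambda_22 = 0 but x_22 = 1
  expect_error(pnmf_objective(X, H, W), "\\(2, 2\\)")
})

test_that("the scale term of the augmented objective is minimized at s = t", {
  X <- as_count_matrix(rbind(c(3, 1), c(0, 2)))
  t <- Matrix::rowSums(X)
  L <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  F <- cbind(c(0.2, 0.8), c(0.9, 0.1))
  at_t <- augmented_objective(X, L, F, t)
  for (d in c(-0.1, 0.1, 0.5, -0.3))
    expect_gt(augmented_objective(X, L, F, t + d), at_t)
})

test_that("log-likelihoods include their constants", {
  X <- as_count_matrix(matrix(c(1, 0), 1, 2))
  H <- matrix(c(1, 0), 1, 2)
  W <- rbind(c(1, 1), c(0, 0))     # lambda = (1, 0); x = (1, 0)
  expect_equal(pnmf_loglik(X, H, W), dpois(1, 1, log = TRUE))
  X11 <- as_count_matrix(matrix(c(1, 1), 1, 2))
  L <- matrix(c(0.5, 0.5), 1, 2)
  F <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(mtm_loglik(X11, L, F), log(2 * 0.25))
})

test_that("the likelihood identity holds exactly across random instances", {
  # 1x1 instance: analytically zero gap
  X <- as_count_matrix(matrix(2))
  expect_equal(lemma_identity_gap(X, matrix(1, 1, 2), matrix(1, 1, 2)), 0,
               tolerance = 1e-12)
  for (seed in 1:25) {
    sim <- simulate_pnmf_data(30, 40, 5, scale = 2, seed = seed)
    hw <- random_hw(30, 40, 5, seed + 500)
    gap <- lemma_identity_gap(sim$X, hw$H, hw$W)
    ref <- abs(pnmf_loglik(sim$X, hw$H, hw$W))
    expect_lt(abs(gap), 1e-8 * (1 + ref))
  }
  # a zero-count row in X (t_i = 0) with positive rates still satisfies it
  D <- rbind(c(2, 1, 0), c(0, 0, 0), c(1, 0, 3))
  X <- as_count_matrix(D)
  hw <- random_hw(3, 3, 2, 7)
  expect_lt(abs(lemma_identity_gap(X, hw$H, hw$W)),
            1e-8 * (1 + abs(pnmf_loglik(X, hw$H, hw$W))))
})

test_that("penalties reduce to zero at a = 1, b = 0 and match arithmetic", {
  X <- as_count_matrix(rbind(c(2, 1), c(0, 3)))
  hw <- random_hw(2, 2, 2, 3)
  pen0 <- penalty_params(1, 0, m = 2, K = 2)
  expect_identical(penalized_pnmf_objective(X, hw$H, hw$W, pen0),
                   pnmf_objective(X, hw$H, hw$W))
  # W = ones, a = 2, b = 1: penalty = -(sum of log 1) + sum of w = K*m... here
  # 1x2 factors W=[[1,1]]: rho = 0 + 2
  X1 <- as_count_matrix(matrix(c(1, 1), 2, 1))
  W1 <- matrix(1, 1, 2)
  H1 <- matrix(1, 2, 2)
  pen <- penalty_params(2, 1, m = 1, K = 2)
  expect_equal(penalized_pnmf_objective(X1, H1, W1, pen) -
                 pnmf_objective(X1, H1, W1), 2)
  expect_error(penalized_pnmf_objective(X1, H1, matrix(c(0, 1), 1, 2), pen),
               "infinite")
})

test_that("the penalized objectives stay equivalent along the parameter map", {
  # the gap l* - phi* - psi depends only on the topic scales u, so it is
  # constant across parameter points sharing the same u
  for (seed in 1:8) {
    set.seed(seed)
    n <- 15; m <- 12; K <- 3
    sim <- simulate_topic_data(n, m, K, doc_size = 50, seed = seed)
    pen <- penalty_params(1 + matrix(runif(m * K), m, K), runif(K), m, K)
    u <- runif(K, 0.5, 2)
    gaps <- replicate(5, {
      L <- t(apply(matrix(rgamma(n * K, 1), n, K), 1, function(r) r / sum(r)))
      F <- apply(matrix(rgamma(m * K, 1), m, K), 2, function(c) c / sum(c))
      s <- runif(n, 10, 100)
      hw <- mtm_to_pnmf(L, F, s, u)
      t <- Matrix::rowSums(sim$X)
      penalized_pnmf_objective(sim$X, hw$H, hw$W, pen) -
        penalized_mtm_objective(sim$X, L, F, pen) -
        (sum(s) - sum(t * log(s)))
    })
    expect_lt(max(gaps) - min(gaps), 1e-8 * (1 + max(abs(gaps))))
  }
})
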