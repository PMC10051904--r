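test_that("similarity and constraint value follow their definitions", {
  set.seed(1)
  r <- rnorm(100)
  expect_equal(similarity(r, r), 1)
  expect_equal(similarity(r, -r), 1)
  y <- rnorm(100)
  y_perp <- y - mean(y)
  r_c <- r - mean(r)
  y_perp <- y_perp - sum(y_perp * r_c) / sum(r_c^2) * r_c
  expect_lt(similarity(r, y_perp), 1e-10)
  expect_equal(constraint_value(0.3, r, r), -0.7)
  expect_equal(constraint_value(0.3, r, y_perp), 0.3, tolerance = 1e-9)
  # theta = 0 is always satisfied
  for (i in 1:10) expect_lte(constraint_value(0, rnorm(50), rnorm(50)), 0)
  expect_error(similarity(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(constraint_value(1.2, r, y), "0, 1")
})

test_that("multiplier updates clip at zero and follow the max rule", {
  expect_equal(update_multiplier(0, -0.2, 3), 0)
  expect_equal(update_multiplier(0.5, 0.1, 1), 0.6)
  # a strictly satisfied constraint drives the multiplier to exactly 0
  mu <- 2
  for (i in 1:10) mu <- update_multiplier(mu, -0.3, 1)
  expect_identical(mu, 0)
  expect_error(update_multiplier(-1, 0, 1), "nonnegative")
  expect_error(update_multiplier(0, 0, 0), "positive")
})

test_that("constraint gradient reduces to the unconstrained gradient when inactive", {
  set.seed(2)
  X <- whiten(matrix(rnorm(4 * 3000), 4, 3000))$X
  W <- fsig:::random_orthogonal(4)
  w <- W[1, ]; d <- decoupling_vector(W, 1)
  y <- drop(w %*% X)
  r <- y + rnorm(3000, sd = 0.1)   # epsilon near 1, constraint far satisfied
  g_con <- constrained_row_gradient(w, X, d, r, mu_n = 0, gamma = 3,
                                    theta = 0.3, table = tab)
  g_off <- constrained_row_gradient(w, X, d, r, mu_n = 0, gamma = 3,
                                    theta = 0, table = tab)
  expect_identical(g_con, g_off)
  # the penalty depends on the reference only through |corr|, so the
  # gradient is invariant under a sign flip of the reference: sign(r'y)
  # and X r flip together and their product is unchanged
  r2 <- rnorm(3000)
  g_p <- constrained_row_gradient(w, X, d, r2, mu_n = 2, gamma = 3,
                                  theta = 0.9, table = tab)
  g_m <- constrained_row_gradient(w, X, d, -r2, mu_n = 2, gamma = 3,
                                  theta = 0.9, table = tab)
  g_u <- constrained_row_gradient(w, X, d, r2, mu_n = 0, gamma = 3,
                                  theta = 0, table = tab)
  expect_equal(g_p, g_m, tolerance = 1e-12)
  # and the active penalty moves the gradient away from the unconstrained one
  expect_gt(max(abs(g_p - g_u)), 1e-6)
})

test_that("gradient matches central differences of the augmented cost", {
  worst <- fd_gradient_worst(seed = 3, n_points = 20)
  expect_lt(worst, 1e-4)
})

test_that("degenerate directions are rejected", {
  X <- whiten(matrix(rnorm(3 * 1000), 3, 1000))$X
  d <- c(1, 0, 0)
  w <- c(0, 1, 0)    # orthogonal to d
  expect_error(constrained_row_gradient(w, X, d, rnorm(1000), 0, 3, 0.3, tab),
               "degenerate")
  expect_equal(cebm_row_cost(w, X, d, rnorm(1000), 0, 3, 0.3, tab), Inf)
})

test_that("feasible references are satisfied at theta = 0.3", {
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 5))
  fit <- cebm(sim$subjects[[1]]$X, sim$references, theta = 0.3, table = tab,
              seed = 11)
  expect_true(all(fit$constraint$satisfied))
  expect_true(all(fit$constraint$mu >= 0))
  expect_true(all(fit$constraint$epsilon >= 0.3 - 1e-8))
})

test_that("theta = 0 reproduces the unconstrained fit from the same start", {
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 6))
  X <- sim$subjects[[2]]$X
  W0 <- fsig:::random_orthogonal(4)
  wd <- whiten(X)
  f0 <- cebm(wd, sim$references, theta = 0, table = tab, W0 = W0)
  f1 <- ica_ebm(wd, table = tab, W0 = W0)
  cc <- abs(diag(stats::cor(t(f0$S), t(f1$S))))
  expect_true(all(cc > 0.999))
})

test_that("shared references align components across subjects", {
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 7))
  f1 <- cebm(sim$subjects[[1]]$X, sim$references, theta = 0.3, table = tab,
             seed = 21)
  f2 <- cebm(sim$subjects[[4]]$X, sim$references, theta = 0.3, table = tab,
             seed = 22)
  R <- sim$references$R
  for (n in 1:4) {
    expect_equal(which.max(abs(stats::cor(f1$S[n, ], t(R)))), n)
    expect_equal(which.max(abs(stats::cor(f2$S[n, ], t(R)))), n)
  }
})

test_that("the mean final similarity is non-decreasing in theta", {
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 8))
  X <- sim$subjects[[3]]$X
  eps_mean <- vapply(c(0, 0.3, 0.6, 0.9), function(th) {
    f <- suppressWarnings(cebm(X, sim$references, theta = th, table = tab,
                               seed = 33, max_sweeps = 256))
    mean(f$constraint$epsilon)
  }, 0)
  expect_true(all(diff(eps_mean) >= -1e-6))
})

test_that("fits are deterministic given a seed and reject bad inputs", {
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 9))
  X <- sim$subjects[[1]]$X
  f1 <- cebm(X, sim$references, theta = 0.3, table = tab, seed = 44)
  f2 <- cebm(X, sim$references, theta = 0.3, table = tab, seed = 44)
  expect_identical(f1$W, f2$W)
  expect_error(cebm(X, sim$references$R[, 1:100], table = tab), "same number")
  expect_error(cebm(X, rbind(sim$references$R, sim$references$R[1:2, ] + 1e-14),
                    table = tab), "correlated|references")
  expect_error(cebm(X, sim$references, theta = 2, table = tab), "0, 1")
})
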