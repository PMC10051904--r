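test_that("whitening yields identity covariance and keeps the transform", {
  set.seed(1)
  raw <- matrix(rnorm(6 * 500), 6, 500) * (1:6)
  wd <- whiten(raw, 4)
  C <- tcrossprod(wd$X) / (500 - 1)
  expect_lt(norm(C - diag(4), "F"), 1e-6)
  expect_equal(sort(eigen(C)$values), rep(1, 4), tolerance = 1e-8)
  # idempotence: whitening already-white data changes nothing essential
  wd2 <- whiten(wd$X, 4)
  C2 <- tcrossprod(wd2$X) / (500 - 1)
  expect_lt(norm(C2 - diag(4), "F"), 1e-6)
})

test_that("whitening a rank-deficient matrix beyond its rank errors", {
  set.seed(2)
  low <- matrix(rnorm(2 * 300), 2, 300)
  raw <- rbind(low, low[1, ] + low[2, ])
  expect_error(whiten(raw, 3), "rank")
})

test_that("decoupling vectors span the correct null spaces", {
  expect_equal(decoupling_vector(diag(3), 2), c(0, 1, 0))
  # orthogonal W: d_n is the (normalized) row itself
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  for (n in 1:4)
    expect_equal(decoupling_vector(Q, n), Q[n, ] / sqrt(sum(Q[n, ]^2)),
                 tolerance = 1e-12)
  # random invertible W: orthogonal to all other rows, positive with own row
  W <- matrix(rnorm(16), 4)
  for (n in 1:4) {
    d <- decoupling_vector(W, n)
    expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)
    expect_lt(max(abs(W[-n, ] %*% d)), 1e-10)
    expect_gt(sum(d * W[n, ]), 0)
  }
  W[2, ] <- W[1, ]
  expect_error(decoupling_vector(W, 3), "degenerate")
})

test_that("decoupled cost vanishes for Gaussian sources and is additive in log|d.w|", {
  set.seed(4)
  X <- whiten(matrix(rnorm(2 * 5e4), 2, 5e4))$X
  w <- c(1, 0); d <- c(1, 0)
  c0 <- decoupled_cost(w, X, d, tab)
  expect_lt(abs(as.numeric(c0)), 0.02)
  # halving d.w at a fixed source distribution adds exactly log 2
  c_half <- decoupled_cost(0.5 * w, X, d, tab)
  expect_equal(as.numeric(c_half) - as.numeric(c0), log(2), tolerance = 1e-12)
  # sign invariance
  expect_equal(as.numeric(decoupled_cost(-w, X, d, tab)), as.numeric(c0),
               tolerance = 1e-12)
})

test_that("two non-Gaussian sources are recovered from a mixture", {
  set.seed(5)
  V <- 20000
  S <- rbind(runif(V, -sqrt(3), sqrt(3)),
             rexp(V) * sample(c(-1, 1), V, TRUE) / sqrt(2))
  A <- matrix(c(1, 0.6, -0.4, 1), 2, 2)
  wd <- whiten(A %*% S)
  fit <- ica_ebm(wd, table = tab, seed = 9)
  expect_true(fit$converged)
  expect_lt(isi(global_matrix(fit, wd, A)), 0.05)
})

test_that("an identity mixture started at identity stays a signed permutation", {
  S <- gen_sources(3, 10000, seed = 6)
  fit <- ica_ebm(S, table = tab, W0 = diag(3))
  expect_lt(isi(fit$W), 0.02)
})

test_that("zero sweeps returns the initialization unchanged", {
  S <- gen_sources(2, 2000, seed = 7)
  W0 <- matrix(c(2, 1, 0, 1), 2, 2)
  fit <- ica_ebm(S, table = tab, W0 = W0, max_sweeps = 0)
  expect_false(fit$converged)
  expect_identical(fit$W, W0)
})

test_that("accepted line-search steps never increase the row cost", {
  S <- gen_sources(4, 8000, seed = 8)
  A <- matrix(rnorm(16), 4)
  wd <- whiten(A %*% S)
  fit <- ica_ebm(wd, table = tab, seed = 21)
  expect_gt(nrow(fit$step_costs), 0)
  expect_true(all(fit$step_costs$cost_after <= fit$step_costs$cost_before))
})

test_that("fits are equivariant to signed permutations of the input rows", {
  S <- gen_sources(3, 15000, seed = 9)
  A <- matrix(rnorm(9), 3)
  X <- A %*% S
  P <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, -1))
  f1 <- ica_ebm(whiten(X), table = tab, seed = 31)
  f2 <- ica_ebm(whiten(P %*% X), table = tab, seed = 31)
  cc <- abs(stats::cor(t(f1$S), t(f2$S)))
  matched <- apply(cc, 1, max)
  expect_true(all(matched > 0.999))
})

test_that("recovery holds across seeds for four distinct source shapes", {
  isis <- vapply(1:5, function(s) {
    S <- gen_sources(4, 20000, seed = 200 + s)
    set.seed(300 + s)
    A <- matrix(rnorm(16), 4)
    wd <- whiten(A %*% S)
    fit <- suppressWarnings(ica_ebm(wd, table = tab, seed = 400 + s))
    isi(global_matrix(fit, wd, A))
  }, 0)
  expect_lt(stats::median(isis), 0.1)
})

test_that("NaN input is rejected", {
  S <- gen_sources(2, 1000, seed = 10)
  S[1, 5] <- NA
  expect_error(ica_ebm(S, table = tab), "missing")
})
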