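test_that("SCV covariance reduces to known forms", {
  V <- 500
  base <- rnorm(V)
  Y <- rbind(base, base, base)
  expect_equal(scv_covariance(Y), matrix(1, 3, 3), ignore_attr = TRUE)
  # mutually orthogonal zero-mean rows give the identity: orthogonalize
  # against the constant vector so centering is exact
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(3 * V), V, 3))))[, 2:4]
  expect_equal(scv_covariance(t(Q)), diag(3), ignore_attr = TRUE,
               tolerance = 1e-8)
  set.seed(1)
  y1 <- rnorm(V); y2 <- 0.6 * y1 + rnorm(V)
  rho <- cor(y1, y2)
  expect_equal(scv_covariance(rbind(y1, y2)),
               matrix(c(1, rho, rho, 1), 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(scv_covariance(rbind(y1, rep(2, V))), "constant")
})

test_that("scv_stack standardizes, aligns signs, and validates shapes", {
  set.seed(2)
  S1 <- gen_sources(3, 800, seed = 21)
  S2 <- S1 * c(-1, 1, -1) + matrix(rnorm(3 * 800, sd = 0.1), 3)
  scvs <- scv_stack(list(S1, S2))
  expect_length(scvs, 3)
  for (s in scvs) {
    expect_equal(rowMeans(s$Y), c(0, 0), tolerance = 1e-8, ignore_attr = TRUE)
    expect_gt(cor(s$Y[1, ], s$Y[2, ]), 0.9)  # sign-aligned
  }
  raw <- scv_stack(list(S1, S2), align_sign = FALSE)
  expect_lt(cor(raw[[1]]$Y[1, ], raw[[1]]$Y[2, ]), 0)
  expect_error(scv_stack(list(S1)), "at least 2")
  expect_error(scv_stack(list(S1, S2[, 1:100])), "share")
})

test_that("Gershgorin detection matches closed-form planted structure", {
  # identity: no eigenvalue escapes the (zero-radius) smallest disc
  p0 <- gershgorin_subgroups(diag(5))
  expect_equal(p0$r_min, 0)
  expect_equal(p0$n_subgroups, 0)
  expect_true(all(p0$membership == "rest"))

  # one block of 3 at rho = 0.8 among 6 subjects: eigenvalues are
  # 1 + 2*0.8 = 2.6, three 1's, and 1 - 0.8 = 0.2 twice
  C1 <- make_block_cor(6, list(1:3), 0.8)
  p1 <- gershgorin_subgroups(C1)
  expect_equal(p1$r_min, 0)
  expect_equal(sort(p1$eigenvalues),
               sort(c(2.6, 1, 1, 1, 0.2, 0.2)), tolerance = 1e-12)
  expect_equal(p1$n_subgroups, 1)
  expect_equal(p1$membership, c("SG1", "SG1", "SG1", "rest", "rest", "rest"))
  expect_equal(p1$eigenvalues, eigen(C1, symmetric = TRUE)$values,
               tolerance = 1e-12)

  # two disjoint blocks of 3 at rho = 0.9 plus 2 singletons
  C2 <- make_block_cor(8, list(1:3, 4:6), 0.9)
  p2 <- gershgorin_subgroups(C2)
  expect_equal(p2$n_subgroups, 2)
  expect_setequal(unique(p2$membership[1:3]), p2$membership[1])
  expect_setequal(unique(p2$membership[4:6]), p2$membership[4])
  expect_true(p2$membership[1] != p2$membership[4])
  expect_equal(p2$membership[7:8], c("rest", "rest"))
})

test_that("detection is permutation-equivariant and validates its input", {
  C <- make_block_cor(7, list(2:5), 0.7, noise_sd = 0.03, seed = 4)
  p <- gershgorin_subgroups(C)
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  pp <- gershgorin_subgroups(C[perm, perm])
  expect_identical(pp$membership, p$membership[perm])
  bad <- C; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(gershgorin_subgroups(bad), "symmetric")
  bad2 <- C; diag(bad2) <- 0.9
  expect_error(gershgorin_subgroups(bad2), "unit diagonal")
})

test_that("noisy planted blocks are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  truth <- block_labels(12, list(1:4))
  aris <- vapply(1:20, function(s) {
    C <- make_block_cor(12, list(1:4), 0.6, noise_sd = 0.05, seed = 100 + s)
    p <- gershgorin_subgroups(C)
    mclust::adjustedRandIndex(p$membership, truth)
  }, 0)
  expect_gte(mean(aris >= 0.9), 0.9)
  expect_gte(stats::median(aris), 0.9)
})

test_that("modularity matches closed forms and beats shuffled labels", {
  C <- make_block_cor(8, list(1:4, 5:8), 0.8)
  truth <- block_labels(8, list(1:4, 5:8))
  expect_equal(modularity_score(C, truth), 0.5, tolerance = 1e-12)
  expect_equal(modularity_score(C, rep("SG1", 8)), 0)
  expect_equal(modularity_score(diag(8), truth), 0)
  set.seed(5)
  q_true <- modularity_score(C, truth)
  shuffled <- vapply(1:100, function(i) modularity_score(C, sample(truth)), 0)
  expect_true(all(shuffled <= q_true + 1e-12))
  expect_gt(mean(shuffled < q_true - 1e-12), 0.9)
})

test_that("modularity agrees with the igraph implementation", {
  skip_if_not_installed("igraph")
  C <- make_block_cor(10, list(1:4), 0.5, noise_sd = 0.1, seed = 6)
  labs <- block_labels(10, list(1:4))
  A <- abs(C); diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  q_ig <- igraph::modularity(g, as.integer(factor(labs)),
                             weights = igraph::E(g)$weight)
  expect_equal(modularity_score(C, labs), q_ig, tolerance = 1e-12)
})

test_that("SCV clustering recovers planted covariance patterns", {
  # single cluster: aggregate is the plain mean
  C_list <- lapply(1:3, function(i) make_block_cor(6, list(1:3), 0.5 + 0.1 * i))
  cl1 <- cluster_scvs(C_list, candidate_I = 1)
  expect_equal(cl1$aggregated[[1]], Reduce(`+`, C_list) / 3, tolerance = 1e-12)
  # two well-separated patterns
  Ca <- lapply(1:4, function(i) make_block_cor(8, list(1:4), 0.8,
                                               noise_sd = 0.02, seed = i))
  Cb <- lapply(1:4, function(i) make_block_cor(8, list(5:8), 0.8,
                                               noise_sd = 0.02, seed = 10 + i))
  cl2 <- cluster_scvs(c(Ca, Cb), candidate_I = 2, seed = 3)
  expect_equal(length(unique(cl2$assignments[1:4])), 1)
  expect_equal(length(unique(cl2$assignments[5:8])), 1)
  expect_true(cl2$assignments[1] != cl2$assignments[5])
  # duplicated matrices always co-cluster
  dup <- c(Ca[1], Ca[1], Cb[1], Cb[1])
  cl3 <- cluster_scvs(dup, candidate_I = 2, seed = 4)
  expect_equal(cl3$assignments[1], cl3$assignments[2])
  expect_equal(cl3$assignments[3], cl3$assignments[4])
})

test_that("cluster selection maximizes Gershgorin-partition modularity", {
  # two conflicting block patterns: averaging them blurs both, so the
  # modularity-based rule must prefer separating the clusters
  Ca <- lapply(1:3, function(i) make_block_cor(10, list(1:5), 0.8,
                                               noise_sd = 0.02, seed = 20 + i))
  Cb <- lapply(1:3, function(i) make_block_cor(10, list(4:8), 0.8,
                                               noise_sd = 0.02, seed = 30 + i))
  cl <- cluster_scvs(c(Ca, Cb), candidate_I = c(1, 2), seed = 5)
  expect_equal(cl$n_clusters, 2)
  expect_gt(cl$modularity_per_I[["2"]], cl$modularity_per_I[["1"]])
  expect_length(unique(cl$assignments[1:3]), 1)
  expect_length(unique(cl$assignments[4:6]), 1)
  expect_equal(cl$partition$n_subgroups, 1)
  sg <- which(cl$partition$membership == "SG1")
  expect_true(setequal(sg, 1:5) || setequal(sg, 4:8))
})
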