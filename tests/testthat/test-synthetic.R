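test_that("configuration invariants are enforced before sampling", {
  expect_error(simulation_config(K = 8, N = 3, V = 1000, rho_out = 0.9,
                                 blocks = list(list(subjects = 1:3,
                                                    rho_in = 0.5))),
               "rho_in")
  expect_error(simulation_config(K = 8, N = 3, V = 1000,
                                 blocks = list(list(subjects = 1:3, rho_in = 0.5),
                                               list(subjects = 3:5, rho_in = 0.5))),
               "disjoint")
  expect_error(simulation_config(K = 8, N = 3, V = 1000,
                                 reference_fidelity = 0), "0, 1")
  expect_error(simulation_config(K = 8, N = 3, V = 1000,
                                 blocks = list(list(subjects = 1:9,
                                                    rho_in = 0.5))),
               "out of range")
  expect_error(fsig_preset("huge"), "arg")
})

test_that("no planted structure yields near-zero realized correlations", {
  cfg <- simulation_config(K = 10, N = 2, V = 20000,
                           n_subgrouped_components = 2,
                           blocks = list(list(subjects = 1:4, rho_in = 0)),
                           rho_out = 0, seed = 4)
  sim <- generate_fsig_data(cfg)
  expect_lt(max(abs(sim$ground_truth$realized_block_correlation)), 0.05)
})

test_that("planted correlations survive the copula within tolerance", {
  cfg <- simulation_config(K = 12, N = 3, V = 20000,
                           n_subgrouped_components = 2,
                           blocks = list(list(subjects = 1:4, rho_in = 0.8)),
                           rho_out = 0, seed = 5)
  sim <- generate_fsig_data(cfg)
  r <- sim$ground_truth$realized_block_correlation
  expect_true(all(r > 0.7 & r < 0.9))
  # realized within-block mean correlation within 0.1 of the target
  expect_true(all(abs(r - 0.8) < 0.1))
})

test_that("references hit the requested fidelity", {
  cfg <- simulation_config(K = 6, N = 3, V = 5000, reference_fidelity = 1,
                           seed = 6)
  sim <- generate_fsig_data(cfg)
  for (n in 1:3)
    expect_equal(abs(cor(sim$references$R[n, ],
                         sim$ground_truth$mean_maps[n, ])), 1,
                 tolerance = 1e-12)
  cfg2 <- simulation_config(K = 6, N = 3, V = 20000,
                            reference_fidelity = 0.7, seed = 7)
  sim2 <- generate_fsig_data(cfg2)
  fids <- vapply(1:3, function(n)
    abs(cor(sim2$references$R[n, ], sim2$ground_truth$mean_maps[n, ])), 0)
  expect_equal(mean(fids), 0.7, tolerance = 0.05)
})

test_that("sources are non-Gaussian by construction", {
  cfg <- fsig_preset("tiny", seed = 8)
  sim <- generate_fsig_data(cfg)
  for (n in seq_len(cfg$N)) {
    kurt <- apply(sim$ground_truth$sources[[n]], 1,
                  function(y) mean(y^4) - 3)
    if (cfg$source_shape[n] != 2) expect_true(all(abs(kurt) > 0.5))
  }
})

test_that("ground-truth SCV covariance alone recovers the planted block", {
  # detector correctness isolated from ICA estimation error
  sim <- generate_fsig_data(fsig_preset("tiny", seed = 9))
  C <- scv_covariance(sim$ground_truth$sources[[1]])
  p <- gershgorin_subgroups(C)
  expect_equal(p$n_subgroups, 1)
  expect_setequal(which(p$membership == "SG1"), 1:3)
})

test_that("fixture writing is deterministic and complete", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  write_fixture("tiny", d1, seed = 3)
  write_fixture("tiny", d2, seed = 3)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_true(all(c("subj1.tsv", "references.tsv", "ground_truth.tsv",
                    "ground_truth.json") %in% f1))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$K, 8)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the stress preset is well-formed", {
  cfg <- fsig_preset("stress", seed = 1)
  expect_equal(cfg$K, 200)
  expect_equal(cfg$N, 20)
  expect_equal(length(cfg$blocks[[1]]$subjects), 50)
})
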