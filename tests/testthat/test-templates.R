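make_group_subjects <- function(K = 5, Tn = 40, V = 3000, n_maps = 6,
                                seed = 1, noise_sd = 0.05) {
  maps <- gen_sources(n_maps, V, seed = seed)
  subjects <- lapply(seq_len(K), function(k) {
    set.seed(seed + 10 * k)
    TC <- matrix(rnorm(Tn * n_maps), Tn, n_maps)
    TC %*% maps + matrix(rnorm(Tn * V, sd = noise_sd), Tn, V)
  })
  list(subjects = subjects, maps = maps)
}

test_that("group ICA-EBM recovers shared spatial maps", {
  fx <- make_group_subjects(seed = 11)
  dec <- suppressWarnings(group_ica_ebm(fx$subjects, model_order = 6,
                                        seed = 5, table = tab))
  cc <- abs(stats::cor(t(fx$maps), t(dec$group_maps)))
  expect_true(all(apply(cc, 1, max) > 0.9))
  expect_equal(dim(dec$group_maps), c(6, 3000))
  expect_length(dec$timecourses, 5)
  expect_equal(dim(dec$timecourses[[1]]), c(40, 6))
})

test_that("group decomposition validates its inputs and boundary orders", {
  fx <- make_group_subjects(K = 2, Tn = 12, V = 400, n_maps = 3, seed = 2)
  expect_error(group_ica_ebm(fx$subjects[1], model_order = 2),
               "at least 2")
  expect_error(group_ica_ebm(fx$subjects, model_order = 500), "rank")
  # full concatenated rank still runs
  dec <- suppressWarnings(group_ica_ebm(fx$subjects, model_order = 5,
                                        seed = 1, table = tab,
                                        max_sweeps = 64))
  expect_equal(dec$model_order, 5)
})

test_that("group decomposition is invariant to subject ordering", {
  fx <- make_group_subjects(K = 4, Tn = 30, V = 1500, n_maps = 4, seed = 3)
  d1 <- suppressWarnings(group_ica_ebm(fx$subjects, model_order = 4,
                                       seed = 9, table = tab))
  d2 <- suppressWarnings(group_ica_ebm(fx$subjects[c(3, 1, 4, 2)],
                                       model_order = 4, seed = 9, table = tab))
  cc <- abs(stats::cor(t(d1$group_maps), t(d2$group_maps)))
  expect_true(all(apply(cc, 1, max) > 0.999))
})

test_that("power ratio separates low- and high-frequency signals", {
  tr <- 2
  # 0.05 Hz sits exactly on a frequency bin for 160 samples at TR = 2 s,
  # so the low-frequency tone leaks no power into the high band
  t_axis <- seq(0, by = tr, length.out = 160)
  low <- sin(2 * pi * 0.05 * t_axis)
  high <- sin(2 * pi * 0.2 * t_axis)
  expect_equal(power_ratio(low, tr, 0.10, 0.15), Inf)
  expect_lt(power_ratio(high, tr, 0.10, 0.15), 0.01)
  # white noise: flat spectrum, ratio near the bandwidth ratio
  set.seed(4)
  ratios <- vapply(1:30, function(i)
    power_ratio(rnorm(4096), tr, 0.10, 0.15), 0)
  expected <- 0.10 / (0.25 - 0.15)
  expect_equal(mean(ratios), expected, tolerance = 0.2 * expected)
  expect_error(power_ratio(rnorm(8), tr), "length")
  expect_error(power_ratio(rnorm(64), tr, 0.2, 0.1), "Nyquist|low_cut")
})

test_that("RSN selection filters by spectral content, masks and overrides", {
  tr <- 2
  t_axis <- seq(0, by = tr, length.out = 64)
  tc <- cbind(sin(2 * pi * 0.03 * t_axis), sin(2 * pi * 0.05 * t_axis),
              sin(2 * pi * 0.08 * t_axis), sin(2 * pi * 0.18 * t_axis),
              sin(2 * pi * 0.2 * t_axis), sin(2 * pi * 0.22 * t_axis))
  set.seed(5)
  maps <- gen_sources(6, 500, seed = 6)
  dec <- structure(list(group_maps = maps, timecourses = list(tc, tc),
                        model_order = 6, run_seed = 1),
                   class = "group_decomposition")
  sel <- select_rsns(dec, min_power_ratio = 2, sampling_period = tr)
  expect_equal(sel$selected_indices, 1:3)
  expect_equal(select_rsns(dec, min_power_ratio = 0,
                           sampling_period = tr)$selected_indices, 1:6)
  expect_warning(
    none <- select_rsns(dec, min_power_ratio = Inf, sampling_period = tr),
    "no component")
  expect_length(none$selected_indices, 0)
  over <- select_rsns(dec, min_power_ratio = 2, sampling_period = tr,
                      override = list(include = 5, exclude = 1))
  expect_setequal(over$selected_indices, c(2, 3, 5))
  refs <- templates_as_references(dec, sel)
  expect_s3_class(refs, "reference_set")
  expect_equal(nrow(refs$R), 3)
  expect_equal(rowMeans(refs$R), rep(0, 3), tolerance = 1e-10)
})
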