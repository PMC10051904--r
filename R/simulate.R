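# Synthetic multi-subject generator with planted subgroup structure.
#
# Component n of all K subjects is drawn as a K-dimensional latent with a
# block covariance (rho_in inside planted subject blocks, rho_out elsewhere)
# through a Gaussian copula whose marginals are mapped to generalized
# Gaussian shapes, yielding correlated but non-Gaussian source component
# vectors.  Each subject's sources are mixed by a random square matrix of
# bounded condition number, and references are noisy across-subject mean
# maps.  The copula transform attenuates the target correlations, so the
# realized within-block correlations are measured and reported.

#' Simulation configuration
#'
#' @param K Number of subjects.
#' @param N Components per subject.
#' @param V Samples (voxels) per component.
#' @param n_subgrouped_components How many components (the first ones) carry
#'   the planted block structure.
#' @param blocks List of blocks, each a list with `subjects` (integer index
#'   set) and `rho_in` (within-block latent correlation); blocks must be
#'   disjoint.
#' @param rho_out Background latent correlation between all other subject
#'   pairs (networks are similar across all subjects; blocks are *more*
#'   similar).  Must satisfy `0 <= rho_out < rho_in <= 1`.
#' @param source_shape Generalized-Gaussian shape per component (2 =
#'   Gaussian; values below give heavy tails, above light tails).  Recycled
#'   to length `N`.  Defaults cycle through sub- and super-Gaussian shapes
#'   so every source is identifiably non-Gaussian.
#' @param mixing_condition Upper bound on the condition number of each
#'   subject's mixing matrix.
#' @param reference_fidelity Target correlation between each reference and
#'   the across-subject mean source map, in `(0, 1]` (1 = noiseless).
#' @param seed Integer master seed; sources, mixing and reference noise use
#'   named substreams derived from it.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(K, N, V, n_subgrouped_components = 1L,
                              blocks = list(list(subjects = 1:max(2, K %/% 4),
                                                 rho_in = 0.8)),
                              rho_out = 0.2,
                              source_shape = rep(c(1, 4, 1.5, 3),
                                                 length.out = N),
                              mixing_condition = 10,
                              reference_fidelity = 0.9,
                              seed = 1L) {
  stopifnot(K >= 2, N >= 2, V > N)
  source_shape <- rep(source_shape, length.out = N)
  if (any(source_shape <= 0)) stop("'source_shape' must be positive")
  if (reference_fidelity <= 0 || reference_fidelity > 1)
    stop("'reference_fidelity' must be in (0, 1]")
  all_block <- unlist(lapply(blocks, `[[`, "subjects"))
  if (anyDuplicated(all_block)) stop("blocks must be disjoint")
  if (any(all_block < 1 | all_block > K)) stop("block subject index out of range")
  for (b in blocks) {
    if (length(b$subjects) < 2) stop("each block needs at least 2 subjects")
    if (!(rho_out <= b$rho_in && b$rho_in <= 1) || b$rho_in < 0)
      stop("need 0 <= rho_out <= rho_in <= 1")
  }
  if (rho_out < 0 || rho_out > 1) stop("'rho_out' must be in [0, 1]")
  if (n_subgrouped_components < 0 || n_subgrouped_components > N)
    stop("'n_subgrouped_components' must be in [0, N]")
  if (mixing_condition < 1) stop("'mixing_condition' must be at least 1")
  structure(list(K = as.integer(K), N = as.integer(N), V = as.integer(V),
                 n_subgrouped_components = as.integer(n_subgrouped_components),
                 blocks = blocks, rho_out = rho_out,
                 source_shape = source_shape,
                 mixing_condition = mixing_condition,
                 reference_fidelity = reference_fidelity,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# generalized Gaussian with unit variance: density ~ exp(-|x/alpha|^beta)
gg_alpha <- function(beta) sqrt(gamma(1 / beta) / gamma(3 / beta))

#' Generalized-Gaussian quantile function (unit variance)
#'
#' @param p Probabilities.
#' @param beta Shape parameter (2 = Gaussian, 1 = Laplace).
#' @return Quantiles of the zero-mean unit-variance generalized Gaussian.
#' @export
q_generalized_gaussian <- function(p, beta) {
  a <- gg_alpha(beta)
  u <- 2 * abs(p - 0.5)
  u <- pmin(u, 1 - 1e-16)
  sign(p - 0.5) * a * stats::qgamma(u, shape = 1 / beta)^(1 / beta)
}

#' Random generalized-Gaussian deviates (unit variance)
#'
#' @param n Number of draws.
#' @param beta Shape parameter.
#' @export
r_generalized_gaussian <- function(n, beta) {
  q_generalized_gaussian(stats::runif(n), beta)
}

block_covariance <- function(config, component) {
  K <- config$K
  Sigma <- matrix(config$rho_out, K, K)
  diag(Sigma) <- 1
  if (component <= config$n_subgrouped_components) {
    for (b in config$blocks) {
      idx <- b$subjects
      Sigma[idx, idx] <- b$rho_in
      diag(Sigma)[idx] <- 1
    }
  }
  Sigma
}

random_bounded_condition <- function(N, cond) {
  Q1 <- random_orthogonal(N)
  Q2 <- random_orthogonal(N)
  s <- exp(seq(log(sqrt(cond)), log(1 / sqrt(cond)), length.out = N))
  Q1 %*% diag(s, N) %*% Q2
}

#' Generate a synthetic multi-subject dataset with planted subgroups
#'
#' @param config A [simulation_config()].
#' @return List with `subjects` (per subject the mixed `N x V` matrix `X`
#'   and `subject_id`), `references` (a [reference_set()]), and
#'   `ground_truth` (per-subject mixing `A` and sources `S`, per-component
#'   block labels, the noiseless mean maps, and the realized within-block
#'   mean correlation per structured component).
#' @export
#' @examples
#' \donttest{
#' sim <- generate_fsig_data(simulation_config(K = 6, N = 3, V = 2000, seed = 1))
#' sapply(sim$subjects, function(s) dim(s$X))
#' }
generate_fsig_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$K; N <- config$N; V <- config$V
  # feasibility of every component covariance before any sampling
  chols <- lapply(seq_len(N), function(n) {
    Sigma <- block_covariance(config, n)
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10)
      stop("correlation settings give a non-positive-semidefinite covariance")
    chol(Sigma + diag(1e-12, K))
  })

  set.seed(config$seed + 1L)  # substream: sources
  sources <- vector("list", N)    # per component: K x V
  for (n in seq_len(N)) {
    Z <- crossprod(chols[[n]], matrix(stats::rnorm(K * V), K, V))
    U <- stats::pnorm(Z)
    Sn <- matrix(q_generalized_gaussian(U, config$source_shape[n]), K, V)
    sources[[n]] <- standardize_rows(Sn)
  }

  set.seed(config$seed + 2L)  # substream: mixing
  A <- lapply(seq_len(K), function(k)
    random_bounded_condition(N, config$mixing_condition))

  set.seed(config$seed + 3L)  # substream: reference noise
  R <- matrix(0, N, V)
  means <- matrix(0, N, V)
  f <- config$reference_fidelity
  for (n in seq_len(N)) {
    m <- colMeans(sources[[n]])
    means[n, ] <- m
    if (f >= 1) {
      R[n, ] <- m
    } else {
      sigma <- stats::sd(m) * sqrt(1 / f^2 - 1)
      R[n, ] <- m + stats::rnorm(V, sd = sigma)
    }
  }

  subjects <- lapply(seq_len(K), function(k) {
    Sk <- do.call(rbind, lapply(sources, function(Sn) Sn[k, ]))
    list(X = A[[k]] %*% Sk, subject_id = paste0("subj", k))
  })

  block_labels <- rep("rest", K)
  for (i in seq_along(config$blocks))
    block_labels[config$blocks[[i]]$subjects] <- paste0("SG", i)
  realized <- vapply(seq_len(config$n_subgrouped_components), function(n) {
    cc <- stats::cor(t(sources[[n]]))
    vals <- unlist(lapply(config$blocks, function(b) {
      cb <- cc[b$subjects, b$subjects]
      cb[upper.tri(cb)]
    }))
    mean(vals)
  }, 0)

  list(subjects = subjects,
       references = reference_set(R, labels = paste0("src", seq_len(N))),
       ground_truth = list(A = A, sources = sources,
                           block_labels = block_labels,
                           mean_maps = means,
                           realized_block_correlation = realized,
                           config = config))
}

#' Named simulation presets
#'
#' `"tiny"` (K=8, N=4, V=5000) for smoke tests, `"standard"`
#' (K=40, N=10, V=20000, one block of 10 subjects at rho_in 0.8) matching
#' the package's reference study conditions, and `"stress"`
#' (K=200, N=20, V=20000) for large-K behavior.
#'
#' @param preset One of `"tiny"`, `"standard"`, `"stress"`.
#' @param seed Master seed.
#' @return A [simulation_config()].
#' @export
fsig_preset <- function(preset = c("tiny", "standard", "stress"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = simulation_config(K = 8, N = 4, V = 5000,
                             n_subgrouped_components = 2,
                             blocks = list(list(subjects = 1:3, rho_in = 0.8)),
                             rho_out = 0.2, seed = seed),
    standard = simulation_config(K = 40, N = 10, V = 20000,
                                 n_subgrouped_components = 3,
                                 blocks = list(list(subjects = 1:10,
                                                    rho_in = 0.8)),
                                 rho_out = 0.2, seed = seed),
    stress = simulation_config(K = 200, N = 20, V = 20000,
                               n_subgrouped_components = 5,
                               blocks = list(list(subjects = 1:50,
                                                  rho_in = 0.8)),
                               rho_out = 0.2, seed = seed))
}

#' Write a synthetic fixture dataset to disk
#'
#' Generates a preset dataset and writes it in the pipeline's native plain
#' formats: per-subject TSV data matrices, a reference TSV, and ground-truth
#' labels (TSV) plus a JSON sidecar with the configuration and realized
#' correlations.  Deterministic for a given seed.
#'
#' @param preset Preset name or a [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param seed Master seed (ignored when `preset` is already a config).
#' @return Invisibly, the directory path.
#' @export
write_fixture <- function(preset = "tiny", dir, seed = 1L) {
  config <- if (inherits(preset, "simulation_config")) preset
            else fsig_preset(preset, seed = seed)
  sim <- generate_fsig_data(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in sim$subjects)
    data.table::fwrite(data.table::as.data.table(s$X),
                       file.path(dir, paste0(s$subject_id, ".tsv")),
                       sep = "\t", col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(sim$references$R),
                     file.path(dir, "references.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(subject_id = vapply(sim$subjects,
                                                    `[[`, "", "subject_id"),
                                block = sim$ground_truth$block_labels),
                     file.path(dir, "ground_truth.tsv"), sep = "\t")
  meta <- unclass(config)
  meta$realized_block_correlation <- sim$ground_truth$realized_block_correlation
  jsonlite::write_json(meta, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
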