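# Shared fixtures, built in code.  The bound table is memoized inside the
# package environment, so the first test file to touch it pays the build
# cost once per session.

tab <- fsig::default_bound_table()

# independent non-Gaussian sources with distinct generalized-Gaussian shapes
gen_sources <- function(N, V, seed = 1,
                        shapes = rep(c(1, 4, 1.5, 3, 0.8), length.out = N)) {
  set.seed(seed)
  t(vapply(seq_len(N), function(n) {
    y <- r_generalized_gaussian(V, shapes[n])
    (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  }, numeric(V)))
}

# planted-block correlation matrix: blocks is a list of index vectors,
# rho the within-block correlation, background exactly zero plus optional
# symmetric Gaussian noise
make_block_cor <- function(K, blocks, rho, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- matrix(0, K, K)
  for (idx in blocks) C[idx, idx] <- rho
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(K * K, 0, noise_sd), K, K)
    C <- C + (E + t(E)) / 2
  }
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  C
}

block_labels <- function(K, blocks) {
  lab <- rep("rest", K)
  for (i in seq_along(blocks)) lab[blocks[[i]]] <- paste0("SG", i)
  lab
}

# global mixing-demixing product of a fit on whitened data
global_matrix <- function(fit, whitened, A) {
  fit$W %*% whitened$whitening_transform %*% A
}

# brute-force: is |G| a signed scaled permutation (one nonzero per row/col)?
is_signed_scaled_perm <- function(G, tol = 1e-8) {
  A <- abs(G) > tol * max(abs(G))
  all(rowSums(A) == 1) && all(colSums(A) == 1)
}

# Worst relative finite-difference error of the constrained row gradient
# against central differences of the augmented row cost, over random
# differentiable points.  The cost has measure-zero kinks — where the
# selected measuring function switches, where the penalty activates, and
# where a sample value of y crosses the |x| kink of G_2 — so points whose
# difference path straddles a kink are redrawn: the gradient claim is about
# differentiable points.
fd_gradient_worst <- function(seed, n_points = 20, h = 1e-6) {
  set.seed(seed)
  S <- gen_sources(4, 5000, seed = seed)
  X <- fsig::whiten(matrix(stats::rnorm(16), 4) %*% S)$X
  r <- stats::rnorm(5000)
  r_std <- (r - mean(r)) / sqrt(mean((r - mean(r))^2))
  worst <- 0
  got <- 0
  while (got < n_points) {
    W <- fsig:::random_orthogonal(4)
    w <- W[1, ] * stats::runif(1, 0.85, 1.2)
    d <- fsig::decoupling_vector(W, 1)
    mu <- stats::runif(1, 0, 2); th <- stats::runif(1)
    ga <- stats::runif(1, 1, 5)
    y <- drop(w %*% X)
    epsl <- mean(r_std * y)
    act <- ga * (th - abs(epsl)) + mu
    if (abs(act) < 5e-3 || abs(epsl) < 1e-3) next
    if (min(abs(y)) < 20 * h * max(abs(X))) next
    m_at <- function(wp) fsig:::negentropy_from_moments(
      fsig:::sample_moments(drop(wp %*% X)), tab)$m_star
    ms <- vapply(0:8, function(j) {
      if (j == 0) return(m_at(w))
      i <- (j - 1) %% 4 + 1; s <- if (j > 4) -h else h
      e <- rep(0, 4); e[i] <- s
      m_at(w + e)
    }, 0L)
    if (length(unique(ms)) > 1) next
    got <- got + 1
    g <- fsig::constrained_row_gradient(w, X, d, r, mu, ga, th, tab)
    fd <- vapply(1:4, function(i) {
      e <- rep(0, 4); e[i] <- h
      (fsig::cebm_row_cost(w + e, X, d, r, mu, ga, th, tab) -
       fsig::cebm_row_cost(w - e, X, d, r, mu, ga, th, tab)) / (2 * h)
    }, 0)
    worst <- max(worst, max(abs(g - fd)) / max(abs(fd)))
  }
  worst
}

# brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}
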