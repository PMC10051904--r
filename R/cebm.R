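# Constrained EBM: the decoupled row problem of ICA-EBM augmented with a
# reference-similarity inequality constraint handled by an augmented
# Lagrangian.  Each constrained row n must satisfy
#     h_n = theta_n - epsilon(r_n, y_n) <= 0,
# where epsilon is the absolute Pearson correlation between the estimate and
# its reference.  The slack variable of the equality reformulation is
# eliminated analytically, leaving the max-form penalty whose multiplier is
# updated once per sweep.

#' Reference set for constrained ICA
#'
#' Validates and standardizes a matrix of spatial reference maps (one row per
#' reference).  Rows are zero-meaned and scaled to unit (population)
#' variance, which makes the linear similarity term of the optimizer equal to
#' the Pearson correlation for unit-variance source estimates.
#'
#' @param R Numeric matrix, references by samples.
#' @param labels Optional character vector of reference names.
#' @return Object of class `reference_set` with standardized matrix `R` and
#'   `labels`.
#' @export
reference_set <- function(R, labels = rownames(R)) {
  if (!is.matrix(R) || !is.numeric(R)) stop("'R' must be a numeric matrix")
  if (anyNA(R)) stop("references contain missing values")
  sds <- apply(R, 1, stats::sd)
  if (any(sds == 0)) stop("reference(s) with zero variance: ",
                          paste(which(sds == 0), collapse = ", "))
  Rs <- standardize_rows(R)
  if (nrow(Rs) > 1) {
    cc <- stats::cor(t(Rs))
    diag(cc) <- 0
    if (any(abs(cc) >= 1 - 1e-12))
      stop("two references are perfectly correlated")
  }
  if (is.null(labels)) labels <- paste0("ref", seq_len(nrow(Rs)))
  structure(list(R = Rs, labels = labels), class = "reference_set")
}

# zero mean, unit population variance per row
standardize_rows <- function(M) {
  M <- M - rowMeans(M)
  s <- sqrt(rowMeans(M^2))
  if (any(s == 0)) stop("zero-variance row")
  M / s
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %d references x %d samples\n",
              nrow(x$R), ncol(x$R)))
  invisible(x)
}

#' Similarity between a reference and a source estimate
#'
#' The absolute Pearson correlation \eqn{\epsilon(r, y) = |corr(r, y)|}.
#'
#' @param r,y Numeric vectors of equal length with nonzero variance.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' similarity(1:10, 10:1)  # 1
similarity <- function(r, y) {
  if (length(r) != length(y)) stop("'r' and 'y' must have equal length")
  if (stats::sd(r) == 0 || stats::sd(y) == 0)
    stop("similarity undefined for zero-variance input")
  abs(stats::cor(r, y))
}

#' Inequality constraint value
#'
#' \eqn{h = \theta - \epsilon(r, y)}; the constraint is satisfied when
#' `h <= 0`.
#'
#' @param theta Constraint parameter in `[0, 1]`.
#' @inheritParams similarity
#' @return The scalar constraint value.
#' @export
constraint_value <- function(theta, r, y) {
  if (theta < 0 || theta > 1) stop("'theta' must be in [0, 1]")
  theta - similarity(r, y)
}

#' Augmented-Lagrangian multiplier update
#'
#' One multiplier step, `mu <- max(0, gamma * h + mu)`.
#'
#' @param mu Current multiplier (nonnegative).
#' @param h Current constraint value.
#' @param gamma Positive learning parameter.
#' @return Updated multiplier.
#' @export
#' @examples
#' update_multiplier(0.5, 0.1, 1)  # 0.6
update_multiplier <- function(mu, h, gamma) {
  if (any(mu < 0)) stop("'mu' must be nonnegative")
  if (gamma <= 0) stop("'gamma' must be positive")
  pmax(0, gamma * h + mu)
}

#' Augmented single-row cost of constrained EBM
#'
#' The decoupled row cost plus the augmented-Lagrangian penalty
#' \eqn{\frac{1}{2\gamma}(\max\{0, \gamma h + \mu\}^2 - \mu^2)}.
#' This is the exact primitive the row update differentiates: the moments are
#' taken on the raw estimate `y = w_n' X` and the similarity enters through
#' the linear surrogate \eqn{(1/V) \tilde r' y} (with \eqn{\tilde r} the
#' standardized reference), which equals the Pearson correlation whenever `y`
#' has unit sample variance — the normalization the optimizer maintains.
#'
#' @inheritParams decoupled_cost
#' @param r_n Reference vector (standardized internally).
#' @param mu_n Current multiplier.
#' @param gamma Penalty learning parameter.
#' @param theta Constraint parameter in `[0, 1]`.
#' @return Scalar cost in nats.
#' @export
cebm_row_cost <- function(w_n, X, d_n, r_n, mu_n, gamma, theta,
                          table = default_bound_table()) {
  X <- as_whitened_matrix(X)
  r <- drop(standardize_rows(matrix(r_n, 1)))
  y <- drop(w_n %*% X)
  ne <- negentropy_from_moments(sample_moments(y), table)
  dw <- sum(d_n * w_n)
  if (dw == 0) return(Inf)
  epsl <- sum(r * y) / length(y)
  coef <- max(0, gamma * (theta - abs(epsl)) + mu_n)
  -ne$value - log(abs(dw)) + (coef^2 - mu_n^2) / (2 * gamma)
}

#' Gradient of the augmented single-row cost
#'
#' The sum of (a) the negentropy term
#' \eqn{-O_m'\{E[G_m(y)]\}\, E[g_m(y) x]}, (b) the decoupling term
#' \eqn{-d_n / (d_n' w_n)}, and (c) the constraint term
#' \eqn{-\max(0, \gamma h + \mu)\, \mathrm{sign}(r' y)\, (1/V) X \tilde r},
#' which vanishes identically while the penalty is inactive.  This is the
#' exact gradient of [cebm_row_cost()].
#'
#' @inheritParams cebm_row_cost
#' @return Numeric gradient vector of length `N`.
#' @export
constrained_row_gradient <- function(w_n, X, d_n, r_n, mu_n, gamma, theta,
                                     table = default_bound_table()) {
  X <- as_whitened_matrix(X)
  V <- ncol(X)
  r <- drop(standardize_rows(matrix(r_n, 1)))
  y <- drop(w_n %*% X)
  t_m <- sample_moments(y)
  ne <- negentropy_from_moments(t_m, table)
  dw <- sum(d_n * w_n)
  if (dw == 0) stop("degenerate direction: d_n . w_n = 0")
  gvec <- evaluate_measuring_function(ne$m_star, y, deriv = TRUE)
  # entropy-bound parameterization: the negentropy term of the cost is
  # O_m(t) - const, hence +O_m'(t) in the gradient
  Op <- bound_value(table, ne$m_star, t_m[ne$m_star], deriv = TRUE,
                    quiet = TRUE)
  grad <- Op * drop(X %*% gvec) / V - d_n / dw
  epsl <- sum(r * y) / V
  coef <- max(0, gamma * (theta - abs(epsl)) + mu_n)
  if (coef > 0) grad <- grad - coef * sign(epsl) * drop(X %*% r) / V
  grad
}

#' Fit constrained EBM for one subject
#'
#' Row-wise ICA-EBM in which the first `nrow(references)` components are tied
#' to spatial reference maps by inequality constraints: reference `k`
#' constrains component `k`, and any remaining components are unconstrained.
#' Because every subject is fitted against the same references, component
#' order is aligned across subjects without post-hoc matching.  Subjects are
#' independent: fitting them in any order (or in parallel) with per-subject
#' seeds gives identical results.
#'
#' @inheritParams ica_ebm
#' @param references A [reference_set()] or a numeric matrix of reference
#'   maps (rows), at most `N` of them, each with nonzero variance.
#' @param theta Constraint parameter(s) in `[0, 1]`, scalar or one per
#'   constrained component.  Default 0.3: low enough to preserve
#'   inter-subject variability while still aligning components.
#' @param gamma Augmented-Lagrangian learning parameter (default 3).
#' @param init Initialization of the demixing matrix when `W0` is not
#'   given: `"reference"` (default) starts each constrained row at the
#'   matched filter of its reference in whitened space, which places the
#'   search inside the feasible basin of the constraint; `"random"` uses
#'   the seeded random orthogonal initialization of [ica_ebm()].
#' @return An object of class `c("cebm", "ica_ebm")`; in addition to the
#'   `ica_ebm` fields it carries `constraint` with `theta`, final multipliers
#'   `mu`, per-sweep similarity trace `epsilon_trace`, final per-component
#'   similarities `epsilon`, and satisfaction flags.
#' @export
cebm <- function(data, references, theta = 0.3, gamma = 3,
                 n_components = NULL, table = default_bound_table(),
                 W0 = NULL, init = c("reference", "random"),
                 max_sweeps = 512L, tol = 1e-6, seed = NULL,
                 restarts = 1L) {
  init <- match.arg(init)
  refs <- if (inherits(references, "reference_set")) references
          else reference_set(references)
  sd_obj <- prepare_subject(data, n_components)
  N <- nrow(sd_obj$X)
  n_ref <- nrow(refs$R)
  if (n_ref > N)
    stop(sprintf("more references (%d) than components (%d)", n_ref, N))
  if (ncol(refs$R) != ncol(sd_obj$X))
    stop("references and data must have the same number of samples")
  if (length(theta) == 1L) theta <- rep(theta, n_ref)
  if (length(theta) != n_ref) stop("'theta' must be scalar or one per reference")
  if (any(theta < 0 | theta > 1)) stop("'theta' must be in [0, 1]")
  if (gamma <= 0) stop("'gamma' must be positive")
  if (is.null(W0) && init == "reference") {
    if (!is.null(seed)) set.seed(seed)
    W0 <- reference_init(sd_obj$X, refs$R)
  }
  fit <- ebm_fit_restarts(sd_obj$X, table, refs = refs$R, theta = theta,
                          gamma = gamma, W0 = W0, max_sweeps = max_sweeps,
                          tol = tol, seed = seed, restarts = restarts)
  fit$whitening <- sd_obj$whitening
  fit$subject_id <- sd_obj$subject_id
  fit$reference_labels <- refs$labels
  class(fit) <- c("cebm", "ica_ebm")
  fit
}

# Default initialization for the constrained fit: each constrained row
# starts at the matched filter of its reference in whitened space (the
# direction maximizing the correlation with the reference), and the
# remaining rows at a random basis of the orthogonal complement.  This
# starts the optimization inside the feasible basin of each constraint.
reference_init <- function(X, R_std) {
  N <- nrow(X); V <- ncol(X)
  n_ref <- nrow(R_std)
  W0 <- matrix(0, N, N)
  for (n in seq_len(n_ref)) {
    w <- drop(tcrossprod(R_std[n, , drop = FALSE], X)) / V
    nw <- sqrt(sum(w^2))
    W0[n, ] <- if (nw > 0) w / nw else random_orthogonal(N)[1, ]
  }
  if (n_ref < N) {
    Q <- qr.Q(qr(cbind(t(W0[seq_len(n_ref), , drop = FALSE]),
                       matrix(stats::rnorm(N * (N - n_ref)), N))))
    W0[(n_ref + 1):N, ] <- t(Q[, (n_ref + 1):N, drop = FALSE])
  }
  # guard against (near-)collinear matched filters
  if (abs(det(W0)) < 1e-10) W0 <- W0 + 0.01 * random_orthogonal(N)
  W0
}

#' @export
plot.cebm <- function(x, which = c("epsilon", "cost"), ...) {
  which <- match.arg(which)
  if (which == "cost") return(NextMethod())
  tr <- x$constraint$epsilon_trace
  if (is.null(tr)) { warning("no similarity trace recorded"); return(invisible(x)) }
  graphics::matplot(tr, type = "l", lty = 1, xlab = "sweep",
                    ylab = "similarity epsilon", main = "c-EBM constraint trace",
                    ylim = c(0, 1), ...)
  graphics::abline(h = x$constraint$theta, lty = 3)
  invisible(x)
}
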