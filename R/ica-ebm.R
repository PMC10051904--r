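# ICA by entropy bound minimization with non-orthogonal row-wise decoupling.
#
# The mutual-information cost is minimized one demixing row at a time.  For
# row n the decoupling vector d_n (orthogonal to every other row) reduces the
# log-determinant regularizer to log|d_n' w_n|, so each row is optimized by
# gradient descent with a backtracking line search while the others are held
# fixed.  Rows are rescaled after every accepted step so the corresponding
# source estimate keeps unit sample variance, which removes the ICA scale
# ambiguity.

#' Decoupling vector for one demixing row
#'
#' Returns the unit vector spanning the one-dimensional null space of the
#' matrix of all demixing rows except row `n`, i.e. the direction orthogonal
#' to every other row.  The sign is chosen so that `d_n . w_n > 0`.
#'
#' @param W Square numeric demixing matrix (`N x N`).
#' @param n Row index to decouple.
#' @return Unit-norm numeric vector of length `N`.
#' @export
#' @examples
#' decoupling_vector(diag(3), 2)  # e2
decoupling_vector <- function(W, n) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("'W' must be a square matrix")
  N <- nrow(W)
  if (n < 1 || n > N) stop("row index 'n' out of range")
  Wm <- W[-n, , drop = FALSE]
  qr_t <- qr(t(Wm))
  if (qr_t$rank < N - 1)
    stop("degenerate demixing matrix: rows excluding row n do not have full rank")
  Q <- qr.Q(qr_t, complete = TRUE)
  d <- Q[, N]
  if (sum(d * W[n, ]) < 0) d <- -d
  d
}

#' Decoupled single-row ICA-EBM cost
#'
#' The cost of demixing row `w_n` with the other rows held fixed:
#' the negative EBM negentropy of the normalized source estimate minus
#' `log |d_n . w_n|` (additive constants dropped).  The source estimate
#' `y = w_n' X` is normalized to unit sample variance before the moment
#' evaluation.
#'
#' @param w_n Numeric row vector (length `N`).
#' @param X Whitened data (`N x V` matrix or `subject_data`).
#' @param d_n Decoupling vector for this row (see [decoupling_vector()]).
#' @param table Entropy-bound table.
#' @return The cost in nats, with attribute `m_star` giving the selected
#'   measuring function.  `d_n . w_n = 0` yields `+Inf`.
#' @export
decoupled_cost <- function(w_n, X, d_n, table = default_bound_table()) {
  X <- as_whitened_matrix(X)
  if (all(w_n == 0)) stop("'w_n' must be nonzero")
  y <- drop(w_n %*% X)
  y <- y - mean(y)
  s <- sqrt(mean(y^2))
  if (s == 0) stop("'w_n' yields a constant source estimate")
  y <- y / s
  ne <- negentropy_from_moments(sample_moments(y), table)
  dw <- sum(d_n * w_n)
  val <- if (dw == 0) Inf else -ne$value - log(abs(dw))
  structure(val, m_star = ne$m_star)
}

sample_moments <- function(y) {
  a <- abs(y)
  c(mean(y^4), mean(a / (1 + a)), mean(y * a / (10 + a)), mean(y / (1 + y^2)))
}

#' Fit single-dataset ICA by entropy bound minimization
#'
#' Cyclically optimizes each demixing row by gradient descent with a
#' backtracking (halving, Armijo-style) line search on the decoupled cost,
#' re-deriving the decoupling vectors every sweep.  Convergence is declared
#' when the largest angular change of any row direction,
#' `max_n (1 - |w_new . w_old|)` on unit vectors, falls below `tol`.
#'
#' @param data Whitened `N x V` matrix or a [whiten()] result; a raw matrix
#'   with non-identity covariance is whitened internally to `n_components`.
#' @param n_components Model order when whitening internally.
#' @param table Entropy-bound table.
#' @param W0 Optional initial demixing matrix; default is a seeded random
#'   orthogonal matrix.
#' @param max_sweeps Maximum number of full row sweeps.
#' @param tol Convergence tolerance on row directions.
#' @param seed Integer seed for the random initialization.
#' @param restarts Number of random restarts (best final cost wins).
#' @return An object of class `ica_ebm`: demixing matrix `W`, source
#'   estimates `S` (unit-variance rows), `decoupling_vectors`, per-sweep
#'   `cost_trace`, per-step line-search record `step_costs`, `converged`,
#'   `sweeps`, and `seed`.
#' @export
#' @examples
#' \donttest{
#' set.seed(1)
#' S <- rbind(runif(2000, -sqrt(3), sqrt(3)),
#'            rexp(2000) * sample(c(-1, 1), 2000, TRUE) / sqrt(2))
#' X <- matrix(rnorm(4), 2, 2) %*% S
#' fit <- ica_ebm(whiten(X), seed = 7)
#' fit$converged
#' }
ica_ebm <- function(data, n_components = NULL, table = default_bound_table(),
                    W0 = NULL, max_sweeps = 512L, tol = 1e-6, seed = NULL,
                    restarts = 1L) {
  sd_obj <- prepare_subject(data, n_components)
  fit <- ebm_fit_restarts(sd_obj$X, table, refs = NULL, theta = numeric(0),
                          gamma = 3, W0 = W0, max_sweeps = max_sweeps,
                          tol = tol, seed = seed, restarts = restarts)
  fit$whitening <- sd_obj$whitening
  fit$subject_id <- sd_obj$subject_id
  class(fit) <- "ica_ebm"
  fit
}

prepare_subject <- function(data, n_components = NULL) {
  if (inherits(data, "subject_data"))
    return(list(X = data$X, whitening = data, subject_id = data$subject_id))
  X <- as_whitened_matrix(data)
  if (anyNA(X)) stop("'data' contains missing values")
  V <- ncol(X)
  C <- tcrossprod(X - rowMeans(X)) / (V - 1)
  # treat data as already white when the sample covariance is close to the
  # identity (finite-sample noise on independent unit-variance rows is
  # O(1/sqrt(V)), well below this threshold for mixed data)
  if (max(abs(C - diag(nrow(X)))) > 0.03 ||
      (!is.null(n_components) && n_components < nrow(X))) {
    wd <- whiten(X, if (is.null(n_components)) nrow(X) else n_components)
    return(list(X = wd$X, whitening = wd, subject_id = NULL))
  }
  list(X = X, whitening = NULL, subject_id = NULL)
}

random_orthogonal <- function(N) {
  M <- matrix(stats::rnorm(N * N), N, N)
  q <- qr.Q(qr(M))
  q * sign(diag(qr.R(qr(M))))[col(q)]
}

ebm_fit_restarts <- function(X, table, refs, theta, gamma, W0, max_sweeps,
                             tol, seed, restarts) {
  restarts <- max(1L, as.integer(restarts))
  best <- NULL
  for (r in seq_len(restarts)) {
    W_init <- W0
    if (is.null(W_init)) {
      if (!is.null(seed)) set.seed(seed + r - 1L)
      W_init <- random_orthogonal(nrow(X))
    }
    fit <- ebm_core(X, table, refs, theta, gamma, W_init, max_sweeps, tol)
    fit$seed <- if (is.null(seed)) NA_integer_ else seed + r - 1L
    if (is.null(best) || fit$final_cost < best$final_cost) best <- fit
    if (!is.null(W0)) break
  }
  best
}

# Core cyclic row optimizer shared by ica_ebm() and cebm().  `refs` is a
# matrix of standardized references (zero mean, unit population variance,
# one row per constrained component) or NULL.
ebm_core <- function(X, table, refs = NULL, theta = numeric(0), gamma = 3,
                     W0 = NULL, max_sweeps = 512L, tol = 1e-6) {
  N <- nrow(X); V <- ncol(X)
  if (anyNA(X)) stop("input data contain missing values")
  n_ref <- if (is.null(refs)) 0L else nrow(refs)
  if (n_ref > 0 && length(theta) == 1L) theta <- rep(theta, n_ref)
  Cpop <- tcrossprod(X) / V
  XR <- if (n_ref > 0) tcrossprod(X, refs) / V else NULL  # N x n_ref
  W <- if (is.null(W0)) random_orthogonal(N) else W0
  if (!is.matrix(W) || any(dim(W) != N)) stop("'W0' must be an N x N matrix")

  if (max_sweeps <= 0) {
    return(finalize_fit(W, X, refs, XR, theta, mu = rep(0, n_ref), gamma,
                        converged = FALSE, sweeps = 0L,
                        cost_trace = numeric(0), steps = NULL,
                        eps_trace = NULL, table = table, normalized = FALSE))
  }

  normalize_row <- function(w) {
    v <- as.numeric(crossprod(w, Cpop %*% w))
    if (v <= 0) stop("degenerate demixing row (zero-variance estimate)")
    w / sqrt(v)
  }
  for (n in 1:N) W[n, ] <- normalize_row(W[n, ])

  mu <- rep(0, n_ref)
  step <- rep(0.25, N)
  cost_now <- rep(NA_real_, N)
  cost_trace <- numeric(0)
  eps_trace <- if (n_ref > 0) NULL else NULL
  eps_rows <- list()
  st_sweep <- st_row <- integer(0); st_before <- st_after <- numeric(0)
  converged <- FALSE
  sweeps_done <- 0L

  row_cost <- function(w, n, d) {
    y <- drop(w %*% X)
    ne <- negentropy_from_moments(sample_moments(y), table)
    dw <- sum(d * w)
    base <- if (dw == 0) Inf else -ne$value - log(abs(dw))
    if (n <= n_ref) {
      epsl <- sum(w * XR[, n])
      coef <- max(0, gamma * (theta[n] - abs(epsl)) + mu[n])
      base <- base + (coef^2 - mu[n]^2) / (2 * gamma)
    }
    base
  }

  for (sweep in seq_len(max_sweeps)) {
    W_prev <- W / sqrt(rowSums(W^2))
    for (n in 1:N) {
      d <- decoupling_vector(W, n)
      w <- W[n, ]
      y <- drop(w %*% X)
      t_m <- sample_moments(y)
      ne <- negentropy_from_moments(t_m, table)
      dw <- sum(d * w)
      gvec <- evaluate_measuring_function(ne$m_star, y, deriv = TRUE)
      # the table stores the entropy bound; the cost's negentropy term is
      # O_m(t) - const, so its gradient carries +O_m'(t)
      Op <- bound_value(table, ne$m_star, t_m[ne$m_star], deriv = TRUE,
                        quiet = TRUE)
      grad <- Op * drop(X %*% gvec) / V - d / dw
      pen0 <- 0
      if (n <= n_ref) {
        epsl <- sum(w * XR[, n])
        coef <- max(0, gamma * (theta[n] - abs(epsl)) + mu[n])
        if (coef > 0) grad <- grad - coef * sign(epsl) * XR[, n]
        pen0 <- (coef^2 - mu[n]^2) / (2 * gamma)
      }
      c0 <- -ne$value - log(abs(dw)) + pen0
      cost_now[n] <- c0
      # move along the tangential (projected) gradient direction on the
      # unit-variance sphere; step is arc length, searched from a per-row
      # adaptive start
      w_unit <- w / sqrt(sum(w^2))
      ghat <- grad - sum(grad * w_unit) * w_unit
      gn <- sqrt(sum(ghat^2))
      if (gn < 1e-14) next
      u <- ghat / gn
      s <- min(1, step[n] * 4)
      best_c <- Inf; best_w <- NULL; accepted <- FALSE
      for (ls in 1:30) {
        wc <- w - s * u
        v <- as.numeric(crossprod(wc, Cpop %*% wc))
        if (v > 1e-20) {
          wc <- wc / sqrt(v)
          cc <- row_cost(wc, n, d)
          if (is.finite(cc)) {
            if (cc <= c0 - 1e-4 * s * gn) {
              best_c <- cc; best_w <- wc; accepted <- TRUE; break
            }
            if (cc < best_c) { best_c <- cc; best_w <- wc }
          }
        }
        s <- s / 2
      }
      if (!accepted && is.finite(best_c) && best_c < c0) accepted <- TRUE
      if (accepted) {
        W[n, ] <- best_w
        step[n] <- max(s, 1e-12)
        cost_now[n] <- best_c
        st_sweep <- c(st_sweep, sweep); st_row <- c(st_row, n)
        st_before <- c(st_before, c0); st_after <- c(st_after, best_c)
      } else {
        step[n] <- max(step[n] / 2, 1e-12)
      }
    }
    if (n_ref > 0) {
      epsl <- vapply(1:n_ref, function(n) sum(W[n, ] * XR[, n]), 0)
      h <- theta - abs(epsl)
      mu <- pmax(0, gamma * h + mu)
      eps_rows[[sweep]] <- abs(epsl)
    }
    cost_trace <- c(cost_trace, sum(cost_now))
    sweeps_done <- sweep
    dirs <- W / sqrt(rowSums(W^2))
    delta <- max(1 - abs(rowSums(dirs * W_prev)))
    if (delta < tol) { converged <- TRUE; break }
  }

  steps <- data.frame(sweep = st_sweep, row = st_row,
                      cost_before = st_before, cost_after = st_after)
  eps_trace <- if (n_ref > 0) do.call(rbind, eps_rows) else NULL
  finalize_fit(W, X, refs, XR, theta, mu, gamma, converged, sweeps_done,
               cost_trace, steps, eps_trace, table, normalized = TRUE)
}

finalize_fit <- function(W, X, refs, XR, theta, mu, gamma, converged, sweeps,
                         cost_trace, steps, eps_trace, table,
                         normalized = TRUE) {
  N <- nrow(X); V <- ncol(X)
  n_ref <- if (is.null(refs)) 0L else nrow(refs)
  if (normalized) {
    # unit-variance source estimates; deterministic sign convention
    Y <- W %*% X
    for (n in 1:N) {
      s <- sqrt(mean(Y[n, ]^2))
      if (s > 0) { W[n, ] <- W[n, ] / s; Y[n, ] <- Y[n, ] / s }
      flip <- if (n <= n_ref) {
        sum(Y[n, ] * refs[n, ]) < 0
      } else {
        sk <- mean(Y[n, ]^3)
        if (abs(sk) > 1e-3) sk < 0 else Y[n, which.max(abs(Y[n, ]))] < 0
      }
      if (flip) { W[n, ] <- -W[n, ]; Y[n, ] <- -Y[n, ] }
    }
  } else {
    Y <- W %*% X
  }
  dvec <- try(t(vapply(1:N, function(n) decoupling_vector(W, n),
                       numeric(N))), silent = TRUE)
  if (inherits(dvec, "try-error")) dvec <- NULL
  out <- list(W = W, S = Y, decoupling_vectors = dvec,
              cost_trace = cost_trace, step_costs = steps,
              converged = converged, sweeps = sweeps,
              final_cost = if (length(cost_trace)) cost_trace[length(cost_trace)] else NA_real_)
  if (!converged && sweeps > 0)
    warning(sprintf("ICA-EBM did not converge within %d sweeps", sweeps),
            call. = FALSE)
  if (n_ref > 0) {
    eps <- vapply(1:n_ref, function(n)
      abs(stats::cor(Y[n, ], refs[n, ])), 0)
    out$constraint <- list(theta = theta, mu = mu, gamma = gamma,
                           epsilon = eps, epsilon_trace = eps_trace,
                           satisfied = eps >= theta - 1e-8)
  }
  out
}

#' @export
print.ica_ebm <- function(x, ...) {
  cat(sprintf("ICA-EBM fit: %d components, %d samples\n",
              nrow(x$S), ncol(x$S)))
  cat(sprintf("  sweeps: %d, converged: %s, final cost: %.4f\n",
              x$sweeps, x$converged, x$final_cost))
  if (!is.null(x$constraint)) {
    cat(sprintf("  constrained components: %d, similarity range: [%.3f, %.3f]\n",
                length(x$constraint$epsilon), min(x$constraint$epsilon),
                max(x$constraint$epsilon)))
    cat(sprintf("  constraints satisfied: %d / %d\n",
                sum(x$constraint$satisfied), length(x$constraint$satisfied)))
  }
  invisible(x)
}

#' @export
coef.ica_ebm <- function(object, ...) object$W

#' @export
fitted.ica_ebm <- function(object, ...) object$S

#' @export
plot.ica_ebm <- function(x, ...) {
  if (length(x$cost_trace) == 0) {
    warning("no cost trace recorded"); return(invisible(x))
  }
  graphics::plot(seq_along(x$cost_trace), x$cost_trace, type = "l",
                 xlab = "sweep", ylab = "total decoupled cost (nats)",
                 main = "ICA-EBM cost trace", ...)
  invisible(x)
}

#' @export
summary.ica_ebm <- function(object, ...) {
  kurt <- apply(object$S, 1, function(y) mean(y^4) - 3)
  out <- list(n_components = nrow(object$S), n_samples = ncol(object$S),
              converged = object$converged, sweeps = object$sweeps,
              excess_kurtosis = kurt, constraint = object$constraint)
  class(out) <- "summary.ica_ebm"
  out
}

#' @export
print.summary.ica_ebm <- function(x, ...) {
  cat(sprintf("ICA-EBM: %d components x %d samples (converged: %s, %d sweeps)\n",
              x$n_components, x$n_samples, x$converged, x$sweeps))
  cat("Excess kurtosis of source estimates:\n")
  print(round(x$excess_kurtosis, 3))
  if (!is.null(x$constraint)) {
    cat("Constraint similarity (epsilon) per constrained component:\n")
    print(round(x$constraint$epsilon, 3))
  }
  invisible(x)
}
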