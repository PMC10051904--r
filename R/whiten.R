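#' PCA whitening of a reduced data matrix
#'
#' Standard ICA preprocessing: rows are zero-meaned and the data are projected
#' onto the leading `n_components` principal axes, rescaled so that the sample
#' covariance of the output equals the identity.  The forward transform and
#' its back-projection are retained so that estimated spatial maps can be
#' taken back to the original row space.
#'
#' @param raw Numeric matrix, `P` variables (rows) by `V` samples (columns).
#' @param n_components Number of whitened components `N` to retain
#'   (default: `nrow(raw)`).
#' @param subject_id Optional label stored with the result.
#' @param mask_reference Optional voxel-space descriptor carried along for
#'   writing maps back to image space.
#' @return An object of class `subject_data`: list with the whitened `N x V`
#'   matrix `X`, the `whitening_transform` (`N x P`), the back-projection
#'   `dewhitening` (`P x N`), the removed `row_means`, and provenance fields.
#' @export
#' @examples
#' raw <- matrix(rnorm(5 * 400), 5, 400)
#' sd <- whiten(raw, 3)
#' round(tcrossprod(sd$X) / (400 - 1), 6)  # identity
whiten <- function(raw, n_components = nrow(raw), subject_id = NULL,
                   mask_reference = NULL) {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("'raw' must be a numeric matrix")
  if (anyNA(raw)) stop("'raw' contains missing values")
  P <- nrow(raw); V <- ncol(raw)
  if (n_components < 1 || n_components > P)
    stop("'n_components' must be between 1 and nrow(raw)")
  if (V <= n_components) stop("need more samples than components")
  mu <- rowMeans(raw)
  Xc <- raw - mu
  C <- tcrossprod(Xc) / (V - 1)
  eig <- eigen(C, symmetric = TRUE)
  tol <- max(eig$values) * 1e-10
  achievable <- sum(eig$values > tol)
  if (n_components > achievable)
    stop(sprintf("rank of 'raw' is %d; cannot whiten to %d components",
                 achievable, n_components))
  idx <- seq_len(n_components)
  d <- eig$values[idx]
  E <- eig$vectors[, idx, drop = FALSE]
  # canonical eigenvector signs (largest-magnitude loading positive) so the
  # transform is deterministic under row permutations of the input
  for (j in idx) {
    piv <- which.max(abs(E[, j]))
    if (E[piv, j] < 0) E[, j] <- -E[, j]
  }
  Tm <- diag(1 / sqrt(d), n_components) %*% t(E)
  structure(list(X = Tm %*% Xc,
                 whitening_transform = Tm,
                 dewhitening = E %*% diag(sqrt(d), n_components),
                 row_means = mu,
                 eigenvalues = eig$values,
                 subject_id = subject_id,
                 mask_reference = mask_reference),
            class = "subject_data")
}

# accept either a subject_data object or an already-whitened matrix
as_whitened_matrix <- function(data) {
  if (inherits(data, "subject_data")) return(data$X)
  if (is.matrix(data) && is.numeric(data)) return(data)
  stop("'data' must be a numeric matrix or a 'subject_data' object")
}

#' @export
print.subject_data <- function(x, ...) {
  cat(sprintf("Whitened subject data%s: %d components x %d samples\n",
              if (is.null(x$subject_id)) "" else paste0(" '", x$subject_id, "'"),
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
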