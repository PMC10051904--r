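# Subgroup identification from source component vectors (SCVs).
#
# The nth SCV stacks component n of every subject into a K x V matrix; its
# K x K correlation matrix encodes how similarly that functional network is
# expressed across subjects.  SCV covariances are clustered and aggregated,
# and homogeneous subject subgroups appear as diagonal blocks whose
# eigenvalues escape the smallest Gershgorin disc.

#' Stack aligned per-subject components into SCV matrices
#'
#' @param fits List of `cebm`/`ica_ebm` fits (or of `N x V` source matrices),
#'   one per subject, with components aligned across subjects.
#' @param references Optional [reference_set()] used to sign-align each
#'   subject's component to its reference (the similarity constraint uses an
#'   absolute correlation, so a subject's component may be sign-flipped
#'   relative to the others).  With `align_sign = FALSE` rows are stacked
#'   as-is.
#' @param align_sign Sign-align rows before stacking (default `TRUE`; aligns
#'   to the reference when given, otherwise to the first subject).
#' @param subject_ids Optional subject labels.
#' @return List of class `scv_matrix` objects, one per component: each has
#'   the standardized `K x V` matrix `Y`, `component_index`, `subject_ids`.
#' @export
scv_stack <- function(fits, references = NULL, align_sign = TRUE,
                      subject_ids = NULL) {
  Ss <- lapply(fits, function(f) if (inherits(f, "ica_ebm")) f$S else f)
  K <- length(Ss)
  if (K < 2) stop("need at least 2 subjects")
  N <- nrow(Ss[[1]]); V <- ncol(Ss[[1]])
  if (any(vapply(Ss, function(S) any(dim(S) != c(N, V)), TRUE)))
    stop("all subjects must share component count and sample count")
  if (is.null(subject_ids)) subject_ids <- paste0("subj", seq_len(K))
  R <- if (inherits(references, "reference_set")) references$R else references
  lapply(seq_len(N), function(n) {
    Y <- t(vapply(seq_len(K), function(k) Ss[[k]][n, ], numeric(V)))
    Y <- standardize_rows(Y)
    if (align_sign) {
      anchor <- if (!is.null(R) && n <= nrow(R)) R[n, ] else Y[1, ]
      sgn <- sign(Y %*% anchor)
      sgn[sgn == 0] <- 1
      Y <- Y * drop(sgn)
    }
    structure(list(Y = Y, component_index = n, subject_ids = subject_ids),
              class = "scv_matrix")
  })
}

#' Sample covariance (correlation) matrix of an SCV
#'
#' `C = Y Y' / (V - 1)` with rows standardized, then the diagonal normalized
#' to exactly one, giving the across-subject correlation matrix of one
#' functional network.
#'
#' @param Y An `scv_matrix` or a `K x V` numeric matrix.
#' @return Symmetric `K x K` matrix with unit diagonal.
#' @export
scv_covariance <- function(Y) {
  ids <- NULL
  if (inherits(Y, "scv_matrix")) { ids <- Y$subject_ids; Y <- Y$Y }
  if (!is.matrix(Y) || ncol(Y) < 2) stop("'Y' must be a K x V matrix, V >= 2")
  sds <- apply(Y, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("constant row(s) for subject(s): ", lab)
  }
  Ys <- (Y - rowMeans(Y)) / (sds * sqrt((ncol(Y) - 1) / ncol(Y)))
  C <- tcrossprod(Ys) / ncol(Y)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  if (!is.null(ids)) dimnames(C) <- list(ids, ids)
  C
}

check_correlation_matrix <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("'C' must be square")
  if (max(abs(C - t(C))) > 1e-8) stop("'C' must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8) stop("'C' must have unit diagonal")
  invisible(C)
}

#' Gershgorin-disc subgroup detection
#'
#' For a unit-diagonal correlation matrix every Gershgorin disc is centered
#' at 1 with radius \eqn{R_i = \sum_{j \ne i} |\rho_{ij}|}.  The number of
#' subgroups is the number of eigenvalues lying strictly outside the
#' smallest disc, i.e. `B = #\{lambda > R_min + 1\}`; the corresponding
#' eigenvectors identify the member subjects.  By default each of the `B`
#' outlying eigenvectors is 2-means-clustered on absolute loadings and the
#' high-loading cluster forms that subgroup ("per-eigenvector"); subjects
#' claimed by several eigenvectors go to the one where their absolute
#' loading is largest, and unclaimed subjects are labeled `"rest"`.  The
#' `"joint"` alternative clusters the rows of the `B` absolute eigenvector
#' loadings with (B+1)-means and labels the cluster with the smallest
#' centroid norm `"rest"`.
#'
#' @param C Correlation-form covariance matrix (symmetric, unit diagonal).
#' @param method Membership rule, `"per-eigenvector"` (default) or
#'   `"joint"`.
#' @param seed Seed for the k-means restarts.
#' @return Object of class `subgroup_partition`: Gershgorin `radii`,
#'   `r_min`, `eigenvalues` (descending), `n_subgroups`, `membership`
#'   (per subject, `"SG1", ..., "rest"`), block-`ordering` for reporting,
#'   eigenvector `loadings`, and Newman-Girvan `modularity` of the final
#'   partition.
#' @export
#' @examples
#' C <- diag(6); C[1:3, 1:3] <- 0.8; diag(C) <- 1
#' p <- gershgorin_subgroups(C)
#' p$n_subgroups   # 1
#' p$membership    # SG1 SG1 SG1 rest rest rest
gershgorin_subgroups <- function(C, method = c("per-eigenvector", "joint"),
                                 seed = 1L) {
  method <- match.arg(method)
  check_correlation_matrix(C)
  K <- nrow(C)
  radii <- rowSums(abs(C)) - 1
  r_min <- min(radii)
  eig <- eigen(C, symmetric = TRUE)
  B <- sum(eig$values > r_min + 1)
  membership <- rep("rest", K)
  loadings <- NULL
  if (B > 0) {
    loadings <- abs(eig$vectors[, seq_len(B), drop = FALSE])
    if (method == "per-eigenvector") {
      claims <- matrix(FALSE, K, B)
      for (b in seq_len(B)) {
        av <- loadings[, b]
        if (diff(range(av)) < 1e-12) { claims[, b] <- TRUE; next }
        set.seed(seed)
        km <- stats::kmeans(av, centers = rbind(min(av), max(av)))
        claims[, b] <- km$cluster == which.max(km$centers)
      }
      for (i in seq_len(K)) {
        cb <- which(claims[i, ])
        if (length(cb))
          membership[i] <- paste0("SG", cb[which.max(loadings[i, cb])])
      }
    } else {
      set.seed(seed)
      km <- stats::kmeans(loadings, centers = B + 1, nstart = 20)
      norms <- sqrt(rowSums(km$centers^2))
      rest_cl <- which.min(norms)
      ranks <- rank(-norms, ties.method = "first")
      for (i in seq_len(K))
        if (km$cluster[i] != rest_cl)
          membership[i] <- paste0("SG", ranks[km$cluster[i]])
    }
  }
  ordering <- order(factor(membership,
                           levels = c(paste0("SG", seq_len(max(B, 1))), "rest")),
                    -if (is.null(loadings)) rep(0, K) else
                      apply(loadings, 1, max))
  structure(list(radii = radii, r_min = r_min, eigenvalues = eig$values,
                 eigenvectors = eig$vectors,
                 n_subgroups = B, membership = membership,
                 ordering = ordering, loadings = loadings,
                 modularity = modularity_score(C, membership),
                 method = method),
            class = "subgroup_partition")
}

#' Newman-Girvan modularity of a subject partition
#'
#' Computed on the weighted graph with edge weights `|rho[i, j]|` (diagonal
#' excluded).  All subjects labeled `"rest"` form one community.  Returns 0
#' when all off-diagonal weights are zero.
#'
#' @param C Correlation-form covariance matrix.
#' @param labels Community label per subject.
#' @return Modularity `Q`.
#' @export
modularity_score <- function(C, labels) {
  check_correlation_matrix(C)
  K <- nrow(C)
  if (length(labels) != K) stop("'labels' must cover all subjects")
  A <- abs(C); diag(A) <- 0
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(labels, labels, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

#' Cluster SCV covariance matrices and select the best aggregation
#'
#' Step I of the subgroup workflow: the vectorized upper triangles of the
#' per-component covariance matrices are k-means clustered for each
#' candidate cluster count `I`; each cluster's matrices are averaged into an
#' aggregated matrix, scored by the modularity of its Gershgorin partition.
#' The candidate `I` — and the cluster within it — maximizing that
#' modularity is selected.
#'
#' @param covariances List of `K x K` correlation-form matrices (at least 2).
#' @param candidate_I Integer vector of candidate cluster counts, within
#'   `[1, length(covariances)]`.
#' @param seed Seed for k-means (20 restarts).
#' @param retry_cap Maximum reseeding attempts when k-means returns an empty
#'   cluster.
#' @return Object of class `scv_clustering`: `assignments` (component to
#'   cluster, for the selected `I`), `n_clusters`, per-cluster `aggregated`
#'   matrices, `modularity_per_I`, `best_cluster`, the winning
#'   `partition` (a [gershgorin_subgroups()] result), and `seed`.
#' @export
cluster_scvs <- function(covariances, candidate_I = seq_len(min(5, length(covariances))),
                         seed = 1L, retry_cap = 5L) {
  Ncomp <- length(covariances)
  if (Ncomp < 2) stop("need at least 2 component covariance matrices")
  lapply(covariances, check_correlation_matrix)
  if (any(candidate_I < 1 | candidate_I > Ncomp))
    stop("'candidate_I' must lie in [1, number of components]")
  K <- nrow(covariances[[1]])
  ut <- upper.tri(covariances[[1]])
  feats <- t(vapply(covariances, function(C) C[ut], numeric(sum(ut))))
  results <- list()
  for (I in sort(unique(candidate_I))) {
    if (I == 1) {
      cl <- rep(1L, Ncomp)
    } else if (I == Ncomp) {
      cl <- seq_len(Ncomp)
    } else {
      cl <- NULL
      for (attempt in 0:retry_cap) {
        set.seed(seed + attempt)
        km <- suppressWarnings(stats::kmeans(feats, centers = I, nstart = 20))
        if (all(tabulate(km$cluster, I) > 0)) { cl <- km$cluster; break }
      }
      if (is.null(cl)) stop("k-means produced an empty cluster repeatedly")
    }
    agg <- lapply(seq_len(I), function(i) {
      M <- Reduce(`+`, covariances[cl == i]) / sum(cl == i)
      (M + t(M)) / 2
    })
    parts <- lapply(agg, gershgorin_subgroups, seed = seed)
    Qs <- vapply(parts, `[[`, 0, "modularity")
    results[[as.character(I)]] <- list(I = I, cl = cl, agg = agg,
                                       parts = parts, Q = max(Qs),
                                       best = which.max(Qs))
  }
  Q_per_I <- vapply(results, `[[`, 0, "Q")
  win <- results[[which.max(Q_per_I)]]
  structure(list(assignments = win$cl, n_clusters = win$I,
                 aggregated = win$agg,
                 modularity_per_I = stats::setNames(Q_per_I, names(results)),
                 best_cluster = win$best,
                 partition = win$parts[[win$best]],
                 seed = seed),
            class = "scv_clustering")
}

#' @export
print.scv_clustering <- function(x, ...) {
  cat(sprintf("SCV clustering: %d components into %d cluster(s)\n",
              length(x$assignments), x$n_clusters))
  cat(sprintf("  modularity by candidate I: %s\n",
              paste(sprintf("%s=%.3f", names(x$modularity_per_I),
                            x$modularity_per_I), collapse = ", ")))
  cat(sprintf("  selected cluster %d; detected subgroups: %d\n",
              x$best_cluster, x$partition$n_subgroups))
  invisible(x)
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("Gershgorin subgroup partition: K = %d subjects\n",
              length(x$membership)))
  cat(sprintf("  R_min = %.4f; eigenvalues above R_min + 1: %d\n",
              x$r_min, x$n_subgroups))
  tab <- table(x$membership)
  cat("  membership: ", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  cat(sprintf("  modularity Q = %.4f\n", x$modularity))
  invisible(x)
}

#' @export
plot.subgroup_partition <- function(x, C = NULL, ...) {
  if (is.null(C)) {
    graphics::plot(seq_along(x$eigenvalues), sort(x$eigenvalues, TRUE),
                   xlab = "index", ylab = "eigenvalue",
                   main = "Eigenspectrum vs smallest Gershgorin disc", ...)
    graphics::abline(h = x$r_min + 1, lty = 2)
  } else {
    o <- x$ordering
    graphics::image(abs(C[o, o])[, rev(seq_len(ncol(C)))],
                    main = "Permuted |covariance|", axes = FALSE, ...)
  }
  invisible(x)
}
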