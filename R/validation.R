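# Statistical validation of identified subgroups: voxelwise two-sample
# t-maps with FDR correction and the |t|-weighted global difference map.

#' Voxelwise two-sample t-map
#'
#' Pooled-variance (Student) two-sample t statistic at every voxel, two-sided
#' p-values, Benjamini-Hochberg correction, and a map-level summary
#' statistic `t_q` (by default the t value at the peak `|t|` voxel of the
#' significant mask; `summary = "mean"` uses the mean `|t|` over significant
#' voxels instead).  Voxels with zero pooled variance get `t = 0` and are
#' counted in `n_zero_variance`.
#'
#' @param maps_g1,maps_g2 Numeric matrices, subjects (rows) by voxels, one
#'   per group; each group needs at least 2 subjects.
#' @param q FDR level for the significance mask (default 0.05).
#' @param summary Map-level summary rule for `t_q`.
#' @param component_index Optional component label carried in the result.
#' @return Object of class `tmap_result`: `t_values`, `p_values`,
#'   `q_values`, logical `significant_mask`, `t_q`, `peak_voxel`,
#'   `group_sizes`, `n_zero_variance`.
#' @export
two_sample_tmap <- function(maps_g1, maps_g2, q = 0.05,
                            summary = c("peak", "mean"),
                            component_index = NULL) {
  summary <- match.arg(summary)
  if (!is.matrix(maps_g1)) maps_g1 <- matrix(maps_g1, nrow = 1)
  if (!is.matrix(maps_g2)) maps_g2 <- matrix(maps_g2, nrow = 1)
  n1 <- nrow(maps_g1); n2 <- nrow(maps_g2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  if (ncol(maps_g1) != ncol(maps_g2)) stop("groups must share the voxel grid")
  m1 <- colMeans(maps_g1); m2 <- colMeans(maps_g2)
  ss1 <- colSums(maps_g1^2) - n1 * m1^2
  ss2 <- colSums(maps_g2^2) - n2 * m2^2
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_values <- ifelse(se > 0, (m1 - m2) / se, 0)
  nzv <- sum(se <= 0)
  if (nzv > 0)
    warning(sprintf("%d voxel(s) with zero pooled variance set to t = 0", nzv))
  p_values <- 2 * stats::pt(-abs(t_values), df)
  fdr <- fdr_correct(p_values, q)
  sig <- fdr$significant_mask
  if (any(sig)) {
    peak <- which(sig)[which.max(abs(t_values[sig]))]
    t_q <- if (summary == "peak") t_values[peak] else mean(abs(t_values[sig]))
  } else {
    peak <- NA_integer_
    t_q <- 0
  }
  structure(list(component_index = component_index, t_values = t_values,
                 p_values = p_values, q_values = fdr$q_values,
                 significant_mask = sig, t_q = t_q, peak_voxel = peak,
                 peak_t = t_values[which.max(abs(t_values))],
                 group_sizes = c(n1, n2), df = df,
                 n_zero_variance = nzv),
            class = "tmap_result")
}

#' @export
print.tmap_result <- function(x, ...) {
  cat(sprintf("Two-sample t-map%s: %d voxels, groups %d vs %d (df = %d)\n",
              if (is.null(x$component_index)) ""
              else sprintf(" (component %d)", x$component_index),
              length(x$t_values), x$group_sizes[1], x$group_sizes[2], x$df))
  cat(sprintf("  significant voxels: %d; t_q = %.3f\n",
              sum(x$significant_mask), x$t_q))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR control: adjusted q-values and the rejection mask at level
#' `q`.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param q FDR level in `(0, 1)`.
#' @return List with `q_values` (monotone in the sorted order and elementwise
#'   at least the p-values) and logical `significant_mask`.
#' @export
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.2), 0.05)$significant_mask  # TRUE TRUE FALSE
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
  q_values <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q_values, significant_mask = q_values <= q)
}

#' Global difference map
#'
#' Summarizes the discriminative anatomy of several component t-maps as the
#' weighted sum \eqn{T_{GDM} = \sum_q \frac{|t_q|}{\sum_l |t_l|} T_q},
#' with weights from the map-level summary statistics (nonnegative, summing
#' to one).  The absolute value is used in the denominator as well so the
#' weights form a convex combination.
#'
#' @param tmaps List of [two_sample_tmap()] results, or of lists with fields
#'   `t_values` and `t_q`.  At least one map must have a nonzero `t_q`.
#' @return Object of class `gdm_result`: `map`, `weights`,
#'   `contributing_components`.
#' @export
global_difference_map <- function(tmaps) {
  if (length(tmaps) == 0) stop("need at least one t-map")
  tq <- vapply(tmaps, function(m) abs(m$t_q), 0)
  if (all(tq == 0)) stop("all t-maps have zero summary statistic")
  weights <- tq / sum(tq)
  V <- length(tmaps[[1]]$t_values)
  map <- numeric(V)
  for (i in seq_along(tmaps)) map <- map + weights[i] * tmaps[[i]]$t_values
  idx <- vapply(seq_along(tmaps), function(i) {
    ci <- tmaps[[i]]$component_index
    if (is.null(ci)) i else ci
  }, 0)
  structure(list(map = map, weights = weights,
                 contributing_components = idx),
            class = "gdm_result")
}

#' @export
print.gdm_result <- function(x, ...) {
  cat(sprintf("Global difference map over %d component(s)\n", length(x$weights)))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Compare subject covariates across identified subgroups
#'
#' Generic validation of a partition against external per-subject scores:
#' per-score two-sample t-tests between a subgroup and the remaining
#' subjects, plus a multivariate analysis of variance over all scores.
#'
#' @param scores Numeric matrix or data frame, subjects by scores.
#' @param membership Character vector of subgroup labels per subject.
#' @param group Label of the subgroup to contrast against all other subjects
#'   (default the first non-"rest" label).
#' @return List with per-score data frame `tests` (mean difference, t, p)
#'   and `manova_p` (NA when fewer than 2 scores).
#' @export
compare_covariates <- function(scores, membership, group = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(membership))
    stop("'scores' and 'membership' must cover the same subjects")
  labs <- setdiff(unique(membership), "rest")
  if (is.null(group)) group <- labs[1]
  g <- membership == group
  if (sum(g) < 2 || sum(!g) < 2) stop("both groups need at least 2 subjects")
  tests <- do.call(rbind, lapply(seq_len(ncol(scores)), function(j) {
    tt <- stats::t.test(scores[g, j], scores[!g, j], var.equal = TRUE)
    data.frame(score = colnames(scores)[j] %||% paste0("score", j),
               mean_diff = unname(diff(rev(tt$estimate))),
               t = unname(tt$statistic), p = tt$p.value)
  }))
  manova_p <- NA_real_
  if (ncol(scores) >= 2) {
    fit <- stats::manova(scores ~ factor(g))
    manova_p <- summary(fit)$stats[1, "Pr(>F)"]
  }
  list(tests = tests, manova_p = manova_p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
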