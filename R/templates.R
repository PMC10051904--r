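# Group-level template generation: two-level PCA followed by ICA-EBM on the
# concatenated reduced data, and selection of resting-state-network-like
# components by spectral power ratio and spatial criteria.

#' Group ICA-EBM over multiple subjects
#'
#' First-level PCA reduces each subject's (time x voxel) data to an
#' intermediate order; the reduced data are concatenated across subjects and
#' a second-level PCA whitens them to `model_order`; ICA-EBM on the group
#' data then yields group spatial maps.  Group-level component time courses
#' are recovered per subject by back-projecting the mixing matrix through
#' both PCA levels, which supports the spectral screening of
#' [select_rsns()] without subject-map back-reconstruction.
#'
#' @param subjects List (at least 2) of numeric matrices, time points by
#'   voxels, sharing the voxel dimension.
#' @param model_order Number of group components.
#' @param intermediate_order First-level PCA order per subject (default
#'   `ceiling(1.5 * model_order)`, capped by each subject's rank).
#' @param seed,table,max_sweeps,tol Passed to [ica_ebm()].
#' @return Object of class `group_decomposition`: `group_maps`
#'   (`model_order x V`, rows zero-meaned unit-variance),
#'   `timecourses` (list, per subject a `T_k x model_order` matrix),
#'   `model_order`, `run_seed`.
#' @export
group_ica_ebm <- function(subjects, model_order,
                          intermediate_order = ceiling(1.5 * model_order),
                          seed = 1L, table = default_bound_table(),
                          max_sweeps = 512L, tol = 1e-6) {
  if (!is.list(subjects) || length(subjects) < 2)
    stop("need at least 2 subjects")
  V <- ncol(subjects[[1]])
  if (any(vapply(subjects, ncol, 0L) != V))
    stop("all subjects must share the voxel dimension")
  K <- length(subjects)
  level1 <- lapply(subjects, function(Xk) {
    Xk <- Xk - rowMeans(Xk)
    sv <- svd(Xk)
    rank_k <- sum(sv$d > max(sv$d) * 1e-10)
    ord <- min(intermediate_order, rank_k)
    # PCA scores over voxels (ord x V) and the time basis for back-projection
    list(scores = diag(sv$d[1:ord], ord) %*% t(sv$v[, 1:ord, drop = FALSE]),
         time_basis = sv$u[, 1:ord, drop = FALSE])
  })
  G <- do.call(rbind, lapply(level1, `[[`, "scores"))
  if (model_order > nrow(G))
    stop(sprintf("model order %d exceeds concatenated rank %d",
                 model_order, nrow(G)))
  wd <- whiten(G, model_order)
  fit <- ica_ebm(wd, table = table, max_sweeps = max_sweeps, tol = tol,
                 seed = seed)
  maps <- standardize_rows(fit$S)
  # loadings of concatenated reduced rows on components: G ~ M %*% maps
  M <- wd$dewhitening %*% solve(fit$W)
  offsets <- c(0, cumsum(vapply(level1, function(l) nrow(l$scores), 0L)))
  timecourses <- lapply(seq_len(K), function(k) {
    rows <- (offsets[k] + 1):offsets[k + 1]
    level1[[k]]$time_basis %*% M[rows, , drop = FALSE]
  })
  structure(list(group_maps = maps, timecourses = timecourses,
                 model_order = model_order, run_seed = seed,
                 subject_orders = vapply(level1, function(l) nrow(l$scores), 0L),
                 fit = fit),
            class = "group_decomposition")
}

#' @export
print.group_decomposition <- function(x, ...) {
  cat(sprintf("Group ICA-EBM decomposition: order %d, %d subjects, %d voxels\n",
              x$model_order, length(x$timecourses), ncol(x$group_maps)))
  invisible(x)
}

#' Low/high frequency power ratio of a component time course
#'
#' Spectral power in the band `(0, low_cut]` divided by power in
#' `[high_cut, Nyquist]`, computed from the periodogram.  BOLD-plausible
#' resting-state components concentrate power at low frequencies, so large
#' ratios indicate plausible networks.  A zero high-band power yields
#' `+Inf`.
#'
#' @param timecourse Numeric vector, length at least 16.
#' @param sampling_period Sampling interval (seconds), e.g. the repetition
#'   time of the scan.
#' @param low_cut,high_cut Band edges in Hz with
#'   `low_cut < high_cut < Nyquist`.
#' @return Nonnegative scalar (possibly `Inf`).
#' @export
power_ratio <- function(timecourse, sampling_period, low_cut = 0.10,
                        high_cut = 0.15) {
  n <- length(timecourse)
  if (n < 16) stop("'timecourse' must have length at least 16")
  nyquist <- 1 / (2 * sampling_period)
  if (!(low_cut < high_cut && high_cut < nyquist))
    stop("need low_cut < high_cut < Nyquist frequency")
  x <- timecourse - mean(timecourse)
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * sampling_period)
  half <- which(freqs > 0 & freqs <= nyquist + 1e-12)
  p_low <- sum(spec[half][freqs[half] <= low_cut])
  p_high <- sum(spec[half][freqs[half] >= high_cut])
  # high-band power at floating-point noise level counts as zero
  if (p_high <= 1e-12 * (p_low + p_high)) return(Inf)
  p_low / p_high
}

#' Select resting-state-network components from a group decomposition
#'
#' Deterministic screening of group components into template candidates:
#' keep components whose (subject-averaged) low/high power ratio meets
#' `min_power_ratio` and whose peak activation voxel falls inside
#' `include_mask` and outside `exclude_mask`; an explicit `override` list
#' adds or removes components from the automatic choice, mirroring the
#' manual-inspection step of template curation.
#'
#' @param decomp A [group_ica_ebm()] result.
#' @param min_power_ratio Minimum power ratio (default 0: no spectral
#'   filter).
#' @param sampling_period,low_cut,high_cut Passed to [power_ratio()].
#' @param include_mask,exclude_mask Optional logical vectors over voxels.
#' @param override Optional list with integer vectors `include` and/or
#'   `exclude` forcing the final status of specific components.
#' @param labels Optional functional-area tags for the selected components.
#' @return Object of class `rsn_selection`: `selected_indices`,
#'   `power_ratio` per component, `labels`.
#' @export
select_rsns <- function(decomp, min_power_ratio = 0, sampling_period = 2,
                        low_cut = 0.10, high_cut = 0.15,
                        include_mask = NULL, exclude_mask = NULL,
                        override = NULL, labels = NULL) {
  stopifnot(inherits(decomp, "group_decomposition"))
  n <- decomp$model_order
  pr <- vapply(seq_len(n), function(cmp) {
    per_subj <- vapply(decomp$timecourses, function(tc)
      power_ratio(tc[, cmp], sampling_period, low_cut, high_cut), 0)
    mean(per_subj)
  }, 0)
  keep <- pr >= min_power_ratio
  peaks <- apply(abs(decomp$group_maps), 1, which.max)
  if (!is.null(include_mask)) keep <- keep & include_mask[peaks]
  if (!is.null(exclude_mask)) keep <- keep & !exclude_mask[peaks]
  if (!is.null(override$include)) keep[override$include] <- TRUE
  if (!is.null(override$exclude)) keep[override$exclude] <- FALSE
  sel <- which(keep)
  if (length(sel) == 0) warning("no component passed the selection criteria")
  if (is.null(labels)) labels <- paste0("RSN", seq_along(sel))
  structure(list(selected_indices = sel, power_ratio = pr, labels = labels),
            class = "rsn_selection")
}

#' @export
print.rsn_selection <- function(x, ...) {
  cat(sprintf("RSN selection: %d component(s) selected\n",
              length(x$selected_indices)))
  if (length(x$selected_indices))
    cat("  indices:", paste(x$selected_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a reference set of templates from a group decomposition
#'
#' Hands the selected group maps to the constrained fit as a validated,
#' standardized [reference_set()].
#'
#' @param decomp A [group_ica_ebm()] result.
#' @param selection An [select_rsns()] result (default: all components).
#' @return A [reference_set()].
#' @export
templates_as_references <- function(decomp, selection = NULL) {
  idx <- if (is.null(selection)) seq_len(decomp$model_order)
         else selection$selected_indices
  labels <- if (is.null(selection)) paste0("IC", idx) else selection$labels
  reference_set(decomp$group_maps[idx, , drop = FALSE], labels = labels)
}
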