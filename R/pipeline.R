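# Pipeline orchestration and imaging I/O.  The full flow: templates (group
# ICA-EBM on an independent dataset) -> per-subject constrained EBM against
# the shared templates -> SCV covariance -> clustering + Gershgorin subgroup
# detection -> validation statistics.

#' Load a masked 4D fMRI volume as a time-by-voxel matrix
#'
#' Voxels where the mask is positive are vectorized in the mask array's
#' native storage order, which is fixed and recorded through `voxel_index`
#' so that maps can be written back to image space losslessly.
#'
#' @param path Path to a 4D NIfTI file.
#' @param mask_path Path to a 3D NIfTI mask on the same grid.
#' @param affine_tol Tolerance for comparing the two affines.
#' @return Object of class `fmri_matrix`: `data` (time x voxels),
#'   `voxel_index`, `mask_dim`, and the mask image for write-back.
#' @export
load_fmri <- function(path, mask_path, affine_tol = 1e-4) {
  img <- RNifti::readNifti(path)
  mask <- RNifti::readNifti(mask_path)
  di <- dim(img); dm <- dim(mask)
  if (length(di) != 4) stop("'path' must be a 4D volume")
  if (length(dm) != 3 || any(di[1:3] != dm))
    stop("mask grid does not match the data grid")
  if (max(abs(RNifti::xform(img) - RNifti::xform(mask))) > affine_tol)
    stop("mask affine does not match the data affine")
  idx <- which(as.array(mask) > 0)
  if (length(idx) == 0) stop("empty mask")
  vol <- matrix(as.array(img), prod(dm), di[4])
  structure(list(data = t(vol[idx, , drop = FALSE]), voxel_index = idx,
                 mask_dim = dm, mask = mask),
            class = "fmri_matrix")
}

#' Write a voxel vector back into mask space as a 3D NIfTI map
#'
#' @param values Numeric vector, one value per mask voxel (in the order of
#'   `voxel_index`).
#' @param geometry An `fmri_matrix` (from [load_fmri()]) providing the mask
#'   geometry.
#' @param path Output NIfTI path.
#' @return Invisibly, the path.
#' @export
write_brain_map <- function(values, geometry, path) {
  stopifnot(inherits(geometry, "fmri_matrix"))
  if (length(values) != length(geometry$voxel_index))
    stop("'values' must have one entry per mask voxel")
  arr <- array(0, dim = geometry$mask_dim)
  arr[geometry$voxel_index] <- values
  RNifti::writeNifti(RNifti::asNifti(arr, reference = geometry$mask), path)
  invisible(path)
}

#' Fit the full subgroup-identification model in memory
#'
#' The flagship fitting function: applies constrained EBM to every subject
#' independently against shared reference templates, stacks the aligned
#' components into SCVs, clusters their covariance matrices, and detects
#' homogeneous subgroups from the selected aggregated matrix with the
#' Gershgorin-disc rule.
#'
#' @param subjects List of per-subject data matrices (`N x V` or richer) or
#'   `subject_data` objects; entries may also be lists with fields `X` and
#'   `subject_id` as produced by [generate_fsig_data()].
#' @param references A [reference_set()] or reference matrix shared by all
#'   subjects.
#' @param theta,gamma Constraint parameters passed to [cebm()].
#' @param n_components Model order per subject (default: number of rows).
#' @param candidate_I Candidate SCV cluster counts for [cluster_scvs()].
#' @param seed Base seed; subject `k` uses `seed + k`, making the fit
#'   order-independent and parallelizable.
#' @param max_sweeps,tol,table Optimizer settings passed to [cebm()].
#' @param verbose Print progress.
#' @return Object of class `fsig`: per-subject `fits`, `scvs`,
#'   `covariances`, `clustering`, the winning `partition`, a `membership`
#'   data frame, and `settings`.
#' @export
fsig <- function(subjects, references, theta = 0.3, gamma = 3,
                 n_components = NULL, candidate_I = NULL, seed = 1L,
                 max_sweeps = 512L, tol = 1e-6,
                 table = default_bound_table(), verbose = FALSE) {
  refs <- if (inherits(references, "reference_set")) references
          else reference_set(references)
  K <- length(subjects)
  if (K < 2) stop("need at least 2 subjects")
  ids <- vapply(seq_len(K), function(k) {
    s <- subjects[[k]]
    if (is.list(s) && !is.null(s$subject_id)) s$subject_id else paste0("subj", k)
  }, "")
  fits <- vector("list", K)
  for (k in seq_len(K)) {
    s <- subjects[[k]]
    X <- if (is.list(s) && !inherits(s, "subject_data") && !is.null(s$X)) s$X else s
    if (verbose) message(sprintf("c-EBM subject %d/%d (%s)", k, K, ids[k]))
    fits[[k]] <- suppressWarnings(
      cebm(X, refs, theta = theta, gamma = gamma,
           n_components = n_components, table = table,
           max_sweeps = max_sweeps, tol = tol, seed = seed + k))
  }
  scvs <- scv_stack(fits, references = refs, subject_ids = ids)
  covs <- lapply(scvs, scv_covariance)
  if (is.null(candidate_I)) candidate_I <- seq_len(min(5, length(covs)))
  clustering <- cluster_scvs(covs, candidate_I = candidate_I, seed = seed)
  partition <- clustering$partition
  sat <- vapply(fits, function(f) mean(f$constraint$satisfied), 0)
  structure(list(fits = fits, scvs = scvs, covariances = covs,
                 clustering = clustering, partition = partition,
                 membership = data.frame(subject_id = ids,
                                         subgroup = partition$membership),
                 constraint_satisfaction = sat,
                 settings = list(theta = theta, gamma = gamma, seed = seed,
                                 candidate_I = candidate_I)),
            class = "fsig")
}

#' @export
print.fsig <- function(x, ...) {
  cat(sprintf("fSIG fit: %d subjects, %d components\n",
              nrow(x$membership), length(x$scvs)))
  cat(sprintf("  constraint satisfaction: %.0f%% of components across subjects\n",
              100 * mean(x$constraint_satisfaction)))
  print(x$clustering)
  invisible(x)
}

#' @export
summary.fsig <- function(object, ...) {
  out <- list(membership = object$membership,
              n_subgroups = object$partition$n_subgroups,
              modularity = object$partition$modularity,
              eigenvalues = object$partition$eigenvalues,
              r_min = object$partition$r_min,
              constraint_satisfaction = object$constraint_satisfaction)
  class(out) <- "summary.fsig"
  out
}

#' @export
print.summary.fsig <- function(x, ...) {
  cat(sprintf("Subgroups detected: %d (modularity %.3f, R_min %.3f)\n",
              x$n_subgroups, x$modularity, x$r_min))
  print(table(x$membership$subgroup))
  invisible(x)
}

#' @export
plot.fsig <- function(x, ...) {
  C <- x$clustering$aggregated[[x$clustering$best_cluster]]
  o <- x$partition$ordering
  graphics::image(t(abs(C[o, o]))[, rev(seq_len(ncol(C)))],
                  main = "Aggregated |SCV covariance| (block order)",
                  axes = FALSE, ...)
  invisible(x)
}

#' Validate identified subgroups with voxelwise statistics
#'
#' For each component, contrasts the subgroup's subject maps against the
#' remaining subjects with a voxelwise pooled-variance t-test and FDR
#' correction, then summarizes the components showing significant
#' differences (by default those in the selected SCV cluster) into a global
#' difference map.
#'
#' @param fit An [fsig()] object, or a list of `scv_matrix` objects.
#' @param membership Optional label vector (default: the fit's membership).
#' @param group Subgroup label to contrast (default `"SG1"`).
#' @param q FDR level.
#' @param components Components to test (default: those in the selected
#'   cluster when `fit` is an `fsig` object, otherwise all).
#' @return List with `tmaps` (per tested component), `significant`
#'   component indices, and `gdm` (or NULL when no component differs).
#' @export
fsig_validate <- function(fit, membership = NULL, group = "SG1", q = 0.05,
                          components = NULL) {
  scvs <- if (inherits(fit, "fsig")) fit$scvs else fit
  if (is.null(membership))
    membership <- if (inherits(fit, "fsig")) fit$partition$membership
                  else stop("'membership' is required")
  if (is.null(components))
    components <- if (inherits(fit, "fsig"))
      which(fit$clustering$assignments == fit$clustering$best_cluster)
    else seq_along(scvs)
  g <- membership == group
  if (sum(g) < 2 || sum(!g) < 2)
    stop("both the subgroup and the remaining subjects need at least 2 members")
  tmaps <- lapply(components, function(n)
    suppressWarnings(two_sample_tmap(scvs[[n]]$Y[g, , drop = FALSE],
                                     scvs[[n]]$Y[!g, , drop = FALSE],
                                     q = q, component_index = n)))
  sig <- components[vapply(tmaps, function(m) any(m$significant_mask), TRUE)]
  gdm <- if (length(sig))
    global_difference_map(tmaps[match(sig, components)]) else NULL
  list(tmaps = tmaps, significant = sig, gdm = gdm)
}

#' Run the pipeline on an on-disk dataset
#'
#' Orchestrates the staged flow over a fixture directory written by
#' [write_fixture()] (per-subject TSVs plus `references.tsv`): per-subject
#' constrained EBM, SCV covariance + clustering + Gershgorin subgroups, and
#' validation.  Every stage persists its artifacts (with MD5 checksums in
#' the run report) under `out_dir` and is skipped on rerun when its marker
#' artifact already exists, unless `force = TRUE`.  Reruns with the same
#' config and inputs reproduce identical outputs.
#'
#' @param config List (or path to a JSON file) with at least `data_dir` and
#'   `out_dir`; optional `theta`, `gamma`, `candidate_I`, `fdr_level`,
#'   `seed`, `stages` (subset of `c("cebm", "subgroup", "validate")`).
#' @param force Recompute stages whose artifacts already exist.
#' @param verbose Print stage progress.
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config, force = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(!is.null(config$data_dir), !is.null(config$out_dir))
  theta <- config$theta %||% 0.3
  gamma <- config$gamma %||% 3
  fdr_level <- config$fdr_level %||% 0.05
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("cebm", "subgroup", "validate")
  max_sweeps <- config$max_sweeps %||% 512L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config[setdiff(names(config), "stages")],
                 seed = seed, package_version = as.character(
                   utils::packageVersion("fsig")),
                 stages = list())
  subj_files <- sort(list.files(config$data_dir, pattern = "^subj.*\\.tsv$",
                                full.names = TRUE))
  if (length(subj_files) < 2) stop("no subject data found in 'data_dir'")
  refs <- as.matrix(data.table::fread(file.path(config$data_dir,
                                                "references.tsv")))
  ids <- sub("\\.tsv$", "", basename(subj_files))

  stage_file <- file.path(config$out_dir, "fit.rds")
  run_stage <- function(name, marker, fun) {
    if (!(name %in% stages)) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    if (!force && file.exists(marker)) {
      report$stages[[name]] <<- list(status = "cached", artifact = marker,
                                     md5 = unname(tools::md5sum(marker)))
      return(invisible(NULL))
    }
    if (verbose) message("stage: ", name)
    ok <- try(fun(), silent = TRUE)
    if (inherits(ok, "try-error")) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(attr(ok, "condition")))
      report_path <- file.path(config$out_dir, "report.json")
      jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(attr(ok, "condition"))))
    }
    report$stages[[name]] <<- list(status = "ok", artifact = marker,
                                   md5 = unname(tools::md5sum(marker)))
    invisible(NULL)
  }

  run_stage("cebm", stage_file, function() {
    subjects <- lapply(seq_along(subj_files), function(k)
      list(X = as.matrix(data.table::fread(subj_files[k])),
           subject_id = ids[k]))
    fit <- fsig(subjects, refs, theta = theta, gamma = gamma, seed = seed,
                candidate_I = config$candidate_I, max_sweeps = max_sweeps,
                verbose = verbose)
    saveRDS(fit, stage_file)
  })
  fit <- readRDS(stage_file)
  report$K <- nrow(fit$membership)
  report$constraint_satisfaction_rate <- mean(fit$constraint_satisfaction)

  member_file <- file.path(config$out_dir, "membership.tsv")
  run_stage("subgroup", member_file, function() {
    data.table::fwrite(fit$membership, member_file, sep = "\t")
    cov_dir <- file.path(config$out_dir, "covariances")
    dir.create(cov_dir, showWarnings = FALSE)
    for (n in seq_along(fit$covariances))
      data.table::fwrite(data.table::as.data.table(fit$covariances[[n]]),
                         file.path(cov_dir, sprintf("component%02d.tsv", n)),
                         sep = "\t", col.names = FALSE)
  })
  report$n_subgroups <- fit$partition$n_subgroups
  report$chosen_I <- fit$clustering$n_clusters
  report$modularity <- fit$partition$modularity

  val_file <- file.path(config$out_dir, "validation.tsv")
  run_stage("validate", val_file, function() {
    if (fit$partition$n_subgroups == 0) {
      data.table::fwrite(data.frame(component = integer(0), t_q = numeric(0),
                                    min_q = numeric(0)), val_file, sep = "\t")
      return(invisible(NULL))
    }
    val <- fsig_validate(fit, q = fdr_level)
    data.table::fwrite(data.frame(
      component = vapply(val$tmaps, `[[`, 0, "component_index"),
      t_q = vapply(val$tmaps, `[[`, 0, "t_q"),
      min_q = vapply(val$tmaps, function(m) min(m$q_values), 0)),
      val_file, sep = "\t")
    if (!is.null(val$gdm))
      data.table::fwrite(data.table::as.data.table(t(val$gdm$map)),
                         file.path(config$out_dir, "gdm.tsv"),
                         sep = "\t", col.names = FALSE)
  })

  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
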