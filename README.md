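# fsig

Identification of homogeneous subject subgroups from multi-subject
resting-state fMRI activity maps, using constrained independent component
analysis and a Gershgorin-disc eigenspectrum rule.

## The problem and the method

Functional activity maps estimated from resting-state fMRI behave like
fingerprints: they are stable within a subject and variable across subjects.
In a large cohort of patients, subjects whose network maps correlate
strongly with each other — more strongly than with everyone else — form a
*homogeneous subgroup*, a candidate stratification for precision-medicine
questions.  Finding such subgroups requires per-subject decompositions that
are (a) individually faithful and (b) mutually aligned, which rules out both
plain ICA (arbitrary component order/sign per subject) and group ICA (a
common spatial model suppresses the inter-subject variability of interest).

`fsig` implements a three-stage pipeline:

1. **Templates.**  Group ICA by entropy bound minimization (two-level PCA +
   ICA-EBM) on an independent dataset yields resting-state-network
   templates, screened by the low/high-frequency power ratio of their time
   courses (`group_ica_ebm()`, `select_rsns()`).

2. **Constrained EBM per subject** (`cebm()`).  Each subject is decomposed
   separately by ICA-EBM — negentropy estimated as the tightest of four
   maximum-entropy bounds built from fixed measuring functions
   `x^4`, `|x|/(1+|x|)`, `x|x|/(10+|x|)`, `x/(1+x^2)` — with non-orthogonal
   row-wise decoupling, and with each component `n` tied to template `r_n`
   by the inequality constraint

       theta_n - |corr(r_n, y_n)| <= 0,

   handled by an augmented Lagrangian (multiplier update
   `mu <- max(0, gamma*h + mu)` once per sweep).  The shared templates align
   components across subjects without any post-hoc matching.

3. **Subgroup detection** (`scv_covariance()`, `cluster_scvs()`,
   `gershgorin_subgroups()`).  The n-th source component vector (SCV) stacks
   component n of all K subjects; its K-by-K correlation matrix `C` encodes
   inter-subject similarity of that network.  SCV covariances are k-means
   clustered and averaged; on the aggregated matrix, every Gershgorin disc
   is centered at 1 with radius `R_i = sum_{j != i} |C_ij|`, and the number
   of subgroups is the number of eigenvalues exceeding `R_min + 1`.  The
   corresponding eigenvectors identify the member subjects; modularity on
   `|C|` selects the clustering.

Validation utilities (`two_sample_tmap()`, `fdr_correct()`,
`global_difference_map()`, `compare_covariates()`) contrast identified
subgroups voxelwise with pooled-variance t-tests under Benjamini–Hochberg
FDR control and summarize significant components into a |t|-weighted global
difference map.  Consistency diagnostics (`isi()`, `cross_isi()`,
`order_selection()`) support model-order choice.  A synthetic multi-subject
generator with planted subgroup structure (`generate_fsig_data()`,
`fsig_preset()`) gives every stage a ground-truthed input.

## Worked example

Simulate 8 subjects with a planted block of 3 (within-block source
correlation 0.8 against a 0.2 background), fit the pipeline, and compare
with the ground truth:

```r
library(fsig)
sim <- generate_fsig_data(fsig_preset("tiny", seed = 1))
fit <- fsig(sim$subjects, sim$references, theta = 0.3, seed = 42)
print(fit)
#> fSIG fit: 8 subjects, 4 components
#>   constraint satisfaction: 100% of components across subjects
#> SCV clustering: 4 components into 3 cluster(s)
#>   modularity by candidate I: 1=0.037, 2=0.096, 3=0.102, 4=0.102
#>   selected cluster 2; detected subgroups: 1

table(predicted = fit$partition$membership,
      truth = sim$ground_truth$block_labels)
#>          truth
#> predicted rest SG1
#>      rest    5   0
#>      SG1     0   3

val <- fsig_validate(fit)
val$significant
#> [1] 2
```

Every constrained component reached similarity at least `theta = 0.3` with
its template; one eigenvalue of the aggregated SCV correlation matrix lies
outside the smallest Gershgorin disc (`R_min = 1.30`), the three planted
subjects are recovered exactly, and the voxelwise contrast flags a
structured component (here component 2) as significantly different between
the subgroup and the remaining subjects.

A command-line wrapper over the same functions ships in `inst/cli/fsig.R`
(subcommands `simulate`, `order-select`, `cebm`, `subgroup`, `validate`,
`run`), and `run_pipeline()` executes the staged flow on an on-disk dataset
with cached, checksummed artifacts.

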