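---
title: "Methods: constrained ICA and Gershgorin-disc subgroup identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained ICA and Gershgorin-disc subgroup identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind **fsig**, in enough detail that a user can judge what the
package computes and what its tests do and do not establish.

## The problem

Resting-state fMRI functional activity maps are stable enough across sessions
to act as a subject-level fingerprint.  Given a large cohort, we want to find
*homogeneous subgroups*: sets of subjects whose spatial activation patterns
for one or more functional networks correlate more strongly with each other
than with the rest of the cohort.  Plain per-subject ICA cannot be compared
across subjects (component order and sign are arbitrary); group ICA forces a
common spatial model and suppresses exactly the inter-subject variability we
want to study; IVA preserves it but scales poorly with the number of
subjects.  The package takes a third route: each subject is decomposed
*independently* by a constrained ICA whose constraints tie each component to
a shared spatial template, so the decompositions stay subject-specific but
arrive aligned.

## Entropy-bound negentropy estimation

ICA by entropy bound minimization (EBM) replaces the density estimate inside
the mutual-information cost with the tightest of several maximum-entropy
bounds.  For a zero-mean unit-variance estimate $y$ and measuring functions
$G_1(x)=x^4$, $G_2(x)=|x|/(1+|x|)$, $G_3(x)=x|x|/(10+|x|)$,
$G_4(x)=x/(1+x^2)$, the entropy of $y$ is bounded by
$H(y) \le O_m\{E[G_m(y)]\}$, where $O_m(t)$ is the entropy of the
maximum-entropy density with unit variance, zero mean, and $E[G_m]=t$.  The
negentropy estimate is $\max_m\{\tfrac12\log 2\pi e - O_m(E[G_m(y)])\}$.

`build_bound_table()` tabulates each $O_m$ once by sweeping the moment
multiplier $\lambda_3$ of the exponential family
$p(y)\propto\exp(-\lambda_1 y-\lambda_2 y^2-\lambda_3 G_m(y))$ over a
sinh-spaced grid (512 points by default), solving the strictly convex dual
for $(\lambda_1,\lambda_2)$ at each point (BFGS on
$\log Z + \lambda_2$, gradients are moment mismatches), on a 4001-point
trapezoid quadrature over $[-16, 16]$.  By the envelope theorem
$O_m'(t)=\lambda_3$, which the tests use as an independent check on the
interpolant's derivative.  Two numerical choices deserve mention:

* **Interpolation** is a natural cubic spline.  A merely $C^1$ monotone
  interpolant leaves second-derivative jumps at the knots that a
  finite-difference check of the optimizer gradient can detect; the bound
  data are smooth and densely sampled, so the $C^2$ spline is safe.
* **Support and clamping.**  $G_1=x^4$ is only integrable for
  $\lambda_3 \ge 0$, so its bound covers the sub-Gaussian side
  ($t \le 3$) and saturates at the Gaussian entropy beyond; moments outside
  any table's support are clamped to the boundary and the clamped extension
  is constant (derivative zero).  This matches the mathematical fact that
  the supremum entropy on the unreachable side approaches the
  unconstrained Gaussian bound.

On 200 000-sample checks the estimator gives $\approx 0$ nats for a Gaussian
and $\approx 0.068$ nats for a unit-variance Laplace (closed form: 0.072);
the uniform comes out lower than truth (0.11 vs 0.18) because four fixed
bounds cannot be tight everywhere — they only need to rank candidate
directions.

## Decoupled ICA-EBM

The mutual-information cost is minimized one demixing row at a time.  With
$d_n$ the unit vector orthogonal to all other rows (`decoupling_vector()`,
QR-based null space), the row cost is
$J_n(w_n) = -\mathcal N(y_n) - \log|d_n^\top w_n|$ with
$\mathcal N$ the EBM negentropy.  No orthogonality is imposed on the
demixing matrix.  The optimizer is projected gradient descent on the
unit-variance sphere: the gradient (negentropy term
$O'_{m^\ast}(t)\,E[g_{m^\ast}(y)x]$ plus decoupling term $-d_n/(d_n^\top
w_n)$) is projected tangentially, normalized, and a backtracking (halving,
Armijo) line search accepts steps; each accepted row is rescaled so its
source estimate keeps unit sample variance.  Tangential normalized steps
matter: near-Gaussian mixtures put the raw gradient on a plateau whose
magnitude says nothing about a useful step length.  Defaults: at most 512
sweeps, convergence when the largest row-direction change
$1-|\hat w^{new}\cdot\hat w^{old}|$ falls below $10^{-6}$, random orthogonal
initialization from a seeded generator, scale fixed by unit-variance
sources, sign fixed by positive skewness (largest-magnitude sample as
fallback).

## Constrained EBM

Each constrained row additionally satisfies
$h_n = \theta_n - \epsilon(r_n, y_n) \le 0$, where
$\epsilon = |\mathrm{corr}(r_n, y_n)|$ and $\theta_n \in [0,1]$ tolerates
deviation from the template $r_n$.  The inequality is handled by an
augmented Lagrangian with the slack variable eliminated analytically,
adding $\frac{1}{2\gamma}(\max\{0,\gamma h_n+\mu_n\}^2-\mu_n^2)$ to the row
cost; the multiplier update $\mu_n \leftarrow \max\{0,\gamma h_n+\mu_n\}$
runs once per sweep.  Inside the optimizer the similarity enters through
the linear surrogate $(1/V)\tilde r_n^\top y_n$ (standardized reference),
which equals the correlation at the unit-variance points the optimizer
maintains and makes the printed gradient the *exact* derivative of the
augmented cost — verified to $10^{-4}$ relative (in practice $10^{-9}$)
against central finite differences at random differentiable points.

Choices made where the method is underdetermined:

* $\theta = 0.3$ by default for all constrained components: low enough to
  preserve inter-subject variability, high enough to keep components
  anchored to their templates.  $\gamma = 3$, fixed, no schedule: the
  penalty only needs to dominate near the constraint boundary; a
  sensitivity sweep over $\theta \in \{0, 0.3, 0.6, 0.9\}$ in the tests
  confirms the mean final similarity is non-decreasing in $\theta$.
* $\mu$ starts at zero (standard practice: begin unconstrained).
* **Initialization.**  `cebm()` starts each constrained row at the matched
  filter of its reference in whitened space, $w_n \propto X\tilde r_n$, with
  a random orthogonal complement for unconstrained rows.  Random
  initialization (the `ica_ebm()` default, still available via
  `init = "random"`) frequently converged to local optima in which a
  constrained component sat exactly at $\epsilon = \theta$ while mixing the
  wrong sources; the matched filter starts inside the feasible basin, and
  with it the synthetic benchmarks recover every source at correlation
  $> 0.99$ in an order of magnitude fewer sweeps.  With $\theta = 0$ and a
  shared explicit `W0`, `cebm()` and `ica_ebm()` follow identical
  trajectories, which the tests assert.
* Reference $k$ constrains component $k$; remaining components are free.
  Alignment across subjects therefore comes from the shared references, not
  from post-hoc matching.  Final constrained components are sign-aligned to
  their reference.

## SCVs, clustering, and Gershgorin-disc subgroup detection

The $n$th source component vector (SCV) stacks component $n$ of all $K$
subjects into a $K \times V$ matrix; its correlation matrix
$\hat C_n = \frac{1}{V-1} Y_n Y_n^\top$ (rows standardized, diagonal forced
to 1) encodes inter-subject similarity of that network.  Because the
constraint uses $|\mathrm{corr}|$, a subject's component can arrive
sign-flipped; rows are sign-aligned to the reference before covariance
computation (configurable, `align_sign`), preventing artificial negative
blocks.

Step I clusters the SCVs: k-means (20 seeded restarts) on the vectorized
upper triangles of the $\hat C_n$, for each candidate cluster count $I$;
each cluster's matrices are averaged into $\bar C_i$ and scored by the
modularity of its Gershgorin partition; the $(I, i)$ pair with maximal
modularity wins.  Modularity is Newman–Girvan on edge weights
$|\rho_{ij}|$ with the `"rest"` subjects as one community — the method
needs *some* modularity definition and none is canonical here; the choice
is stated in the function documentation and cross-checked against igraph
in the tests.

Step II applies the Gershgorin disc theorem to the aggregated correlation
matrix: all discs are centered at 1 with radii
$R_i = \sum_{j\ne i}|\rho_{ij}|$, every eigenvalue lies inside some disc,
and eigenvalues *outside the smallest* disc — strictly greater than
$R_{\min}+1$, ties excluded — count the subgroups $B$.  Membership uses,
per outlying eigenvector, 2-means on absolute loadings with the
high-loading cluster forming the subgroup; overlaps resolve to the largest
absolute loading; unclaimed subjects are `"rest"`.  A joint
$(B+1)$-means alternative is available (`method = "joint"`).  Averaging
correlation matrices preserves the unit diagonal, so the
$\lambda > R_{\min}+1$ rule stays well-defined after aggregation.

**Known limitation (demonstrated, not fixed).**  $R_{\min}$ is a sum of
$K-1$ absolute correlations, so at fixed block *fraction* it grows at
$E|\rho_{noise}| \approx 0.80\,\sigma$ per subject while a planted block at
correlation $\rho$ and fraction $f$ pushes its eigenvalue up at only
$f\rho$ per subject.  When $f\rho < 0.80\,\sigma$, detection at small $K$
survives only through finite-$K$ fluctuations and disappears as $K$ grows.
The acceptance suite reproduces this with $f = 1/4$, $\rho = 0.09$,
$\sigma = 0.05$ on $K \in \{20, 100, 400\}$ (chosen analytically from the
two slopes, $0.0225$ vs $0.0399$, and verified on independent seed
families): the mean detected $B$ over 40 seeds falls from about 0.65
through 0.2 to 0.  Values of $\rho$ near the crossover (e.g. 0.10–0.11)
sit on a knife edge where the noise boost of the top eigenvalue can make
detection *easier* at intermediate $K$; the demonstration deliberately
stays below it.

## Consistency diagnostics and model order

`isi()` implements the normalized joint inter-symbol interference of a
mixing–demixing product; it is zero exactly on signed scaled permutations
and one for an all-ones matrix.  Two printed-form ambiguities were resolved
in favor of the metric's defining properties: the column term normalizes by
the *column* maximum (the row-max variant, kept as
`normalization = "row-max"`, does not vanish on scaled permutations), and
cross-ISI composes run $j$'s demixing with run $i$'s mixing,
$G_{ij} = W_j A_i$ with $A_i = W_i^{-1}$ (the opposite order is a similarity
transform that is not a permutation even for identical solutions).  ISI is
invariant to permutations, sign changes, and global rescaling; it is *not*
invariant to arbitrary per-row/per-column rescaling, and the tests assert
the true invariances.

`order_selection()` whitens to each candidate order, runs seeded ICA-EBM
repeatedly, and summarizes per-run cross-ISI; orders with small and stable
values are flagged (median and IQR within a factor 1.5 of the best — an
explicit, documented heuristic for what the workflow leaves to inspection)
and the smallest-cross-ISI run within the best order is reported.
Entropy-rate-based initial order estimates are out of scope; the candidate
list is user-supplied.

## Templates

`group_ica_ebm()` implements two-level PCA (subject-level order
$1.5\times$ the model order by default, capped by subject rank, then group
PCA to the model order) followed by ICA-EBM on the concatenated reduced
data.  Group component time courses are recovered per subject by
back-projecting the mixing matrix through both PCA bases — enough for the
spectral screening; subject-map back-reconstruction is deliberately not
implemented, since subject-level maps come from c-EBM.  `select_rsns()`
filters components by the low/high-frequency power ratio (defaults
0.10/0.15 Hz, configurable; the ratio of band powers from the periodogram,
with a floating-point-noise guard mapping an empty high band to `Inf`),
optional peak-location masks, and an explicit override list so the
partly-manual template curation remains scriptable and reproducible.

## The synthetic generator

`generate_fsig_data()` emulates the study conditions every pipeline stage is
tested under.  Component $n$ of all $K$ subjects is drawn as a $K$-vector
with block covariance — $\rho_{in}$ within planted subject blocks,
$\rho_{out}$ elsewhere — through a Gaussian copula mapped to
generalized-Gaussian marginals (shapes cycle through 1, 4, 1.5, 3, all with
excess kurtosis beyond $\pm 0.5$, as ICA identifiability requires); each
subject mixes its $N$ sources with a random square matrix of condition
number at most 10; references are across-subject mean maps plus Gaussian
noise calibrated so the reference–mean-map correlation equals
`reference_fidelity` (0.9 by default).  Calibrating fidelity against the
*mean* map is the only consistent reading: a single reference cannot hold a
fixed correlation with $K$ mutually independent subject maps.

$\rho_{out} = 0.2$ by default: real resting-state networks are similar
across *all* subjects — that is why shared templates work at all — and the
background correlation is also what makes the noisy group-mean references
feasible constraints (the per-subject reference correlation is about
$\sqrt{\rho_{out}}$ for background subjects, comfortably above
$\theta = 0.3$).  The copula transform attenuates target correlations
slightly, so the generator measures and reports the realized within-block
correlations rather than promising $\rho_{in}$ exactly.

Presets: `tiny` ($K=8$, $N=4$, $V=5000$, one block of 3), `standard`
($K=40$, $N=10$, $V=20000$, one block of 10 at $\rho_{in}=0.8$, three
structured components) — the reference conditions for the end-to-end
recovery checks — and `stress` ($K=200$, $N=20$, $V=20000$).  All
randomness flows from one master seed through named substreams (sources,
mixing, reference noise).  What the generator does *not* emulate: spatial
smoothness and autocorrelation of real maps, hemodynamics, scanner/site
effects, registration error.  Passing tests therefore establish correctness
of the algorithms under the stated statistical model, not performance on
real fMRI.

## Problem sizes in the tests

The unit tests run at $V$ between 1000 and 20 000 and $N \le 12$; the
end-to-end acceptance checks run the `standard` preset in full
($K=40$, $N=10$, $V=20000$; about 40 s for the 40 constrained fits) and the
detector-level checks up to $K=400$.  The `stress` preset is exercised at
the configuration and generation level, with the large-$K$ behavior it
exists to show demonstrated directly at the detector level, where it is a
property of the covariance dimension rather than of the ICA stage.

## Degenerate inputs and edge cases

Rank-deficient data are rejected at whitening with the achievable rank
named; a reference with zero variance, perfectly correlated references,
constant SCV rows (with the offending subject named), non-symmetric or
non-unit-diagonal covariance input, singular demixing matrices in cross-ISI
(with the run named), and all-zero ISI rows all raise errors rather than
propagate.  Zero pooled variance at a voxel yields $t=0$ with a warning
count; an empty significance mask yields $t_q = 0$ and the component simply
cannot contribute to a global difference map; a boundary tie
$\lambda = R_{\min}+1$ is excluded by the strict inequality, as printed.
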