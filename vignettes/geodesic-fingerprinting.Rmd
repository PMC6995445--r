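---
title: "Geometry-aware comparison of functional connectivity matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-aware comparison of functional connectivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgeodesic)
```

## The problem

A functional connectivity (FC) matrix summarizes the pairwise Pearson
correlations between the activity time series of a set of brain regions
(ROIs).  Many analyses need a notion of *distance* between two FC
matrices — most prominently participant identification
("fingerprinting"): given an FC matrix estimated from an unseen scan, find
the participant in a database whose FC it most resembles.

Correlation matrices are not arbitrary points in Euclidean space.  They
are symmetric and positive semidefinite (for any vector $y$,
$y' Q y \ge 0$), so they live on the cone of positive-semidefinite
matrices, which is closed under positive linear combinations
($\alpha Q_1 + \beta Q_2$ stays on the cone for $\alpha, \beta > 0$).
Distances that ignore this geometry can mislead.  `fcgeodesic` implements
the two measures this package exists to compare, and the complete
identification framework built on them.

## The two measures

**Affine-invariant geodesic distance.**  For strictly positive-definite
$Q_1, Q_2$,
$$d_G(Q_1, Q_2) = \sqrt{\textstyle\sum_i \log^2 \lambda_i},$$
where $\lambda_i$ are the eigenvalues of $Q_1^{-1/2} Q_2\, Q_1^{-1/2}$.
This is the length of the shortest path between the two matrices along
the manifold of positive-definite matrices.  It is a true metric
(non-negative, zero iff equal, symmetric, triangle inequality) and is
invariant under congruence transforms $Q \mapsto A Q A'$ — all properties
the test suite verifies on randomly generated SPD triples.

**Pearson dissimilarity.**  Stack the columns of each matrix into a
vector and compute $d_P = (1 - \mathrm{corr}(q_1, q_2))/2 \in [0, 1]$.
The correlation implicitly mean-centers both vectors, which discards
geometric information: *any* two 2×2 correlation matrices are
indistinguishable under $d_P$ (both centered vectors are positive
multiples of $(1,-1,-1,1)$), while $d_G$ separates them.  `fcgeodesic`
treats this degeneracy as a first-class, tested fact.

```{r degeneracy}
a <- matrix(c(1, .8, .8, 1), 2)
b <- matrix(c(1, -.5, -.5, 1), 2)
c(pearson = pearson_dissimilarity(a, b), geodesic = geodesic_distance(a, b))
```

## Regularization of rank-deficient matrices

A sample correlation matrix estimated from fewer frames than ROIs
($T < R$) is rank deficient, and $d_G$ needs invertible inputs.  The
package adds an identity perturbation $\tau I$ (default $\tau = 1$), and
applies it to **every** matrix of a comparison set as soon as *any*
member is non-invertible, rather than per offending pair.  The rationale
is that a distance used inside one experiment should be a single
consistent function of its two arguments; mixing perturbed and
unperturbed pairs would compare incommensurable quantities.  The applied
$\tau$ is recorded on each matrix (`regularization_tau`), and a matrix
counts as non-invertible when its smallest eigenvalue falls below
`eig_tol`, defaulting to $10^{-10}$ times the largest eigenvalue observed
in the set.  $\tau$ is configurable because the appropriate scale of the
perturbation, relative to the data, is a modelling choice rather than a
mathematical necessity.

## Identification and its inference

Identification is 1-nearest-neighbour classification on the precomputed
$N \times N$ cross-run distance matrix: each test matrix is labeled with
the nearest train participant (ties, which occur with probability zero
for continuous data but matter for reproducibility, go to the lowest
column index with a warning).  Accuracy is the fraction of correct
labels; the reported value averages the two run directions (run 1 as
database/run 2 as queries, then reversed).

Participants in a group are not independent units: whether B is
misidentified can depend on whether a look-alike A is in the database.
Inference therefore treats the whole group as the unit and uses a
two-level bootstrap: a resample is a with-replacement redraw of the $N$
participants; $M$ resamples (default 1000) give one mean score, and
repeating this $B$ times (default 1000) gives the distribution of *mean*
scores.  Two choices deserve comment:

* **Duplicates.**  A resample may contain the same participant several
  times.  Each copy enters as a test item, and a prediction counts as
  correct when the nearest train column belongs to the same *original*
  participant, whichever copy.  This keeps accuracy well defined for
  multisets and consistent with the group-as-unit rationale.
* **Cost.**  Distances are computed once; resampling is pure index
  arithmetic on the stored matrix (implemented in C++), so the cost of
  $M \times B$ resamples does not grow with the ROI dimension.

For the comparison of measures, the difference
$\delta = f_G - f_P$ between geodesic- and Pearson-based accuracy is
computed on the *same* resamples, so comparing a measure with itself
yields exactly zero.  The $B$ mean differences are Fisher-z
(arctanh) transformed — they are bounded percentage differences — and a
two-tailed one-sample t-test against zero is applied.  Whether the
transform should apply to the differences or to each accuracy before
differencing is ambiguous in the usual description of this procedure; the
package transforms the differences by default and exposes
`transform = "accuracies"` for the alternative, without claiming either
is canonical.  Degenerate zero-variance inputs use the conventions
$p = 1$ (all zero) and $p = 0$ (all equal, nonzero), logged.

## Time-series conditioning

* `trim_task_blocks()` removes fixation periods from task runs.
  Uncued blocks drop the first 4 frames (hemodynamic lag) and keep 4
  frames past the block end; cued blocks keep data from 12 s after cue
  onset to 3 s after block end.  Frames are 0-based with half-open
  ranges; seconds convert to frames with `ceiling` at onsets and `round`
  for the 3-second tail — the conservative direction for including
  post-cue frames.  A tail overhanging the run is clipped; a block whose
  own extent exceeds the run is an error.
* `equate_length()` trims every run to a common length (default 138
  frames, the shortest task regime) by keeping the centered window; an
  odd surplus loses its extra frame at the end.
* `sample_segments()` draws contiguous windows with starts sampled
  uniformly *without replacement*, so segment experiments do not favour
  the beginning of the scan.  When fewer distinct starts exist than
  segments requested it returns all of them with a warning instead of
  failing, which keeps short synthetic runs usable.
* `select_subnetworks()` restricts a time series or FC matrix to named
  subnetworks of a parcellation — for an FC matrix the principal
  submatrix, which keeps every within- and between-network connection
  among the selected ROIs and provably preserves positive
  semidefiniteness.  `cortical_parcellation_300()` ships the
  seven-network, 300-ROI layout (visual 47, somatomotor 57, dorsal
  attention 34, ventral attention 34, limbic 20, frontoparietal 40,
  default 68).

In `segment_length_curve()`, all participants of a run share each drawn
window, so a segment compares like with like across participants; the
two runs draw their windows independently.

## Non-metric multidimensional scaling

`nonmetric_mds()` embeds a dissimilarity matrix into (by default) three
dimensions using only the *rank order* of the dissimilarities.  The
recorded stress is
$$S = \frac{\sum_{i<j} (\hat d_{ij} - \|x_i - x_j\|)^2}{\sum_{i<j} \hat d_{ij}^2},$$
with disparities $\hat d$ fitted by monotone (pool-adjacent-violators,
ties averaged) regression of the embedded distances onto the rank order
of the input.  The embedded quantity is the plain Euclidean norm — the
convention of standard non-metric MDS implementations — not its square;
`mds_stress()` also offers the raw-input normalization
($\sum d_{ij}^2$ in the denominator) for users who prefer it.

The optimizer alternates a majorization (Guttman transform) update of
the coordinates with the isotonic fit.  After each fit the disparities
are rescaled to the ratio-optimal norm
$\hat d = p \cdot \sum d_x^2 / \sum p^2$ (where $p$ is the raw isotonic
fit); because isotonic regression is a projection onto a convex cone,
this scaled fit minimizes $S$ over the cone, and the Guttman step cannot
increase the numerator, so the recorded stress is provably
non-increasing at every iteration — a property the tests assert
directly.  Iteration stops at `max_iter` (default 1000) or when the
relative stress change falls below $10^{-8}$.

The first restart starts from classical (Torgerson) scaling — the
standard starting configuration, and the one the widely used
implementations default to — with the remaining restarts random; the
best final stress wins.  The whole computation runs in a canonical
(sorted item-id) order, so jointly permuting the matrix and its ids
permutes the output points identically, to the last bit.  A matrix whose
off-diagonal entries are all equal carries no rank information; the
function warns and returns a best effort.

## The synthetic study generator

Real resting-state and task fMRI data of the scale this framework targets
are access-restricted, so the package ships a generator that plays the
role of the study data.  Each (participant, condition) pair receives a
ground-truth correlation matrix from a factor model:
$L = L_{\text{base}} + s\,L_i + c\,L_c$ with independent
$R \times F$ standard-normal loadings scaled by $1/\sqrt F$, then
$\Sigma = \mathrm{cov2cor}(L L' + \text{noise\_floor} \cdot I)$.
Participant perturbations $L_i$ are shared across conditions and
condition perturbations $L_c$ across participants, so `subject_effect`
($s$) is the fingerprintable signal and `condition_effect` ($c$) the
task-reconfiguration signal.  Runs are i.i.d. Gaussian frames from
$\Sigma$ (Cholesky transform); an AR(1) option exists (default off) for
robustness studies.

Defaults are fixed once and define the package's strong-signal regime:
$N = 100$ participants, $R = 30$ ROIs, $T = 600$ frames, two runs,
$s = 1$, $c = 0.2$, $F = 5$ factors, noise floor $0.5$.  $F = 5$ is a
typical low-rank choice for shared covariance structure; the noise floor
keeps every ground truth strictly positive definite and bounds
correlations away from $\pm 1$.  Setting $s = 0$ gives the chance-level
regime in which 1-NN identification of $N$ participants succeeds with
probability exactly $1/N$ — the calibration experiment run by
`scripts/acceptance.R` with $N = 100$, $R = 20$, $T = 200$ over 1000
replicate groups.

What the generator does *not* emulate matters for interpretation:
hemodynamics, scanner drift, motion artefacts, spatial autocorrelation
of parcels, and family structure are all absent.  Tests passing on this
generator demonstrate the correctness and calibration of the
*machinery*; they do not by themselves establish effect sizes on real
neuroimaging data.

## Problem sizes and numerical choices

The test suite exercises the full-size regimes where the claim depends
on them (chance level: $N = 100$, 1000 replicates; strong signal:
$N = 100$, $R = 30$, $T = 600$, 20 seeds) and deliberately small
configurations elsewhere (enumeration oracles at $N = 3$, segment
curves at $N = 12$), chosen so each property is checked at the smallest
size at which it is informative.  Other conventions: symmetrized inner
products before eigendecompositions; eigenvalue clipping thresholds
relative to the largest eigenvalue; correlation computed with a common
denominator so diagonals are exactly 1; all randomness flows through
explicit seeds (per-batch streams are derived from one master seed, so
enlarging `B` extends rather than reshuffles the draws).

## Limitations

* Only the affine-invariant geodesic and Pearson dissimilarity are
  implemented — no log-Euclidean or Bures–Wasserstein metrics, no
  tangent-space projection, no shrinkage estimators.
* Identification is strictly 1-NN; no confidence scores or $k > 1$.
* The bootstrap provides mean-difference tests, not confidence
  intervals; multiple-comparison handling is limited to reporting a
  Bonferroni reference level by the caller.
* The embedding is for visualization; it is not part of the
  identification pipeline and its coordinates have arbitrary units.
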