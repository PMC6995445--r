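# fcgeodesic

Geometry-aware comparison of functional connectivity (FC) matrices, and
the participant-identification ("fingerprinting") framework built on it.

## The problem

An FC matrix holds the pairwise Pearson correlations between the
activity time series of brain regions (ROIs).  FC matrices are symmetric
and positive semidefinite, so they live on the positive-semidefinite
cone — a curved space.  Comparing them with measures that ignore this
geometry can be misleading: the commonly used *Pearson dissimilarity*

> d_P(Q1, Q2) = (1 − corr(vec(Q1), vec(Q2))) / 2

implicitly mean-centers the vectorized matrices and cannot even
distinguish two different 2×2 correlation matrices.  The
*affine-invariant geodesic distance*

> d_G(Q1, Q2) = sqrt( Σᵢ log² λᵢ ),  λᵢ = eigenvalues of Q1^(−1/2) Q2 Q1^(−1/2)

is a true metric on positive-definite matrices — non-negative, symmetric,
triangle inequality, invariant under congruence transforms — and is the
measure this package is built around.

On top of the two measures, `fcgeodesic` implements the full
identification pipeline for test–retest study designs:

* FC estimation from ROI × time matrices, with identity-perturbation
  regularization for rank-deficient (frames < ROIs) inputs;
* symmetric 1-nearest-neighbour identification (both run directions
  averaged) and cross-condition transfer tables;
* a two-level bootstrap (M resamples per mean, B means) over whole
  participant groups, with Fisher-z t-tests on accuracy differences;
* segment-length experiments, block trimming, length equating, and
  subnetwork selection against a seven-network, 300-ROI cortical
  parcellation;
* non-metric multidimensional scaling (SMACOF majorization + isotonic
  regression) for 3-D visualization of FC distances;
* a multivariate-normal factor-model generator producing synthetic
  multi-participant, multi-condition studies, so every experiment runs
  without access-restricted neuroimaging data;
* a command-line front end (`exec/fcgeo`) covering the pipeline
  (`simulate`, `fc`, `distance`, `identify`, `transfer`, `bootstrap`,
  `seglen`, `embed`), with a reproducibility manifest per run.

## Worked example

Simulate a hard regime — 30 participants, 15 ROIs, only 40 frames per
run, weak participant-specific signal — then identify and compare the
measures:

```r
library(fcgeodesic)

cfg <- generator_config(n_participants = 30, n_rois = 15, n_frames = 40,
                        subject_effect = 0.3, seed = 1)
study <- generate_study(cfg)
dbs <- study_fc_databases(study)

res_g <- symmetric_accuracy(dbs$cond1$run1, dbs$cond1$run2, "geodesic")
res_p <- symmetric_accuracy(dbs$cond1$run1, dbs$cond1$run2, "pearson")
res_g
#> <identification_result> geodesic: run1->run2 0.600, run2->run1 0.567, mean 0.583
res_p
#> <identification_result> pearson: run1->run2 0.433, run2->run1 0.500, mean 0.467

boot <- bootstrap_mean_differences(res_g$dist, res_p$dist,
                                   bootstrap_config(M = 500, B = 500, seed = 2))
boot
#> <bootstrap_result> B = 500 mean differences: mean 0.0928, p = 0
```

With 40 frames the geodesic measure identifies 58% of participants
against 47% for Pearson dissimilarity; over 500 × 500 bootstrap
resamples of the group the mean accuracy advantage is 9.3 percentage
points, and the Fisher-z t-test p-value underflows to zero.  Chance
level for 30 participants would be 1/30 ≈ 3.3%.

The same distances can be embedded for inspection:

```r
D <- combined_dissimilarity(list(dbs$cond1$run1, dbs$cond1$run2), "geodesic")
emb <- nonmetric_mds(D, dim = 3, seed = 3)
emb
#> <mds_embedding> 60 items in 3 dimensions, stress 0.0535 after 1000 iterations
```

Each participant contributes two of the 60 points (one per run); under
stronger signal the run pairs collapse onto each other while
participants separate.

The same pipeline from a shell:

```sh
exec/fcgeo simulate --out study --n-participants 30 --n-rois 15 --n-frames 40 \
    --subject-effect 0.3 --seed 1
exec/fcgeo fc --in study --out derived
exec/fcgeo identify --fc-dir derived --condition cond1 --measure geodesic \
    --out identify.json
```

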