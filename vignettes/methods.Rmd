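---
title: "Methods: brain-network reorganisation analysis for chronic-pain cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-network reorganisation analysis for chronic-pain cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

painnet implements a resting-state functional-connectivity pipeline for
comparing a chronic-pain cohort against healthy controls, starting from
regional (ROI) time series and six-parameter rigid-body motion traces.
This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohorts used in
the test suite do and do not establish about real data.

## Temporal preprocessing

Per subject the package computes framewise displacement
$FD_j = \sum |\Delta d_j| + r \sum |\Delta \theta_j|$ over the three
translations (mm) and three rotations (radians), with $r = 50$ mm — the
standard spherical head radius for converting rotations to displacements;
the upstream description of the scrubbing procedure does not fix a value,
so the convention is stated here and logged in the QC table. Frames with
$FD > 0.5$ mm are censored together with 1 preceding and 2 following
frames (window union over offending frames; `scrub()` is idempotent).

The processing order is fixed and logged: (1) zero-phase band-pass
0.008–0.1 Hz (second-order Butterworth, applied forward and backward to
the full series), (2) nuisance regression of the six motion parameters, a
global-signal regressor and an intercept on the full series, (3) the
scrubbing mask is applied at correlation time only. The order is a design
choice: filtering and regression behave best on uninterrupted series, and
subject-exclusion summaries are defined "after scrubbing", which only
constrains the mask to precede the DVARS summary, not the filter.
DVARS — the RMS frame-to-frame signal change — is computed on the
analysed (filtered, regressed) series; subjects whose post-scrub mean
DVARS falls outside $[Q_1 - 3\,IQR,\; Q_3 + 3\,IQR]$ are excluded.
Quartiles use the linear-interpolation convention (R type 7).

## Connectivity graphs

Pearson correlations over retained frames give a symmetric ROI × ROI
matrix; Fisher z-transformed upper-triangle entries are the classifier
features. For topology analyses the matrix is thresholded adaptively to a
fixed 10% link density: exactly $\lfloor 0.10\, n(n-1)/2 \rfloor$
strongest entries by *signed* correlation are kept (973 edges for
$n = 140$). Ranking by signed rather than absolute correlation follows
the hub-disruption literature this pipeline builds on. Ties at the cut
are broken lexicographically on the upper-triangle index so the edge
count is exact and platform-independent; the result is invariant to any
strictly monotone transform of the weights.

## Nodal metrics and the hub disruption index

Eight binary-graph nodal metrics are screened: degree, clustering
coefficient, betweenness centrality (unnormalised, each unordered pair
counted once, per component), eigenvector centrality (principal
eigenvector of the largest component, unit Euclidean norm, zeros
elsewhere), k-coreness, flow coefficient, local efficiency, and
participation coefficient. The flow coefficient is the standard binary
definition: the fraction of a node's neighbour pairs *not* directly
linked, whose local length-2 path therefore flows through the node; it is
0 for degree < 2 and complements the clustering coefficient on binary
graphs. The participation coefficient needs a module map; when none is
supplied, a single-slice modularity partition of the same graph at
resolution 1 is used. Every metric is validated in the test suite against
brute-force enumeration oracles (exhaustively over all labelled connected
graphs on up to 5 nodes, plus randomized graphs up to 15 nodes).

The hub disruption index $\kappa$ of a subject is the OLS slope (with
intercept) of (subject − control-mean) nodal values regressed on the
control mean across ROIs. Patients are referenced to the full control
cohort; each control is referenced to the remaining controls
(leave-one-out). Groups are compared by a two-tailed Welch t-test —
the unequal-variance form is a deliberate choice where only "two-sample
t-tests" is specified, since patient and control kappas have different
reference structures.

**Calibration caveat.** Because every subject shares (nearly) the same
reference, kappas are correlated and the group test is only calibrated
when the true nodal profile's variance across ROIs dominates the
reference-mean noise. The test suite demonstrates both regimes: with
flat, noise-dominated profiles the null rejection rate roughly doubles
its nominal level — the estimator's documented noise sensitivity — while
with informative reference profiles (hub structure present in both
groups) the rejection rate is close to 5%. Robustness checks recompute
the group test after removing the top 5% of ROIs by reference mean, or a
random 90% of ROIs.

## Multislice modular reorganisation

The group-level consensus method couples all subjects of one group into a
single categorical multislice network: each subject's binary graph is one
slice, and every node is linked to its copies in all other slices with
coupling $\omega$. The quality of a partition $g_{is}$ is

$$Q = \frac{1}{2\mu} \sum_{ijsr} \Big[ \Big(A_{ijs} - \gamma
\frac{k_{is} k_{js}}{2 m_s}\Big)\delta_{sr} + \delta_{ij}\,\omega\,
(1 - \delta_{sr}) \Big] \delta(g_{is}, g_{jr}),$$

with per-slice configuration null model and
$2\mu = \sum_s 2 m_s + \omega n S(S-1)$. Defaults are $\gamma = 1.5$
(about 10–20 modules on cohort-scale brain graphs) and $\omega = 0.1$
(moderate coupling). With one slice and $\omega = 0$ this reduces exactly
to Newman–Girvan modularity; the tests verify that identity against a
literal double-sum oracle.

Optimisation is a generalized Louvain: randomized node-move sweeps over
node-slices followed by community aggregation, with per-slice degree
vectors carried through aggregation so the null model stays exact at
every level. The implementation is in C++; its RNG (xorshift64* on a
splitmix64-scrambled state) is platform-independent, and all derived
seeds are integer-hashed so that the streams of neighbouring repetitions
and permutations are uncorrelated — with a linear seed chain the
permutation distribution was measurably biased.

Each group's agreement matrix is built by repeated subsampling: per
repetition, `n_subsample` subjects (default 70, matching the smaller
group's scale) are drawn, the multislice partition is optimised, and each
ROI pair records the fraction of subject-slices sharing a module label;
the agreement matrix is the mean over repetitions. The per-repetition
co-labelling fraction (rather than a per-repetition consensus partition)
is the design choice where the construction was underdetermined; it is
the natural consensus-clustering estimator and makes the agreement entry
an unbiased co-module probability. Binary 10%-density graphs are the
modularity input, consistent with the hub-disruption analyses; weighted
input is out of scope.

The agreement difference $AD = A_{pain} - A_{control}$ yields per ROI a
positive sum (module partners gained), a negative sum (partners lost) and
the overall metric `positive_sum + |negative_sum|`. Inference permutes
subjects into two groups of the original sizes and repeats the *entire*
analysis (subsampling included); one-sided add-one p-values
$p = (1 + \#\{perm \ge obs\})/(n_{perms} + 1)$ are reported for the
overall metric and separately for each part. The add-one estimator avoids
$p = 0$ and is the standard Monte-Carlo convention. Two practical notes,
both demonstrated in the tests: (i) with very clean planted structure the
statistic degenerates to exactly 0 and the $\ge$ tie rule pushes p-values
to 1 — uniformity of null p-values is a property of noisy, continuous
regimes; (ii) p-values are strongly dependent across ROIs within one
cohort, so the calibration test pools p-values across independent null
cohorts. Full-scale defaults (1000 repetitions / 1000 permutations) sit
behind `profile = "full"`; the desk profile uses 100/200.

## Classifiers

**Linear SVM.** Features are Fisher-z correlations. Validation model 1
trains on all sites but one and tests on the held-out site; validation
model 2 pools sites under stratified leave-two-subjects-out CV (one
patient + one control of the same site per fold). Per bootstrap a
balanced subsample (equal class counts per site, as large as possible) is
drawn and the whole pipeline runs inside the training data of each fold:
univariate two-sample t-test feature selection at $p < 0.05$
(uncorrected), per-feature standardisation, and C grid search over
$10^{-3} \dots 10^3$ by Leave-3-Out CV. Standardisation on training folds
is applied and logged; whether the original analysis standardised is not
stated. Labellings: patient/control, gender, and depression split at
BDI ≥ 3. Permutation p-values rerun everything (bootstraps included)
under shuffled labels. A leakage test verifies that flipping held-out
labels leaves all training artefacts bit-identical.

**Conditional VAE.** The density classifier models per-frame ROI vectors
$x_j$ conditional on the class $y$. Encoder and decoder are 4-layer MLPs
(widths $n_0, n_1, n_2$, latent $n_3$; full scale 140/100/50/10) with
layer normalisation (no affine parameters) + ReLU on hidden layers,
identity outputs, and the condition injected as an extra bias on the
encoder's second and the decoder's first hidden layer. The decoder output
is a diagonal Gaussian with learned per-ROI variance — the choice that
makes the per-ROI marginal log-density, and hence the contribution
weights $\mathcal{L}_i$, well defined. Training minimises the
single-sample ELBO (reconstruction + KL) with Adam
($\alpha = 10^{-3}, \beta_1 = 0.9, \beta_2 = 0.999$); mini-batches draw
equal numbers of patients and controls from every site. Backpropagation
is hand-written and checked against numerical differentiation in the
tests. Subjects are classified by the summed per-frame reconstruction
log-density under each label (ensemble: sum over models; equal priors;
ties go to control). The conditional KL term is excluded from the
classification score: it is a property of the inference network under
each label, contributes a data-independent offset, and empirically biased
all subjects toward one class. Evaluation fixes the latent at the
posterior mean for reproducibility. Desk-scale defaults (halved widths,
ensemble 5, capped iterations) train in seconds; the full-scale profile
is `profile = "full"`.

## The synthetic cohort generator

Node $i$ in module $m$ follows
$x_i(t) = \sqrt{w - b}\,L_m(t) + \sqrt{b}\,G(t) + \sigma\,\epsilon_i(t)$
with white module latents $L_m$, a global latent $G$ and white noise;
with the default $\sigma = \sqrt{1 - w}$ the population correlation is
exactly $w$ within modules and $b$ between ($w = 0.5$, $b = 0.05$ by
default). All channels pass the same 0.008–0.1 Hz band-pass, which
preserves the instantaneous correlation structure while giving synthetic
data the spectral support the pipeline assumes. Sites differ in frame
count (300/234/244), repetition time (2.0/2.5/2.5 s) and a global
variance scale, emulating a three-site acquisition.

Ground truth plants four kinds of structure: (a) reorganised nodes whose
module membership differs between groups (moved to a different existing
module in the pain partition); (b) hubs coupled to three extra module
latents at loading 0.5, attenuated by the factor 0.3 in patients — degree
and centrality drop without changing global density after re-thresholding;
(c) class-signal nodes sharing an extra latent (loading 0.6 by default)
in the pain group only, a covariance difference that survives band-pass
filtering and drives both classifiers; (d) motion traces as low-amplitude
random-walk drift with single-frame spikes (about one per 75 frames,
0.6–2 mm), yielding retained-frame fractions in the range reported for
real cohorts. Effect sizes are chosen for test power, not clinical
realism: the true effect size of group differences in real data is
unknown, so parameter-recovery tests demonstrate that the machinery
detects what was planted, not that real effects are detectable.

What the generator does **not** emulate: haemodynamics, spatially
structured physiological noise, site-specific artefact spectra,
registration error, or heterogeneous symptom-driven effects. Passing
recovery tests therefore validates the estimators and their inference
machinery — not the claim that a given real dataset carries the effects.

## Problem sizes in the test suite

Tests run at sizes chosen so the whole suite completes on one CPU in
minutes, as the package's own desk scale: reorganisation recovery uses
140 ROIs, 80 + 80 subjects, 6 planted nodes, subsample 25, 4 repetitions
and 100 permutations per replicate (20 replicates); permutation
calibration pools 3 null cohorts of 30 ROIs at 20 repetitions / 200
permutations; HDI null calibration uses 500 cohorts of 30 ROIs with
10 + 10 subjects; the SVM checks use 16-ROI cohorts with 100-permutation
inference; the CVAE check uses 20 seeded runs of a 15-ROI, 3-site cohort
with an ensemble of 3. The paper-scale settings (1000/1000 resampling,
ensemble 100, full widths) remain available behind the `"full"`
profiles.

## Known limitations

- The agreement construction within a repetition is a co-labelling
  fraction; alternative consensus constructions (per-repetition consensus
  partitions) would give systematically sharper agreement matrices.
- Permutation resampling preserves the original group sizes; whether the
  original analysis resampled at 71/87 or 70/70 is not determinable.
- Nuisance regression does not include regressor derivatives.
- The HDI group test's calibration depends on the informativeness of the
  reference profile (see above); significant HDI differences on noisy
  data should be read with the documented inflation in mind.
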