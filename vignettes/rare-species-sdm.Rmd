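---
title: "Modelling rare species by phylogenetic niche imputation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rare species by phylogenetic niche imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phyloSDM)
```

# The problem

Presence-background distribution models degrade quickly below a few dozen
occurrences and are conventionally abandoned below five. In clades where
rarity is phylogenetically clustered — close relatives preferring similar
climates — the phylogeny itself carries usable niche information.
`phyloSDM` operationalizes that idea: niche descriptors estimated for
well-sampled species are transferred to data-poor relatives under a
Brownian-motion (BM) model of niche evolution, and a geometric
pseudo-presence rule supplies the minimum of five presence cells needed to
turn an imputed niche into a suitability map. This vignette documents the
model, its tunable parameters, the synthetic validation design, and the
numerical and design decisions a maintainer would want to know.

# The niche model

## ENFA

All environments are standardized per layer to mean 0, sd 1 over the
background sample, using *population* (1/n) moments; the same estimator is
used for 5-point and 500-point presence clouds so that small-sample fits
are not systematically narrower than large ones. For a species with
presence matrix $Z_p$ and background $Z_g$ (standardized):

* marginality $m = \bar{Z_p}$; overall marginality $M = \lVert m\rVert/1.96$,
  so $M \approx 1$ means a one-sd displacement at the 95% envelope;
* specialization axes: eigenvectors of the generalized problem
  $S_g u = \lambda S_p u$ restricted to the orthogonal complement of $m$,
  computed via the symmetric whitened form after a Cholesky factorization;
  eigenvalues are the background-to-presence variance ratio along the axis;
* each axis is sign-fixed (largest-|loading| entry positive) so axes are
  comparable across species — a precondition for imputation;
* $k = \min(k_{spec}+1,\ V,\ n_p-2)$ factors are retained, the marginality
  direction first; the presence cloud's centroid $\mu_F$ and covariance
  $S_F$ in factor space complete the model.

Suitability of a cell with factor projection $f$ is
$P(\chi^2_k \ge D^2)$ with $D^2 = (f-\mu_F)^\top S_F^{-1}(f-\mu_F)$. The
chi-square survival mapping was chosen (over rank or max normalization,
neither of which is dictated by the method's description) because it yields
a calibrated [0, 1] scale with suitability exactly 1 at the niche centroid
and a monotone decrease in Mahalanobis distance.

## Imputation

The trait vector transferred along the tree is
$[m;\ \sqrt{\lambda_1}U_1;\ \sqrt{\lambda_2}U_2]$ (s = 2 specialization
axes by default). Scaling axes by $\sqrt{\lambda}$ lets specialization
*magnitude* survive the implicit averaging of BM conditional expectation;
unscaled unit axes would lose it. Per trait dimension, with phylogenetic
covariance $C$ from the tree's branch lengths, the imputed value for target
$t$ given observed tips $o$ is

$$\hat{x}_t = \hat\mu + C_{to} C_{oo}^{-1} (x_o - \hat\mu \mathbf{1}),
\qquad \hat\mu = \frac{\mathbf{1}^\top C_{oo}^{-1} x_o}
{\mathbf{1}^\top C_{oo}^{-1}\mathbf{1}},$$

with conditional variance $\hat\sigma^2 (C_{tt} - C_{to}C_{oo}^{-1}C_{ot})$
reported per dimension. Decoding inverts the encoding: each axis block's
norm restores $\lambda$, its direction the axis; $\mu_F, S_F$ are recomputed
from the species' own (possibly extended) presence cells projected on the
imputed axes.

Phylogenetic uncertainty: the fit is repeated over the input tree plus 49
perturbed trees (one random nearest-neighbour tip swap plus log-normal
branch jitter, sd 0.1 — the perturbation is deliberately isolated in
`perturbTree()` so a different scheme can be substituted), and the
replicate with the best mean cross-validated AUC wins; replicates below AUC
0.7 are discarded, and a species whose every replicate fails is reported as
model-rejected rather than silently mapped.

## The five-cell extension

Below five presence cells, candidates are the cells a chess-knight move
(±1, ±2 / ±2, ±1) from any reference cell, excluding off-grid, nodata and
reference cells. Candidates are ranked by the mean Pearson correlation
("angle") between their standardized environmental vector and each
reference's vector — the mean (not the max) across references, which is
stabler for 2–4 references and uses all of them. Exactly $5-n$ are
promoted; ties break toward the geographically closest candidate, then
row-major order, making selection fully deterministic. Single-cell species
are excluded from modelling altogether.

# Tiers, ensembles, evaluation

Species with 15–30 cells are fitted with ensembles of small models: every
bivariate layer pair per learner, AUC-filtered (≥ 0.7) and AUC-weight
averaged. Above 30 cells, the three learners use all layers at once. The
learners are a quadratic-term GLM with pairwise products (interaction
level 1; products are toggleable), a 500-tree random forest scoring by
vote fraction, and — in place of the Java MaxEnt application — an
L1-penalized presence-background logistic model on the same expanded
features with classes balanced by weight and the penalty chosen by 5-fold
CV. The penalized logistic formulation is the standard statistical
equivalent for SDM use and sits behind the learner enum so a true MaxEnt
backend could be substituted. All hyperparameters are explicit arguments
with the stated defaults rather than inherited from any modelling
framework's defaults.

Evaluation is a 10-replicate bootstrap: per replicate a random 20% of
presences and background is set aside untouched, a training multiset of
size ⌈0.8 n⌉ is drawn *with replacement* from the remaining 80%, and AUC
(Mann–Whitney), TSS (exhaustive threshold scan) and the continuous Boyce
index (101 overlapping windows of width range/10; zero-background windows
dropped; undefined below 3 usable windows) are computed on the holdout. A
replicate whose test partition lacks a presence or a background point is
skipped with a warning; requiring two or more test presences would make
every five-presence rare fit unevaluable (the 20% partition of five cells
is always a single cell), so one presence — the minimum for a defined
AUC — is the rule, and rare-species AUCs should be read as averages of ten
single-presence ranks.

# Projection, thresholds, dispersal, interactions

Three threshold rules binarize every map (presence at score ≥ value):
SensSpec minimizes |sensitivity − specificity|; MaxSensSpec maximizes
TSS; TenPerc is the nearest-rank 10th percentile of training presence
scores. The "TenPerc" reading (rather than minimum training presence,
which the same label sometimes denotes) matches the abbreviation and is
the more conservative rule; the alternative is one argument away. The
prediction factorial per species is 3 current maps + 18 dynamic-climate
(3 GCMs × 2 SSPs × 3 thresholds) + 6 dynamic-land-use (GCM-free, climate
held constant) + 18 dynamic-both = 45, with current maps counted.

The dispersal constraint buffers the occurrence minimum convex polygon by
rate × horizon (default 1 km/yr over 2010–2070 = 60 km; the horizon is a
config value) in planar geometry; two-point ranges degenerate to a
buffered segment. Masks keep every occurrence cell by construction,
cropping never creates presences, and crop∘crop = crop.

Per-cell interaction classification uses the loss (or gain) counts under
dynamic land use (*a*), dynamic climate (*b*) and dynamic both (*c*),
with precedence: no-interaction (a=b=c=0), climate-only (a=0, b>0),
land-use-only (b=0, a>0), then synergistic / additive / antagonistic by
comparing *c* with *a+b*. The precedence ensures cells with a single
active driver never enter the synergy comparison; the antagonistic
condition, often written as a three-way union of clauses, reduces to
*c* < *a*+*b* whenever both drivers act, and the test suite proves that
equivalence by brute force over all integer triples ≤ 20. The corner case a=b=0, c>0
(covered by no printed rule) classifies as synergistic since c exceeds
a+b=0. Percentages are computed per (threshold, GCM) combination over
classifiable cells only, then averaged across combinations — never by
averaging a, b, c before classification.

Residual spatial autocorrelation is assessed with Moran's I correlograms
(binary distance-class weights, permutation p-values two-sided around the
null mean −1/(n−1)).

# The synthetic validation design

The generator emulates the data a real application would download, with
known truth:

* **Landscape** (default 60 × 60 cells, 1 km): 5 climate layers = an
  oriented linear gradient plus Gaussian-kernel-smoothed noise (range 6 km,
  unit variance), and 3 land-cover layers = Euclidean distance transforms
  from 5 random category patches — mirroring distance-to-category
  predictors.
* **Clade**: 32 species on a birth–death tree scaled to unit height; niche
  optima evolve by BM (rate 1) and are mapped affinely onto each layer's
  observed mean ± sd, so optima are realistic for the landscape and retain
  their phylogenetic signal. Niche breadths are uniform multipliers
  (0.6–1.4) of each layer's sd — breadth is the rarity dial.
* **Occurrences**: cells drawn without replacement with probability
  proportional to Gaussian truth suitability; default counts cycle through
  2–60 so every tier, including 2–4-cell species, is populated.
* **Scenarios**: future climate = per-layer shift (half for the mild
  scenario, full for the severe) plus independent per-GCM jitter — the
  GCM analogue; future land use = a fraction of patches relocated and
  distances recomputed. Dynamic-climate members copy land-cover layers
  bit-for-bit from the present, and vice versa.

On a 3600-cell grid the nominal 10,000 background points cap at the 3600
valid cells (with a warning); validation therefore runs with an exhaustive
background, which only makes the evaluation stricter. The validation suite
checks, among others: imputation recovery (masked BM traits, mean r > 0.7
over 20 replicate clades), rare-species suitability vs truth (Spearman
ρ > 0.5 for 2–4-cell species), and data-rich ensemble AUC > 0.8. Problem
sizes (20 replicate clades, 10 tree replicates for recovery checks, two
data-rich species for the ensemble check) were chosen to keep the full
validation run in minutes on a single core while leaving the statistics
stable across seeds.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sampling bias and spatial clustering of records
beyond suitability weighting, coordinate error, niche evolution departing
from BM (e.g. punctuated shifts or attraction), disequilibrium between
occupancy and suitability, correlated climate–land-use change, and real
GCM structure. The ecoregion background mask of a real analysis is a
caller-supplied input, since no general rule reconstructs it.

# Numerical choices

* Population (1/n) covariance and sd estimators everywhere.
* $S_F$ is ridged by $10^{-6}\,\mathrm{tr}(S_F)/k$; fits with fewer than
  10 presence cells additionally get an eigenvalue floor of $10^{-2}$
  (background-sd units). Without the floor, bootstrap refits from four
  resampled cells can collapse an axis to near-zero variance, $D^2$
  explodes and the chi-square tail underflows to zero for every cell,
  erasing the score ranking the evaluation depends on. The floor says "a
  presence sd along any axis is at least 0.1 background sd", a weak and
  ecologically innocuous prior at that sample size.
* Degenerate marginality (presences centred on the background mean) falls
  back to the first layer axis with a warning; constant candidate vectors
  in angle ranking score −∞ and sort last; GLM separation falls back to a
  ridge fit with a warning.
* Thresholds declare presence at score ≥ value, fixed for
  reproducibility; all tie-breaks (collinearity elimination, pseudo-
  presence ranking) resolve toward earlier input order or smaller
  row-major index.
* Every random step derives a 31-bit sub-seed from the master seed, the
  stage label and the species label, so results are reproducible
  end-to-end and adding a species never perturbs another's stream.
* The collinearity screen eliminates greedily by largest mean absolute
  correlation until no pair exceeds the cutoff (0.7), dropping
  zero-variance layers first.

# Limitations

Planar-kilometre geometry only — geographic inputs must be projected
first. The dispersal buffer ignores landscape connectivity. The BM model
is the only niche-evolution model offered. Supertree assembly and
divergence dating are out of scope: the tree is an input with branch
lengths. TSS and Boyce for rare species may be biased low because model
selection across trees optimizes AUC; no correction is applied, and the
reported TSS/Boyce should be read with that caveat.
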