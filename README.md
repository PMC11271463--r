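# phyloSDM

Species distribution models (SDMs) need tens of occurrence records, yet in
most clades the species of highest conservation concern are exactly the ones
with a handful of them. `phyloSDM` implements a tiered modelling framework
for whole clades that keeps those species in the analysis instead of
discarding them: niche information flows from well-sampled relatives to
data-poor species along a phylogeny, and a pseudo-presence extension pushes
modelling down to **two** occupied grid cells. It is aimed at spatial
ecologists and conservation analysts who need clade-wide current and future
distribution maps — including rare endemics — plus the downstream diversity
accounting (richness, loss, gain) and a per-cell decomposition of how climate
change and land-use change interact.

## The model

Species are routed by occupied-cell count *n*:

| tier | occupied cells | model |
|---|---|---|
| rare | *n* < 15 | phylogenetically imputed ENFA + Mahalanobis suitability |
| intermediate | 15 ≤ *n* ≤ 30 | ensembles of bivariate small models (ESM) |
| data-rich | *n* > 30 | GLM / random forest / penalized presence–background logistic ensemble |

**ENFA.** With cell environments standardized to mean 0, sd 1 over 10,000
background cells, a well-sampled species yields a marginality vector
*m* = mean presence environment (overall marginality *M* = ‖*m*‖/1.96) and
specialization axes: eigenvectors of the background-to-presence
variance-ratio operator S⁻¹ₚS_g restricted to the orthogonal complement of
*m*, with eigenvalues λ ≥ 1 flagging narrowed niche axes.

**Phylogenetic imputation.** Each species' niche is encoded as
[*m*; √λ₁U₁; √λ₂U₂] and treated as a Brownian trait on the clade phylogeny.
For a rare species *t* with observed relatives *o*, the imputed trait is the
BM conditional expectation μ̂ + C_to C_oo⁻¹ (x_o − μ̂1), with μ̂ the GLS root
state and C the phylogenetic covariance. Phylogenetic uncertainty is
handled by refitting over 50 randomly perturbed trees and keeping the
replicate with the best cross-validated AUC (replicates with mean AUC < 0.7
are discarded).

**Below five cells.** Cells one chess-knight move from the references are
candidate pseudo-presences; the 5 − *n* candidates whose standardized
environmental vectors correlate best with the references are promoted, so
every rare species reaches exactly 5 potential presence cells.

**Suitability.** Presences are projected onto the retained factor axes;
each cell's squared Mahalanobis distance D² to the presence centroid maps to
suitability = P(χ²_k ≥ D²), a calibrated [0, 1] scale.

**Projection.** Fitted models are evaluated by 10× bootstrap
cross-validation (80–20, AUC/TSS/Boyce), AUC-weight averaged, projected onto
current and future stacks (dynamic climate × 3 GCMs × 2 SSPs, dynamic land
use, dynamic both), binarized under three threshold rules (SensSpec,
MaxSensSpec, TenPerc) — 45 maps per species — and cropped by a dispersal
buffer (1 km/yr over 2010–2070 = 60 km) around the occurrence minimum convex
polygon. Stacked maps give per-cell richness/loss/gain, and the loss (or
gain) counts *a* (land use only), *b* (climate only), *c* (both) classify
each cell as synergistic (*c* > *a*+*b*), additive (*c* = *a*+*b*),
antagonistic (*c* < *a*+*b*), climate-only or land-use-only.

Everything is validated on a synthetic virtual clade with known truth:
correlated environmental layers, niche optima evolved by Brownian motion on
a simulated phylogeny, Gaussian truth suitability, and occurrence counts
spanning 2 to 60.

## Worked example

```r
library(phyloSDM)

clade <- simulateVirtualClade(nrows = 40, ncols = 40, nSpecies = 12,
  occurrenceCounts = c(3, 4, 20, 40, 50, 60, 35, 45, 55, 38, 42, 48),
  seed = 11)
bg  <- sampleBackground(clade$stack, 1500, seed = 2)
std <- standardizeStack(clade$stack, bg)

# ENFA for every well-sampled species
rich   <- names(clade$counts)[clade$counts >= 15]
models <- setNames(lapply(rich, function(sp)
  fitEnfa(std$stack, clade$occurrences[[sp]]$cellIds, bg$cellIds)), rich)
models[["sp03"]]
#> EnfaModel on 8 layers: M = 0.681, k = 3 factors
#>   specialization eigenvalues: 699, 105, 43.7, 11.4, 3.25, 1.96, 0.755

# a 3-cell species, imputed from its relatives
traits <- nicheTraitTable(models)
fit <- fitEnphylo("sp01", clade$occurrences[["sp01"]]$cellIds,
                  clade$tree, traits, clade$stack, bg,
                  nTreeReps = 10, seed = 42)
fit
#> RareFit 'sp01': 3 reference + 2 pseudo-presence cells
#>   chosen tree replicate: 1; mean AUC = 0.733

# against the generator's known truth surface
truth <- clade$truth[["sp01"]]
ok <- !is.na(truth) & !is.na(fit@suitability)
cor(truth[ok], fit@suitability[ok], method = "spearman")
#> [1] 0.7476574
```

`M = 0.681` says sp03's mean habitat sits ~1.3 background-sd from the mean
available environment; the leading eigenvalue (699) marks a strongly
narrowed niche axis. For the 3-cell species, two knight-move cells were
promoted to reach 5 presences, the input tree beat 9 perturbed replicates,
and the resulting map rank-correlates at ρ ≈ 0.75 with the true (normally
unobservable) suitability surface.

The full pipeline — screening, tiering, fitting, projection, binarization,
dispersal cropping, richness stacking, interaction classification — runs as
`runPipeline(defaultConfig())`, or from a shell via
`inst/scripts/sdm-pipeline.R`.

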