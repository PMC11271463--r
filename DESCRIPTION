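Package: phyloSDM
Title: Phylogenetically Informed Distribution Modelling for Rare Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tiered species distribution modelling for clades containing
    very rare species. Well-sampled species are modelled by Ecological-Niche
    Factor Analysis (ENFA) and ensembles of presence-background learners;
    the niche axes (marginality and specialization) of data-poor species are
    imputed along a phylogeny under a Brownian-motion model and converted to
    habitat suitability through Mahalanobis distances, with a knight-move
    pseudo-presence extension that pushes modelling down to two occurrence
    cells. Includes dispersal-constrained scenario projection, stacked
    richness/loss/gain surfaces, a climate-by-land-use interaction
    classifier, Moran's I residual correlograms, and a synthetic
    virtual-species generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    ape,
    jsonlite,
    glmnet,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    picante,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
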