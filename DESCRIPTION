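Package: neuroslope
Title: Disentangling Accelerated Cognitive Decline from Normal Aging with
    Longitudinal Imaging Pairs and Quantitative-Trait GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to learn the normal-aging component of longitudinal
    cognitive decline from paired structural MRI volumes with a dual-loss
    Siamese network (shared-weight encoder, first-visit score regression head,
    and contrastive head on the embedding distance), to derive per-subject
    accelerated cognitive-decline slopes by rank-based inverse normal
    transformation and residualization, and to run the downstream
    covariate-adjusted quantitative-trait association scan with variant and
    sample quality control, KING-robust relatedness filtering, LD pruning,
    principal components, and LD-based lead-SNP locus definition. A synthetic
    cohort generator (linear cognitive trajectories, intensity-encoded
    phantom volumes, Hardy-Weinberg genotypes with optional LD blocks and
    planted causal variants) makes the whole pipeline testable end to end
    without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
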