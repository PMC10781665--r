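Package: biogeo
Title: Multi-Organ Microbiome Biogeography Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intra-individual, multi-organ 16S amplicon
    surveys of the human surface organs (skin, oral cavity and the digestive
    tract). Provides validated readers for ASV count tables, sample metadata,
    Greengenes-style taxonomy and newick phylogenies; a synthetic study
    generator with planted ground truth; contamination control (rarefaction,
    rare-taxon filtering and prevalence-based contaminant scoring against
    negative controls); alpha/beta diversity with UniFrac, PCoA and
    covariate-adjusted PERMANOVA; an overdispersed beta-binomial logistic
    regression for paired lumen/mucosa niche enrichment; SparCC compositional
    correlation networks with organ-specificity rules; and inter-organ
    translocation analysis from presence, prevalence and subject-level
    abundance correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    phyloseq,
    biomformat,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    optparse
Config/testthat/edition: 3
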