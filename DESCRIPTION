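Package: fiberguilds
Title: Guild Detection and SCFA Response Analysis for Fiber Intervention Microbiome Studies
Version: 0.1.0
Authors@R: person("FYBER", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-arm dietary fiber intervention studies of
    the gut microbiota. Provides compositional data analysis (centered log-ratio
    transform, Aitchison distances, PERMANOVA, nonparametric test batteries with
    Benjamini-Hochberg FDR), detection of co-abundance response groups (CARGs,
    ecological guilds) by hierarchical clustering of CLR shifts with
    PERMANOVA-guided tree cutting, permutation-tested Spearman co-response
    networks, short-chain fatty acid responder stratification, and an
    AICc-ranked multiple linear regression screen linking microbiota and diet
    features to SCFA responses. Includes a synthetic longitudinal study
    generator with planted guild structure and ground-truth evaluators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
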