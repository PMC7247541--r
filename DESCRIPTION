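Package: epimsap
Title: Population Epigenetics of Methylation-Sensitive AFLP (MSAP) Epiloci
Version: 0.1.0
Authors@R: person("epimsap", "developers", role = c("aut", "cre"),
    email = "epimsap@example.org")
Description: Tools for dual-enzyme (HpaII/MspI) methylation-sensitive AFLP
    data: three-state epilocus scoring with size-range and replicate
    reproducibility filters, per-group diversity summaries (polymorphic,
    private and Shannon statistics), distance-based AMOVA with permutation
    Phi-ST, NMDS ordination, stratified Mantel tests, Moran's I and local
    Geary's C spatial autocorrelation, and per-epilocus logistic
    environmental association with Wald and likelihood-ratio (G) model
    selection. Includes a synthetic-study generator emulating a mixed
    diploid/tetraploid sexual-apomictic sampling design so every stage is
    testable without external data, and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
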