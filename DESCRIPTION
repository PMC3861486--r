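Package: pedexome
Title: Pedigree-Driven Filtering and Prioritization of Family Exome Variants
Version: 0.1.0
Authors@R:
    person("pedexome", "developers", email = "pedexome@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate causal variants in small disease
    pedigrees from multi-sample exome variant calls. Implements
    inheritance-model consistency testing (autosomal dominant/recessive,
    X-linked dominant/recessive) by exhaustive genotype assignment search
    under full penetrance, transcript-model based consequence annotation with
    HGVS c./p. naming, a staged annotation/frequency filter cascade with
    per-step accounting, consensus-deleteriousness prioritization over
    categorical predictor profiles with control-panel screening and
    cosegregation checks, and a seeded synthetic family-exome generator with
    a planted causal variant for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
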