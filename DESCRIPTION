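Package: fadpheno
Title: Multi-Modal Phenotyping Analytics for Amyloid Mouse Model Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for deep-phenotyping studies of amyloid
    transgenic mouse models. Implements rule-based EEG sleep staging and
    spike-wave-discharge train detection, amyloid plaque segmentation with
    atlas-region fractional-area density mapping, PET standardized-uptake-
    value-ratio normalization with principal-component consensus-region
    selection and genotype-by-age ANOVA, behavioral and frailty-index
    scoring, and a sex-by-genotype expression linear model with correlation
    against human co-expression module signatures. Seeded synthetic-data
    generators emulate every input modality so the whole pipeline is
    verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    tiff,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
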