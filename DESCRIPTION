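Package: nmascope
Title: Genotype-Phenotype Dissection Toolkit for Non-Muscle Actinopathies
Version: 0.1.0
Authors@R:
    person("NMA", "Toolkit Authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational tools for dissecting disorders caused by
    constitutional variants in the cytoplasmic actin genes ACTB and ACTG1
    (non-muscle actinopathies, NMAs). Provides exhaustive in-silico
    saturation of single-nucleotide variants over coding transcripts with
    internal consequence annotation and nonsense-mediated-decay escape
    calls; comparison of the enumeration against population variant
    tables; a deterministic rule-based clinical classification workflow
    with an auditable rule trace; cosine-distance cohort-delineation
    statistics for facial-embedding vectors (resampling nulls, ROC
    thresholds, positive predictive values, cohesion percentiles);
    single-exponential fitting of pyrene-actin kinetic traces and
    first-derivative melting-point extraction from thermal-shift curves;
    and seeded synthetic-data generators for every input family, wired
    into an end-to-end pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
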