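Package: mitotempo
Title: Temporal Mitochondrial Population Genetics with Serial-Coalescent ABC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing mitochondrial genome diversity between
    historical (museum) and modern samples of the same population. Provides
    alignment input/masking/partitioning, haplotype calling with
    missing-data-aware merging, diversity indices (haplotype diversity,
    nucleotide diversity, Tajima's D, Hudson's FST), variant classification
    against a mitochondrial gene annotation, minimum spanning haplotype
    networks, permutation subsampling to control for unequal sample sizes, a
    heterochronous (serially sampled) coalescent simulator with a
    finite-sites Ts/Tv-biased mutation model, and an approximate Bayesian
    computation framework (rejection plus local-linear regression
    adjustment) for choosing among recent demographic models and estimating
    past versus present female effective population size, including
    pseudo-observed-dataset power analysis. A synthetic-data module emulates
    a museum-plus-modern sampling design so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    parallel,
    stats,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
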