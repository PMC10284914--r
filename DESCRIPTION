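Package: photohet
Title: Marker-Gene Abundance, Amplicon Recruitment and Rhodopsin Screening
    for Marine Photoheterotrophs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-based tools for studying the distribution of
    photoheterotrophic marine bacteria. Provides affine-gap global and
    semiglobal pairwise alignment with a gap-excluded percent-identity
    statistic, 16S rRNA amplicon read recruitment against window-trimmed
    reference fragments with relative-abundance profiling, single-copy
    marker-gene abundance and accessory-operon copy-number estimation from
    gene-catalog coverage matrices, rhodopsin subfamily classification with
    a retinal-binding-lysine filter and greedy identity clustering, and
    seeded simulators that generate inputs with known ground truth for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
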