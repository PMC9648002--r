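Package: persoma
Title: Somatic Variant Comparison Across Personal Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares tumor-normal somatic variant callsets between a
    standard reference assembly and a de novo assembled personal genome.
    Provides flanking-sequence lift-over of SNVs and structural variants
    (SVs) between assemblies with a two-step identity/length gate and a
    four-way classification (identical, equivalent, mapped-without-call,
    unmapped), joint-genotype somatic SV selection with germline
    subtraction, breakpoint-distance consensus merging across callers and
    replicates, assembly contiguity statistics including the Top50 summed
    scaffold length, circular mitochondrial genome rotation and pairwise
    comparison, and a deterministic dual-assembly simulator that plants
    germline and somatic truth variants so the whole pipeline can be
    exercised and scored without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
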