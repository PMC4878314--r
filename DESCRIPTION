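Package: phantomtaxa
Title: Sampling Theory and Comparative Analysis of Paired rRNA/rDNA
    Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models jointly observed total (rDNA) and metabolically active
    (rRNA) microbial communities. A community is realized from a species
    abundance distribution together with a class-wise activity profile
    (fraction of active taxa at each abundance) and activity intensity
    (rRNA:rDNA copy ratio of active taxa). The package provides analytic
    and Monte-Carlo rarefaction expectations for rDNA richness, rRNA
    richness and "phantom" taxa (OTUs detected in rRNA but not rDNA
    libraries), a synthetic generator of paired rRNA/rDNA OTU count tables
    at finite sequencing depth, and a comparative analysis pipeline
    computing OTU partitions, rRNA:rDNA activity ratios, ratio-abundance
    correlations, alpha diversity and Canberra distances.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests: optparse, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
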