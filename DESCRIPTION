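Package: bsamplicon
Title: Bisulfite Amplicon Methylation Analysis for Plant Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cytosine methylation in plant promoter windows from
    bisulfite-converted amplicon sequences. Classifies cytosines into the
    plant contexts CG, CNG and CNN, simulates bisulfite conversion in silico,
    aligns converted amplicons to their reference with bisulfite-aware
    asymmetric scoring, calls per-site methylation from C-to-T substitutions,
    estimates bisulfite conversion rates, and produces per-context summary
    tables, unmethylated-cytosine distributions, temporal pattern
    classifications over a germination time course, and methyltransferase
    activity shares. Includes a seeded synthetic-data generator so the whole
    pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    tools,
    utils,
    stats,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
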