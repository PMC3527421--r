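Package: prolaminr
Title: Discovery and Annotation of Prolamin Seed Storage Protein Gene
    Families from Shotgun Reads and ESTs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining cereal prolamin (gliadin, glutenin, hordein,
    secalin) gene families from low-coverage shotgun reads and expressed
    sequence tags. Simulates polyploid prolamin loci with class-specific
    repeat grammars, separates near-identical gene copies into
    distinguishable read sets and builds strictly terminated consensus
    sequences, classifies sequences into prolamin classes by alignment
    identity, annotates domain structure and inactivating defects
    (premature stop codons, frameshifts), tokenizes tandem repeat domains
    into motifs, builds repeat-stripped neighbor-joining phylogenies with
    outgroup rooting, assigns gene copies to genomes by mismatch counting,
    estimates gene copy number from read counts, and tests EST expression
    distributions with a chi-square goodness-of-fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
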