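Package: ystrtools
Title: Forensic Y-STR Haplotype Diversity, AMOVA Rst and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal marker panels: haplotype-table
    ingestion with forensic allele-naming edge cases (microvariant alleles,
    multi-copy loci, Y-InDels), direct-count allele and haplotype frequency
    spectra, the standard forensic summary statistics (gene and haplotype
    diversity, haplotype match probability, discrimination capacity), panel
    subsetting across commercial Y-STR kits, pairwise Rst genetic distances
    via haploid analysis of molecular variance with squared repeat-difference
    distances, classical multidimensional scaling and Neighbor-Joining trees
    of population distance matrices, and a stepwise-mutation-model simulator
    so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
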