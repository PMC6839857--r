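Package: ystrkit
Title: Forensic Y-STR Population Statistics, AMOVA Rst and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic Y-chromosomal short tandem repeat (Y-STR)
    population studies. Reads haplotype tables with multi-copy loci and
    microvariant alleles, computes forensic summary statistics by direct
    counting (allele frequencies, gene diversity, haplotype diversity,
    random match probability, discrimination capacity), estimates pairwise
    Rst between populations by two-level analysis of molecular variance
    (AMOVA) on squared repeat differences with permutation significance,
    and derives population-structure views from the Rst matrix: classical
    (Torgerson) multidimensional scaling coordinates and a neighbor-joining
    tree. A forward-time Wright-Fisher stepwise-mutation simulator generates
    multi-population panels with controlled divergence for testing and
    power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
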