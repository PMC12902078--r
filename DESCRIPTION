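Package: lucfam
Title: Haplotype Calling and Molecular Evolution of Multi-Copy Luciferase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing multi-copy gene families from amplicon
    sequencing data, motivated by the luciferase loci of calanoid copepods.
    Provides a ground-truthed simulator of paralogous gene families with
    recombinant alleles, clone (Sanger) sampling and error-bearing amplicon
    reads; abundance-based haplotype calling with a cross-evidence validation
    cascade (posterior filter, short-indel and premature-stop rules,
    within-sample frequency rule); diagnostic-site family assignment and
    mosaic (recombinant) allele detection; codon-aware population genetics
    from first principles (Nei-Gojobori synonymous/nonsynonymous counting,
    Jukes-Cantor and gamma distance corrections, nucleotide diversity at
    silent and replacement sites, Tajima's D, haplotype diversity,
    divergence, McDonald-Kreitman test); neighbor-joining phylogenetics on
    synonymous distances with codon bootstrap; and exon/intron annotation
    projection with alternative splice-motif enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
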