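Package: baeocomp
Title: Comparative Genomics of Baeocyte-Forming Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Inference chain for multi-strain cyanobacterial comparative
    genomics: taxonomic contig binning from similarity hit profiles,
    reciprocal-best-hit homology classification, Nei-Gojobori (1986)
    synonymous/nonsynonymous divergence estimation with Jukes-Cantor
    correction, windowed-Ks screening for horizontal gene transfer,
    Tajima relative rate tests, gene presence/absence class analysis,
    plasmid-location enrichment by Fisher exact tests, and a calibrated
    multi-strain codon-evolution simulator that provides ground truth
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
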