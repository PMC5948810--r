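Package: gtrecomb
Title: Homologous Recombination Analysis at GT Microsatellites from Cloned Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures homologous recombination (HR) at innate GT-dinucleotide
    microsatellites from cloned amplicon sequences of an intraspecific
    heterozygote. Provides a two-parent locus model with diagnostic markers
    and repeat motifs, anchor-based marker calling and repeat-length
    genotyping, classification of clones into parental, crossover and
    PCR-artifact classes with breakpoint localization, inference of the
    double-strand-break-bearing homolog from repeat lengths, HR-frequency
    estimation with artifact exclusion, and half-tetrad genotyping of
    gynogenetic diploid progeny. A synthetic-data generator emulating a
    heterozygous fish promoter locus (three GT motifs, flanking indel and
    SNP markers) supplies ground-truth datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
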