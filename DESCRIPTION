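Package: cloneMHC
Title: Clone-Based MHC Class IIb Genotyping and Population Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves MHC Class IIb exon-2 haplotypes from cloned amplicon
    sequences using within-individual clone support, cross-individual
    singleton validation and single-crossover PCR-chimera exclusion; assigns
    haplotypes to paralogous loci (DAB/DBB/DCB) by nearest reference sequence
    with a distance margin and calls per-individual copy-number /
    presence-absence classes; and computes the accompanying population-genetic
    layer: haplotype and nucleotide diversity at all, synonymous and
    nonsynonymous sites (Nei-Gojobori counting), Watterson's theta, Tajima's D,
    multi-allelic exact Hardy-Weinberg tests, McDonald-Kreitman and HKA
    neutrality tests, and a counting-based per-codon selection scan.  Includes
    a synthetic cohort generator emulating the cloning process (amplification
    bias, PCR chimeras, per-base error) and a neutral coalescent sampler for
    statistic calibration, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
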