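# Bundled data: the published per-individual class IIb genotype table for
# the Welsh cohort (18 individuals, loci DAB/DBB/DCB, haplotype labels 1-9).

#' Welsh class IIb genotype table
#'
#' The per-individual genotype table of the 18-frog Welsh cohort: haplotype
#' labels (1-9) observed at each of the three class IIb loci, with empty
#' cells where a locus was not detected.  Useful for exercising the
#' genotype-level layer (CNV calls, heterozygosity, association tests)
#' without sequence data.
#'
#' @return named list: per individual, a named list of per-locus integer
#'   label vectors (see [read_genotype_table()]).
#' @export
welsh_genotypes <- function() {
  read_genotype_table(system.file("extdata", "welsh_classIIb_genotypes.tsv",
                                  package = "cloneMHC", mustWork = TRUE))
}
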