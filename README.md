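# cloneMHC

Clone-based genotyping of multigene MHC families, with the population
genetics to interpret the result.

## The problem

The MHC class IIb region of *Xenopus laevis* contains three paralogous loci
(DAB, DBB, DCB) that co-amplify with one conserved exon-2 primer pair, show
presence/absence variation between individuals, and — like any PCR over
mixed templates — produce artefactual mosaic sequences (PCR chimeras).
Studies of such systems genotype by cloning: sequence 14–21 clones per
individual, then decide which distinct clone sequences are real haplotypes.
`cloneMHC` is for researchers doing (or auditing) that kind of study. It
implements:

* **Haplotype resolution** — exact-sequence collapsing of clones, with two
  validation rules: a variant seen in a single clone counts only if the
  identical sequence occurs in another individual, and a variant that can
  be written as a single-crossover mosaic `A[1..b] + B[b+1..L]` of two
  better-supported variants is excluded as a PCR chimera. Plus the
  saturation diagnostic (haplotypes found vs clones sequenced).
* **Locus assignment and CNV calls** — nearest-reference assignment with a
  confidence margin (ambiguous haplotypes are reported `unresolved`, not
  forced), neighbor-joining genealogies with column bootstrap for display,
  and per-individual copy classes: absent / homozygous-like / heterozygous
  / supernumerary.
* **Population genetics** — haplotype diversity `Hd`, nucleotide diversity
  π and its synonymous/nonsynonymous split π_s, π_n (Nei–Gojobori counting
  with pathway averaging), Watterson's θ_w = S/(a₁L), Tajima's D,
  multi-allelic exact Hardy–Weinberg tests (enumeration or Monte-Carlo),
  McDonald–Kreitman and HKA neutrality tests, a counting-based ("SLAC-like")
  per-codon selection scan, within-individual allele distances,
  likelihood-ratio contingency tests and birth-date trend tests.
* **A synthetic cohort generator** — paralogous allele pools with higher
  between- than within-locus divergence, presence/absence genotypes under
  Hardy–Weinberg proportions, clone sampling with Dirichlet-multinomial
  amplification bias, injected chimeras and per-base error, all with full
  truth tables — plus a neutral infinite-sites coalescent sampler for
  calibrating the estimators.

## Worked example

Simulate a cohort shaped like a small closed amphibian population
(18 individuals, 3 loci, 14–21 clones each, 3% chimeric clones), resolve
haplotypes, assign loci, and call copy-number classes:

```r
library(cloneMHC)

cfg    <- scenario_presets(seed = 11)$welsh_like
cohort <- simulate_cohort(cfg)
res    <- resolve_cohort(cohort$clones, cohort$clone_map)
res$catalog
#> haplotype_catalog: 9 haplotypes across 18 individuals

refs <- vapply(unique(cohort$pool$locus_of), function(l)
  cohort$pool$alignment[[which(cohort$pool$locus_of == l)[1]]], character(1))
asn <- assign_loci(res$catalog, refs, names(refs))
head(asn, 4)
#>   haplotype locus nearest_reference    margin
#> 1         1   DAB               DAB 0.2500000
#> 2         2   DBB               DBB 0.2760417
#> 3         3   DAB               DAB 0.2083333
#> 4         4   DBB               DBB 0.1718750

cnv <- call_cnv(genotypes_from_catalog(res$catalog, asn))
cnv$summary$per_locus_class_counts
#>                 DAB DBB DCB
#> absent            0   5  11
#> homozygous-like   1   3   2
#> heterozygous     16  10   5
#> supernumerary     1   0   0
```

All nine simulated alleles are recovered, every haplotype is assigned to
its true locus with a wide margin (≥ 0.17 substitutions/site), DAB is
present in every individual while DBB/DCB show presence/absence variation,
and one individual carries a supernumerary third DAB haplotype — the
structure the genotyping procedure is designed to detect. The diversity
layer runs on the catalog:

```r
aln <- codon_alignment(setNames(res$catalog$haplotypes$sequence,
                                res$catalog$haplotypes$label))
diversity(aln)
#> diversity_stats: n=9 Nhap=9 S=93 Hd=1.000 pi=0.2180 pi_s=0.2443
#>   pi_n=0.2083 theta_w=0.1782 D=1.152
```

The package also bundles the published per-individual genotype table of the
Welsh *X. laevis* cohort (haplotype labels only, no sequences) for the
genotype-level layer:

```r
h <- heterozygosity(welsh_genotypes(), "all")
h$het_by_homozygote_rule
#> [1] 0.8888889   # 2 of 18 individuals carried a single haplotype
```

`run_pipeline(list(sim = cfg), "out/")` runs every stage and writes the
catalog FASTA, genotype/CNV/diversity TSVs, a newick genealogy and a JSON
manifest into `out/`.

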