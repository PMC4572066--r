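---
title: "Clone-based MHC class IIb genotyping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-based MHC class IIb genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneMHC)
```

## The problem

Multigene immune families such as the MHC class IIb region of *Xenopus
laevis* are hard to genotype: three paralogous loci (DAB, DBB, DCB) amplify
with one conserved exon-2 primer pair, copy number varies between
individuals (presence/absence variation), and PCR over a mixed template
produces artefactual mosaic sequences (chimeras).  The classic solution is
cloning: amplify, clone, sequence 14--21 clones per individual, and decide
which distinct clone sequences are real haplotypes.  `cloneMHC` implements
that decision procedure as a tested pipeline, together with the
population-genetic layer used to interpret the resulting genotypes, and a
synthetic cohort generator so every stage can be validated against known
truth at desk scale.

## Haplotype validation model

Clone sequences from one individual are collapsed by exact sequence
identity into variants with clone-support counts.  Two rules then decide
which variants are haplotypes:

* **Chimera exclusion.**  A variant is a putative PCR chimera when it can be
  reconstructed as a single-crossover mosaic `A[1..b] + B[b+1..L]` of two
  *better-supported* variants of the same individual (each parent with at
  least `min_parent_support = 2` clones).  Single template switching is the
  standard model for PCR recombination over a short (192 bp) amplicon;
  multiple-crossover chimeras are rare enough at this length to ignore, and
  the exact-match default (`max_mismatch = 0`) is appropriate for
  chromatogram-corrected clone sequences.  Variants are examined in order of
  increasing support, and a variant that has served as a parent is never
  itself flagged in the same pass.
* **Singleton validation.**  A variant supported by a single clone is
  accepted only if the identical sequence occurs in at least one other
  individual; variants with two or more clones are self-validating.

Chimera exclusion runs *before* singleton validation, and a sequence
flagged as chimeric in any individual is removed cohort-wide.  The order
matters: the same chimera can arise independently in two individuals that
share the parent haplotypes, and must not rescue itself through the
cross-individual rule.  The source study did not state which order it used
(nor how recombinants were identified); this ordering is the package's own
conservative choice.

Retained sequences are labelled with dense integers by descending total
clone support (ties broken lexicographically), so catalogs are bit-for-bit
reproducible and invariant to the order of individuals and clones.

## Locus assignment and copy-number calls

Haplotypes are assigned to loci by nearest reference ("type") sequence
under uncorrected p-distance, with a confidence margin: the distance gap
between the runner-up locus and the winning locus.  Assignments with margin
below `margin_threshold = 0.02` substitutions/site -- including exact ties
-- are reported `"unresolved"`.  This replaces clade-membership reading of
a genealogy: it is deterministic, testable, and matches how reference
("type") alleles are actually used to anchor locus identity.  With the
within/between-locus divergences typical of this system (about 0.03 vs 0.15
substitutions/site) assignment is unambiguous; the margin mechanism
*surfaces* genuinely ambiguous cases (as with the weakly differentiated
third locus) rather than resolving them.  A neighbor-joining genealogy with
column-bootstrap support is still produced for display, as a deliberate
substitution for maximum-likelihood tree inference: the tree is used only
for visual grouping, never for assignment.

Per-individual, per-locus copy classes follow the number of distinct
detected haplotypes: `absent` (0), `homozygous-like` (1), `heterozygous`
(2), `supernumerary` (3 or more).  "Homozygous-like" is deliberate: one
detected haplotype cannot distinguish true homozygosity from allelic
dropout, and reports carry that caveat.

## The statistics layer

All diversity statistics work on uncorrected p-distances by default
(Jukes-Cantor available behind a flag), matching the defaults of the
standard desktop tools in this field; at the divergences involved the
correction is negligible relative to reporting precision.

* **Synonymous/nonsynonymous counting** is Nei--Gojobori: per-codon site
  counts are the fraction of the nine single-base mutants that are
  synonymous (changes to stop codons count as nonsynonymous), and per-pair
  difference counts average over all orderings of single-step mutational
  pathways, excluding pathways through stop codons.  `pi_s` and `pi_n` are
  means over sequence pairs of pathway differences divided by the pair's
  mean site counts.
* **Watterson's theta** is `S / (a1 L)`; **Tajima's D** uses the 1989
  constants, with the mean pairwise difference *count* in the numerator.
  Both support frequency weights, because cohort-level tables are computed
  over per-individual sequence sets rather than unique haplotypes.  The
  dosage convention needed to reproduce the source study's
  frequency-weighted table is not stated there (its sequence counts per
  individual are not derivable from the genotype table), so those printed
  values are documented as out of reach; the estimators are instead
  validated against independently coded brute-force oracles at 1e-12.
* **Heterozygosity** at a multi-copy locus uses `1 -` (proportion of
  single-haplotype individuals); diploid-coded observed/expected
  heterozygosity and the exact Hardy--Weinberg test additionally exclude
  individuals carrying more than two haplotypes, which cannot be
  represented under diploid inheritance (the convention of the standard
  population-genetics software this mirrors).
* **The exact HWE test** is the conditional (Levene/Guo--Thompson) test:
  full enumeration of genotype tables for small problems (up to 3 alleles,
  or 4 alleles with 12 or fewer individuals), Monte-Carlo pairing of allele
  copies otherwise (default 1e5 draws, seeded; the `+1/(B+1)` correction
  keeps p in (0,1]).
* **McDonald--Kreitman** classifies each variable site as polymorphic or
  fixed in codon context; fixed differences in multiply-hit codons use
  pathway averaging, and fractional counts are rounded for the two-sided
  Fisher test.
* **HKA** fits per-locus `theta` and a common divergence time `T` by
  direct minimisation of the goodness-of-fit statistic
  (`optim`, Nelder-Mead then BFGS on log-parameters) rather than by solving
  the moment equations; on perfectly proportional data the minimum is 0,
  and on neutral two-locus simulations the rejection rate at
  `alpha = 0.05` stays within the binomial confidence interval of 0.05
  (500 replicates).
* **The per-codon selection scan** is a transparent counting analog of
  codon-model selection tests ("SLAC-like", and labelled so in reports,
  never claimed to reproduce likelihood-based classifications): per codon
  column, pathway-averaged synonymous/nonsynonymous differences over all
  sequence pairs, a binomial test of the nonsynonymous count against the
  column's mean synonymous site fraction, and classification at
  `alpha = 0.05` without multiple-testing correction by default (per-site
  results are conventionally reported uncorrected; Bonferroni/BH are a
  flag away).  Pairwise counts are not independent, so the scan is a
  screening tool, not a calibrated test.

In-frame stop codons abort codon-aware statistics with a frame diagnostic
rather than being silently skipped: a stop in this amplicon almost always
means the frame offset is wrong.  The 192-bp exon-2 fragment is treated as
starting in frame (`frame_offset = 0`) by default; the offset is
configurable because the primer system's frame is not documented.

## What the synthetic generator emulates

`scenario_presets()$welsh_like` encodes the shape of the motivating cohort:
18 individuals; three loci with presence probabilities 1.0/0.67/0.5 and
pool sizes 4/3/2; within-locus divergence 0.03 and between-locus divergence
0.15 substitutions/site over 64 codons; 14--21 readable non-recombinant
clones per individual; 3% chimeric clones; no base error.  Choices the
study's tables pin down only indirectly:

* The 14--21 range counts *readable, non-recombinant* clones, so chimeric
  clones are emitted on top of it rather than consuming it.
* Supernumerary (third-allele) genotypes occur only at DAB
  (probability 0.17, matching 3 of 18 individuals), because the other two
  loci were observed predominantly as homozygotes.
* Amplification bias is Dirichlet-multinomial with concentration 40 per
  template: mild enough that at 14--21 clones dropout of a true allele is
  rare -- consistent with the observed saturation behaviour, where
  haplotype count did not correlate with clone count and five haplotypes
  were recovered from 15 clones -- while lowering the concentration or the
  clone count makes dropout reproducible for studying that failure mode.

Under the recovery conditions used in the acceptance suite (chimera rate
0.05, no base error, seeds 1--20) the pipeline recovers 95% of
per-individual haplotype sets exactly; every failure is a true
zero-clone amplification dropout, never a false haplotype.

What the generator does **not** emulate: sequencing error correlated along
reads, chimeras with multiple crossovers, locus-specific primer bias,
allele frequency skew (alleles are drawn uniformly under Hardy--Weinberg
proportions), and linkage between loci.  Passing recovery tests therefore
demonstrates the correctness of the resolution logic under the stated
artefact model, not robustness to every real-world failure mode.

The neutral coalescent sampler is infinite-sites (exponential epoch
lengths, Poisson mutations mapped to unique sites), matching the
assumptions behind the Watterson/Tajima closed forms it calibrates:
over 500 replicates at `n = 18`, `theta L = 5`, `L = 500`, the mean
Watterson estimate is within 5% of truth and mean Tajima's D within 0.15
of zero.  Stop-codon avoidance in the allele-pool generator is a documented
departure from strictly neutral substitution, required to keep codon-aware
statistics total on simulated data.

## Problem sizes and determinism

All validation runs at desk scale: oracle-equivalence tests use random
alignments of at most 10 sequences by 200 sites; calibration uses 500
coalescent replicates; recovery uses 20 cohorts of 18 individuals.  Every
stochastic component takes an explicit integer seed, generator functions
derive fixed per-stage substreams from the config seed, and reruns of the
pipeline with the same config produce byte-identical data files.

## Known limitations

* Sequence-level checks against the deposited GenBank haplotypes
  (KP745469--77) require the user to supply that FASTA; it is not bundled.
  The source text also reports 69 variable nucleotide sites among nine
  haplotypes next to a table giving S = 64 across loci; the package
  computes one definition (sites with at least two non-degenerate states)
  and cannot arbitrate the discrepancy without the sequences.
* Frequency-weighted cohort statistics depend on a per-individual dosage
  convention (`weights`); the convention behind the study's printed values
  is unstated, so exact reproduction of that table is explicitly out of
  scope.
* The ordinary least-squares and one-way ANOVA birth-date trend tests are
  thin wrappers over `lm`/`aov` for pipeline completeness; results carry
  method labels so users can substitute dedicated statistics tools.
* No denoising or OTU-style clustering: exact sequence identity plus the
  two validation rules is the contract.  Data with appreciable per-base
  error need `max_mismatch > 0` and should expect weaker guarantees.
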