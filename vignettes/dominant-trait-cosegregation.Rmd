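---
title: "Mapping a dominant fungal trait by genotype-phenotype co-segregation"
author: "dikaryoMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a dominant fungal trait by genotype-phenotype co-segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dikaryoMap)
```

## The problem

Basidiomycete breeding programs work with two kinds of mycelium: haploid
**monokaryons** (one nuclear type, genetically haploid) and
**dikaryons** (two distinct haploid nuclei, genotypically equivalent to an
unphased diploid). A qualitative trait controlled by a single dominant
allele — here the formation of an abnormal, partial brown mycelial film
(phenotype `AB`) versus the normal brown film (`B`) — segregates 3:1 among
dikaryons obtained by selfing a heterozygous parent. Given whole-genome SNP
genotypes for a small discovery pedigree and a panel of unrelated cultivars,
the mapping question is: *which variants have genotype classes compatible
with every strain's phenotype under dominance?*

dikaryoMap implements that inference as a deterministic filter cascade, not
a statistical association scan. That matches the experimental design it
serves: with five sequenced strains whose pedigree relationships are known,
compatibility with dominance is a yes/no question per site, and the
follow-up cultivar panel plays the role of replication.

## The model

Let the dominant-associated allele at a site be `A` and the alternative `a`.
Genotype classes are:

| karyotype  | allele content | class | notation |
|------------|----------------|-------|----------|
| monokaryon | A              | DOM   | "A"      |
| monokaryon | a              | REC   | "a"      |
| dikaryon   | A/A            | DOM   | "A"      |
| dikaryon   | A/a            | HET   | "A+a"    |
| dikaryon   | a/a            | REC   | "a+a"    |

A phenotyped strain is *compatible* with a site iff
(`AB` and class ∈ {DOM, HET}) or (`B` and class = REC); a site
**co-segregates** iff every strain is compatible and no call is missing.
In the 5-strain discovery design (dominant founder `P1`, F1 dikaryon, two
recessive F2 spore monokaryons, and the dikaryon mated from those spores),
an unlinked biallelic site where the founders differ passes iff *both*
sampled spores happen to carry the recessive founder allele — probability
(1/2)^2 = 1/4. The causal site and everything locked in its linkage block
pass with probability 1. This 4:1 enrichment per independent locus, times
the depth of the pedigree constraint, is what collapses genome-wide variant
lists to a single locus.

### Dominant-allele orientation

The class of a call depends on which allele is "A". By default
(`orientation = "founder"`) it is the allele carried by the designated
dominant founder monokaryon at each site, which is well-defined because a
monokaryon cannot be heterozygous; sites where the founder's call is
missing are skipped with a logged reason. The fallback
(`orientation = "alt"`, used automatically if no founder is genotyped) takes
the VCF ALT allele as dominant — appropriate when the reference assembly is
a recessive-phenotype strain, as it is here. A corollary of founder
orientation worth knowing when reading output tables: at a site where the
founder carries the reference allele, REF *is* the dominant-associated
allele, so recessive strains sharing it are classed `A`/`A+a` and the site
(correctly) fails.

### Mendelian segregation test

Phenotype counts from a selfed cohort are tested against an expected ratio
with the uncorrected Pearson chi-square statistic,
$\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ with $E_i = N r_i / \sum r$, and an
upper-tail p-value on $k - 1$ degrees of freedom. No Yates continuity
correction is applied; the uncorrected statistic is the one that reproduces
the worked cohort example (80 AB : 28 B against 3:1 gives
$\chi^2 = 0.049$, $p = 0.824$) and the correction is known to be
conservative for goodness-of-fit use. For $N \ge 100$ the chi-square tail
agrees with the exact binomial null to well under 0.02 (the test suite
checks both against an enumeration oracle).

### Record-level filtering

Variant records are filtered before co-segregation with four criteria in a
fixed audit order: (i) biallelic SNP records only, (ii) per-call read depth
≥ `min_depth` (default 10), (iii) per-call genotype quality ≥ `min_gq`
(default 60), (iv) no missing calls. Thresholds are inclusive. Depth and
quality are enforced per call across *all* samples — a single failing call
rejects the site — because the completeness criterion (iv) already demands
a callable genotype in every strain, and a site-aggregate depth cannot
guarantee that. Each rejected site is annotated with the first criterion it
failed, so filter output is auditable by criterion. Thresholds that
reference a DP/GQ field absent from the VCF raise an error rather than
silently passing everything.

### Coding-effect classification

Candidate SNPs are classified against a strand-aware gene model (ordered
CDS intervals + coding-strand sequence). The affected codon is rebuilt with
the alternate base and translated with the standard genetic code:
synonymous (equal amino acids, including stop→stop at the terminator),
nonsense (new stop), stop-loss, start-loss (codon 1 no longer ATG), else
missense. Each SNP is classified independently against the reference CDS —
two SNPs sharing a codon are *not* combined into a haplotype codon, which
mirrors how adjacent variants are reported independently in practice and
keeps each VCF record's annotation self-contained. Labels follow the
`"612 C > A"` convention: 1-based CDS position, then reference and
alternate bases on the coding strand.

## The synthetic pedigree generator

Because the real sequencing data live in an external archive, the package
ships a seeded simulator that reproduces the *design* of the experiment so
the whole pipeline is testable offline. It generates:

1. a random reference genome (default 3 × 100 kb scaffolds) carrying one
   clean single-CDS gene (975 bp — a typical short fungal gene; start
   codon, no internal stop, terminal stop);
2. founder haplotypes: the recessive founder equals the reference (the
   reference assembly is a recessive-background strain); the dominant
   founder carries 5 missense + 3 synonymous causal SNPs inside the CDS
   (each placement verified through the package's own effect classifier
   against a translation oracle in the tests) plus background SNPs at
   Bernoulli(10⁻³) per base;
3. the pedigree: F1 dikaryon, two recessive F2 spores and their mated
   dikaryon (the discovery strains), a selfed F2 cohort (default 108, the
   size at which the 3:1 worked example was scored) and a cultivar panel
   (default 3 AB + 13 B dikaryons);
4. VCF 4.2 output with GT/DP/GQ, a TSV sample sheet, reference FASTA and
   gene GFF3.

Design choices that matter:

* **Recombination.** Marker loci segregate independently (free
  recombination) except for a single linkage block of ± 500 bp around the
  causal gene, which co-inherits as one unit. Real chromosomes have linkage
  everywhere; modelling it would only correlate neighbouring background
  sites without changing any per-site pass probability, while the
  independent-locus model makes the closed-form 1/4 background rate exact —
  which is what the calibration tests verify.
* **No mating-type compatibility.** Spore pairs are sampled independently;
  compatibility constrains which crosses *form*, not the segregation ratio
  of an unlinked autosomal locus.
* **Depth noise** is negative-binomial (mean 42 — a typical resequencing
  depth for this design — dispersion size 8) rather than Poisson, to allow
  the over-dispersion real libraries show. A depth of zero makes the call
  missing.
* **Genotype quality** is modelled as `GQ = min(99, 3 × depth)`:
  deterministic given depth, Phred-scaled, and crossing the GQ ≥ 60 filter
  threshold exactly where depth sinks below 20, so the filter path is
  exercised by realistic low-coverage calls.
* **Genotype errors** flip a call to a uniformly chosen *wrong* genotype
  class with probability 0.002 by default.
* **Background SNPs are excluded from the CDS interval** so the planted
  coding-SNP counts are exact; the flanking block may contain linked
  noncoding background SNPs, which — as in real data — show up as perfectly
  co-segregating passengers of the causal haplotype.
* **Seeding.** One master seed; every stage derives its own stream
  (Mersenne-Twister, fixed normal/sample kinds), so identical config + seed
  yields byte-identical FASTA/GFF3/VCF output.

What the simulator does **not** emulate: read-level errors (it starts at
genotypes, as the pipeline starts at VCF), indels and structural variants,
within-block recombination, mating-type loci, population structure in the
panel, and reference bias. Passing tests therefore demonstrate the
*inference logic* under the stated design, not robustness to artefacts that
live below the VCF.

## VCF genotype model

Standard VCF has no dikaryon ploidy, so the package adopts the convention
used in practice: monokaryons as haploid single-allele genotypes (`1`),
dikaryons as unphased diploid genotypes (`0/1`). Readers additionally
accept the all-diploid dialect some callers emit (`1/1` on a monokaryon
collapses to one allele; a *heterozygous* diploid call on a monokaryon is a
genotype-model violation and errors), treat `|` like `/` (phasing ignored,
allele order normalized), and map any token containing `.` to a missing
call. DP/GQ are recorded where present and never imputed. Multi-allelic
records are parsed intact and rejected by the filter, so the rejection log
accounts for them explicitly. Writing is deterministic (no timestamps) and
`readGenotypeVcf(writeGenotypeVcf(x))` is the identity, property-tested on
random tables.

## Worked run

```{r, eval = FALSE}
cfg <- pedigreeSimConfig(seed = 101, n_scaffolds = 2, scaffold_length = 40000,
                         gene_scaffold = 2, background_snp_rate = 1e-3,
                         genotype_error_rate = 0, mean_depth = 60,
                         depth_dispersion = 200)
report <- runPipeline(cfg, outdir = "run1")
report$counts
```

The report narrows the genome-wide site list to the causal locus: stage
counts are non-increasing along filter → co-segregation, the 8 planted
coding SNPs appear among candidates with the 5/3 missense/synonymous split,
and the cultivar panel flags the causal block as trait-associated. Note
that linked noncoding SNPs inside the block are flagged too — exactly the
behaviour expected of a co-segregation filter, which maps a *locus*, not a
nucleotide.

## Numerical and degenerate-input choices

* Inclusive thresholds everywhere (depth 10 and GQ 60 pass the defaults).
* Panel concordance excludes missing classes from score denominators (a
  cultivar without a callable genotype neither supports nor refutes a
  site); discovery co-segregation counts missing as failure, consistent
  with the completeness filter criterion.
* Panel ranking ties break by scaffold then position; candidate output is
  sorted by (scaffold, position).
* Causal-variant placement retries random CDS positions up to a bounded
  number of attempts and then raises a generation error (relevant only for
  tiny genes where, e.g., no synonymous site exists).
* The simulated gene is single-CDS by default, but `GeneModel` supports
  multi-interval CDS on either strand, and coordinate mapping is
  property-tested against an explicit interval walk (the common failure
  mode of hand-written annotation code).
* Problem sizes in the test suite (100-seed recall runs, 10⁴-dikaryon
  cohorts, 10³ random gene models and round-trip tables) were chosen so the
  binomial standard errors of the quantities under test are a few per mille
  — small enough that the 1/4 background rate and 3:1 ratio checks are
  sharp, while the whole suite stays comfortably runnable on a laptop.

## Limitations

* Dominance only: recessive or additive trait models are out of scope, as
  is any statistical significance machinery for concordance (with ≤ 20
  strains the filter is deterministic; a p-value would suggest precision
  the design does not have).
* The effect classifier handles SNPs only — no indels, splice sites, UTRs,
  or haplotype-aware codon reconstruction.
* The co-segregation filter is only as good as its phenotype labels; a
  single mislabelled strain removes the causal site. Running
  `selectCosegregating()` and inspecting near-perfect scores is the
  recommended diagnostic when zero sites pass.
* A co-segregation pass is a *compatibility* statement. Distinguishing the
  causal SNP among linked passengers requires the cultivar panel, and
  ultimately functional validation outside this package's scope.
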