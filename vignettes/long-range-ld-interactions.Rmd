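---
title: "Detecting long-range LD SNP pairs and LD-based gene interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-range LD SNP pairs and LD-based gene interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldgi)
```

## The model

Linkage disequilibrium is the non-random association of alleles at two
loci. On phased haplotypes it is measured directly from haplotype
frequencies: with $P_A$, $P_B$ the major-allele frequencies at the two
SNPs, $P_a = 1 - P_A$, $P_b = 1 - P_B$, and $P_{AB}$ the frequency of
haplotypes carrying both major alleles,

$$D = P_{AB} - P_A P_B, \qquad
  r^2 = \frac{D^2}{P_A P_a P_B P_b}, \qquad
  D' = \begin{cases}
    D/\min(P_A P_B, P_a P_b) & D < 0 \\
    D/\min(P_A P_b, P_a P_B) & D > 0.
  \end{cases}$$

`compute_ld()` implements exactly this, on haplotype rows (each diploid
individual contributes two), never on genotypes. Three numerical
decisions close gaps the formulas leave open:

* **Ties.** At an exact frequency of 0.5 the reference-coded allele is
  designated major. $r^2$ is invariant to the choice; only the sign of
  $D$ depends on it, and the rule makes that sign deterministic.
* **$D = 0$.** The two-branch $D'$ is undefined there; it is defined as
  0, the continuity limit, and $r^2$ is 0 regardless.
* **Missing data.** Haplotypes missing at either locus are dropped per
  pair (pairwise-complete deletion). Phasing software emits complete
  matrices, but the table dialect tolerates gaps; a configurable floor
  (default 40 haplotypes, i.e. 20 individuals, mirroring the
  population floor) skips pairs left with too little data. Frequencies
  use integer haplotype counts divided once, which makes $r^2$ exactly
  invariant under locus swap and allele relabeling rather than
  invariant only up to floating-point rounding.

## The long-range criterion

Strong LD between nearby SNPs is expected — they hitchhike on the same
haplotype block. The scan therefore only tests pairs whose correlation
physical linkage cannot comfortably explain:

* SNPs on **different chromosomes**, or
* SNPs on the same chromosome **separated by at least one
  recombination hotspot**.

Hotspot intervals are merged on load (overlapping *and* abutting
intervals, since crossing a recombination region is what matters, not
how the region was fragmented in the file). "Separated by" is read
conservatively as full containment: a merged interval $[s, e)$ counts
only when $p_1 < s$ and $e \le p_2$ for SNP positions $p_1 < p_2$ — a
hotspot overlapping a SNP does not cleanly separate the loci. Pairs on
the same chromosome with no contained hotspot are presumed same-block
and never reach the LD computation; this positional pre-filter also
keeps the scan complexity at (candidate pairs) rather than (all pairs).

Thresholds are restricted to $r^2 \ge 0.8$, $\ge 0.9$, or $= 1$ ("complete"
LD). The complete tier uses a tolerance of $10^{-9}$, since exact
floating-point equality is not meaningful. The threshold applies to
$r^2$ only; $D'$ is reported but never filtered on, matching the strong-LD
criterion as stated. Populations below 20 individuals are dropped
before scanning: haplotype-frequency estimates from fewer than 40
haplotypes make an $r^2 \ge 0.8$ call unreliable.

## Feature annotation

Gene context comes from GFF3 gene models plus the genome FASTA:

* **Promoter** — the 2 kb immediately upstream of the gene-level TSS
  (the 5'-most transcript start), strand-aware and half-open:
  $[\mathrm{tss} - 2000, \mathrm{tss})$ on the plus strand,
  $[\mathrm{tss} + 1, \mathrm{tss} + 2001)$ on the minus strand,
  clamped at chromosome bounds. Promoters are per gene, not per
  transcript, so a gene contributes one promoter placement however many
  transcripts it has.
* **CDS / UTR** — per transcript, CDS takes precedence; exonic
  positions outside the CDS are 5' or 3' UTR by strand-aware position.
  Both UTR sides collapse to a single "UTR" element in interaction
  categories.
* **Coding effect** — the SNP's CDS-relative offset is found by summing
  spliced CDS segments in strand order (alleles complemented on the
  minus strand), the containing codon is substituted ref to alt, and both
  codons are translated with the standard genetic code. Stop codons
  count as a distinct residue, so stop gain/loss is nonsynonymous — the
  binary scheme has no nonsense class. A ref allele that contradicts
  the genome FASTA is a hard error rather than a silent flip, because a
  silently flipped allele corrupts the coding-effect call.

All placements are reported: a SNP inside two overlapping genes, or in
the CDS of one transcript and the UTR of another, yields one record per
placement, and downstream tables carry the duplication through.

## Gene interactions

Each long-range strong-LD pair contributes the cross product of its two
SNPs' placements. Combinations linking two distinct genes become
interactions, categorized by the unordered feature pair (six
categories; canonical element order PROMOTER < CDS < UTR) with coding
subtypes NONSYN-NONSYN / NONSYN-SYN / SYN-SYN for CDS-CDS and
NONSYN-NA / SYN-NA where only one side is coding. Combinations where
both SNPs fall in the same gene are dropped with a counter — a gene
linked to itself is not an interaction — but remain visible in the
pair-level table. Aggregation is per (gene pair, category, subtype,
population); a cross-population union is a query, not a stored merge,
so population-specific interactions stay inspectable. External
evidence (PPI and co-expression gene-pair lists, SNP-trait lists) is
overlaid as flags computed from scratch on each call, making the
overlay idempotent; unflagged interactions are the potentially
uncharacterized ones.

## The simulator

`simulate_bundle()` writes a complete, seeded input bundle whose truth
is known in advance. Planting inverts the $r^2$ equation analytically:
given the target and the two allele frequencies, the positive-$D$ root
fixes $P_{AB}$, hence all four haplotype-class frequencies; rounding to
integer counts (largest remainder) bounds the achieved-versus-target
gap by $4/n$, and the manifest records the achieved value recomputed
from the realized counts. Infeasible targets (e.g. $r^2 = 1$ at
mismatched frequencies) raise an error stating the maximum attainable
value instead of drifting silently.

The default configuration is the study condition the tests exercise:
one population of 50 individuals (100 haplotypes) on two chromosomes;
25 cross-chromosome pairs with targets 0.9–1.0 at matched major-allele
frequencies 0.5–0.7, chosen so integer rounding keeps every achieved
$r^2 \ge 0.9$; 10 same-block decoy pairs at complete LD that the
positional filter must reject; 5 cross-hotspot decoy pairs at
$r^2 \approx 0.2$ that the threshold must reject; and 25 independent
background SNPs per chromosome (minor-allele frequencies 0.1–0.5). At
$n = 100$ haplotypes the probability that an independent background
pair reaches $\hat r^2 \ge 0.8$ is negligible (roughly a
$\chi^2_1$ tail beyond 80), so recovery should be exact: recall 1,
zero false positives.

Every planted cross-chromosome SNP is embedded in its own two-exon gene
(strands alternating) at a prescribed feature: promoter, 5' or 3' UTR,
or a CDS site engineered to be synonymous (third base of a four-fold
degenerate leucine codon, CTG to CTA) or nonsynonymous (middle base,
CAT to CGT, His to Arg). One SNP additionally falls in the 3' UTR of an
overlapping second gene so duplicate placements are always exercised.
The first eight feature pairings pin down all six categories and all
three CDS-CDS subtypes. Gene geometry is deterministic given the
configuration; only genome bases, background columns and haplotype row
order are random, and all randomness flows from the single seed, so
identical seeds give byte-identical files.

What the simulator does *not* emulate: coalescent realism. There is no
recombination-rate map, demography, or mutation model — background
columns are i.i.d. Bernoulli draws. Passing tests therefore demonstrate
that the machinery is correct under controlled LD structure, not that
any particular biological panel will yield interactions; with real
data, population structure and genotyping error can inflate long-range
LD in ways the null here does not represent.

## Problem sizes and runtime choices

The test suite and the acceptance script run entirely on simulated
bundles: the default 130-SNP, 100-haplotype panel for end-to-end and
recovery checks (10 seeds), 42-SNP panels for the brute-force scan
comparisons (10 seeds), 1,000 random column pairs for the LD oracle,
and the full 576-case genetic-code enumeration on both strands. These
sizes make every check exhaustive at the scale where exhaustiveness is
possible while a full run stays in the order of a minute.

## Known limitations

* Only biallelic SNVs are retained from VCF; multiallelic records are
  dropped, not split.
* Unphased data is out of scope — no EM or composite-LD estimation; the
  method is defined on phased haplotypes.
* Hotspots are modelled as BED intervals; sources that publish hotspot
  point estimates must be converted to intervals upstream.
* Monomorphic-in-population SNPs are skipped per pair rather than
  pre-filtered panel-wide.
* No statistical enrichment test is offered for overlaps with external
  networks; the overlay is descriptive flags only.
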