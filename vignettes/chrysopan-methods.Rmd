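---
title: "Methods: ploidy, composition and pan-genome analysis of chrysophyte assemblies"
author: "chrysopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy, composition and pan-genome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrysopan)
```

## The problem

Chrysophytes (golden algae) span the full range of protist nutrition:
phototrophs that photosynthesize, heterotrophs that prey on bacteria, and
mixotrophs that do both. Comparing their nuclear genomes raises a set of
recurring computational problems that this package packages as reusable,
tested building blocks:

* most strains cannot be cultured axenically — they are fed live bacteria —
  so assemblies are metagenomic mixtures and both contigs and reads must be
  decontaminated;
* the strains vary in ploidy (diploid to tetraploid), which must be
  estimated from read data because chromosome counts are unavailable;
* hypotheses about nutrient and carbon limitation are tested on composition
  statistics (GC content partitioned by genomic region, gene density) and on
  gene-content statistics (pan/core genomes of orthogroup tables), compared
  across trophic modes.

Every stage is backed by a synthetic-data generator with exact ground
truth, so the whole pipeline is testable without any sequencing data.

## Contig-bin decontamination

Taxonomic classifiers label assembled contigs `eukaryotic`, `prokaryotic`
or `unclassified`, and binning tools group contigs into bins. Because
reference databases hold vastly more bacteria than protists, unclassified
contigs in a bin are resolved in favour of the eukaryote by two rules with
inclusive boundaries (`resolve_unclassified()`): the bin's unclassified
contigs become eukaryotic if the number of eukaryotic contigs is at least
half the number of prokaryotic ones, or if the unclassified contigs
outnumber the prokaryotic ones at least two-fold. Otherwise they are
treated as prokaryotic and excluded — the conservative choice for
contaminated material. A bin with no prokaryotic contigs trivially
satisfies the first rule, which we accept as the rules' literal
consequence. The rules are evaluated per bin, not genome-wide.

Read decontamination is incremental (`incremental_read_rescue()`): reads
are first aligned to the bacterial contig set; of those hits, any read that
also aligns to the eukaryotic set is kept rather than randomly assigned,
and only bacteria-exclusive hits are discarded. The aligner is a pluggable
function; the built-in is an exact-seed hit test (31 bp seeds, both
strands), sufficient for synthetic end-to-end tests but not a replacement
for a production aligner. Contigs shorter than 500 bp are discarded;
the boundary contig of exactly 500 bp is kept ("shorter than" reads
naturally as a strict inequality on the discarded side).

## Ploidy from heterozygous k-mer pairs

A heterozygous single-nucleotide site in a genome of ploidy $q$ with
haploid depth $c$ produces pairs of k-mers at Hamming distance 1 whose
coverages split $(m c, (q-m) c)$ when the minor allele occupies $m$ copies.
In the plane of minor-coverage ratio $m/q$ versus total pair coverage
$q c$, heterozygous pairs concentrate in "smudges" — at $(1/2,\,2c)$ for a
diploid, $(1/3,\,3c)$ for a triploid, $(1/4,\,4c)$ and $(1/2,\,4c)$ for a
tetraploid, and so on.

The pipeline counts canonical k-mers ($k = 21$ by default; odd $k$ rules
out reverse-complement palindromes; retention bounds `ci = 1`,
`cs = 10000`), then finds all Hamming-1 pairs with a linear-time masking
scan: for each of the $k$ positions, k-mers (in both orientations) are
grouped by their sequence with that position blanked. K-mers with two or
more candidate partners are dropped outright instead of being paired
greedily; this keeps the pair set order-independent at the cost of a small
loss of signal. A per-pair coverage floor (`min_pair_cov = 4`) removes
sequencing-error k-mers.

K-mers are encoded as base-4 digits packed into doubles, which is exact up
to $k = 26$ (53-bit mantissa); this keeps canonicalization and the masking
scan locale-independent and fast without compiled code, and is why the
counting functions accept $k \le 25$ in practice rather than the
conventional 31.

### Scoring candidate ploidies

Candidate levels $q = 2..8$ are scored by the mean per-pair log-likelihood
of a generative smudge model: the pair total is $\mathrm{Poisson}(qc)$ and,
given the total, the minor count follows a folded binomial at allele
fraction $m/q$, mixed uniformly over $m = 1..\lfloor q/2 \rfloor$; the
haploid depth $c$ runs over a 30-point log grid between
$\tilde t/(2 q_{max})$ and $\tilde t$ (with $\tilde t$ the median pair
total). We chose a density, not a tolerance-band count, deliberately: at
realistic depths the minor ratio of a single pair is noisy (standard
deviation $\approx 0.07$ at a pair total of 50), and any rule that merely
asks "is the ratio within $\varepsilon$ of some $m/q$" lets large $q$ —
whose admissible ratios form a denser grid — absorb the noise tails and
outscore the true level even on clean diploid data. A mixture density has
no such loophole, because probability mass spent on smudges the data do not
populate is paid for where they do.

Scores are reported as relative support $\exp(\bar\ell_q - \bar\ell_{best})
\in (0, 1]$. Since every ploidy-$q$ explanation is nested in its multiples
(a diploid is also a tetraploid with only balanced sites), the smallest $q$
within `parsimony_margin = 0.05` of the best support is returned, and any
level within `ambiguity_margin = 0.05` of the winner is listed as a
near-tie — mirroring the "di- or tetraploid" style of call that real
strains sometimes require. A genuine tetraploid is only separable from a
diploid when both balanced (`AABB`) and unbalanced (`AAAB`) sites are
present; the generator's tetraploid default mixes them 0.5/0.5 for this
reason. The caller refuses to run on fewer than 50 pairs.

`modal_smudge_ratio()` reports the empirical face of the ratio law: each
pair is assigned to the nearest admissible $m/q$ and the most frequent
value is returned (1/2 for diploids, 1/3 for triploids).

## Composition metrics

`genome_stats()` collects N50, the assembly span over contigs passing the
500 bp filter, and GC content partitioned by region. Gene density is
$d = n / \sum \mathrm{bp}_{contigs \ge 500bp} \cdot 10^6$ genes per Mb; the
denominator uses the *kept* contig set, so a contig of exactly 500 bp
counts (the filter text and the formula's strict subscript disagree in the
source material conventions; we follow the filter).

Regions partition every contig base exactly once with precedence
coding > intron > intergenic: coding is the union of CDS intervals,
introns are the gaps between consecutive exons of a transcript, intergenic
is the complement of gene spans (plus any exonic non-CDS remainder, so the
three classes stay a partition). GC3 concatenates CDS segments in
transcript order (reverse-complementing minus-strand genes), trims leading
bases by the first segment's phase and any incomplete trailing codon, and
pools third positions over all transcripts. Non-ACGT symbols are excluded
from GC numerators and denominators, and a sequence with no ACGT bases
yields `NA`, never 0. GC is held at full precision internally and rounded
to one decimal for reporting.

## Pan/core orthogroup analysis

Orthogroup tables arrive in the OrthoFinder TSV dialect (header
`Orthogroup` + strain names, cells holding comma-separated gene ids). The
annotation of an orthogroup is the plurality KO id among its annotated
member genes, pooled across all strains — genes without a KO do not vote,
ties break to the lexicographically smallest KO id (a deterministic,
documented choice), and a group with no annotated gene stays unannotated.

For each of the seven combinations of the three trophic modes, the pan
genome is every orthogroup present in at least one member strain and the
core genome every orthogroup present in all of them; compositions count
orthogroups (not genes) per top-level KEGG category, with the hierarchy
supplied as a plain TSV so no live database access is needed. Presence is
boolean — gene counts are carried for reporting but do not affect the set
algebra. Pathway completeness compares genome-derived and
transcriptome-derived KO sets per strain against pathway definitions,
classifying each (pathway, KO, strain) cell as `genome`, `transcriptome`,
`both` or `absent`.

## Trophic-mode statistics

Group comparisons use classical one-way fixed-effects ANOVA; the posthoc
default is Tukey's HSD (a pairwise-t/Holm alternative is exposed), chosen
because it reproduces the published posthoc p-value on the bundled strain
table even though the original method is not stated. Region-GC comparisons
are *paired* t-tests — the regions belong to the same genomes — reported
raw, without multiple-testing correction, matching how such results are
conventionally quoted. Correlation screens return `NA` rather than failing
on constant input. All statistics are pure functions of their inputs.

The bundled strain metadata (16 chrysophyte strains: species, trophic
mode, assembly GC, BUSCO completeness, N50, reported ploidy) supports the
package's worked examples; the group means (phototroph 43.5%, mixotroph
43.4%), the ANOVA p-value of 0.0041 and the rounded mean BUSCO completeness
of 59% are recomputed by the test suite and the acceptance script, not
hard-coded anywhere in the package.

## The synthetic-data generator

`make_haplotypes()` draws an i.i.d. reference (`P(G)=P(C)=gc/2`), plants
`Poisson(length x het_rate)` single-nucleotide heterozygous sites with a
minimum spacing (default = k, so each site yields clean k-mer pairs; set
spacing 1 for deliberately dirty data), and assigns each site a genotype
pattern (`AB`, `AAB`, `AAAB`/`AABB`, ...) from a configurable mix.
Haplotype truth tables are sufficient for every downstream recovery test.
Defaults encode what we consider a realistic desk-scale experiment:
200 kb genomes, 1% heterozygosity and per-copy depth 25 — heterozygosity
rates for real chrysophyte strains are not published, so 0.5–1% is a
plausible-protist choice, not a measured one.

`plant_genes()` lays out alternating-strand genes with exon/intron/
intergenic structure from named length distributions (constant, uniform,
lognormal), drawing coding bases with separate GC targets for codon
positions 1–2 and 3, and records the realized GC of every region class
exactly — the recovery tests demand equality, not approximation.
`make_contaminated_assembly()` fragments a eukaryotic genome and mixes in
compositionally distinct bacterial contigs; `simulate_reads()` adds
uniform-start reads with per-base substitution errors; and
`simulate_kmer_coverage()` shortcuts sequencing by giving every canonical
k-mer a count drawn at `c x (copies containing it)` under Poisson or
negative-binomial noise — deliberately without error k-mers, which the
`min_pair_cov` filter would remove anyway.

`make_og_table()` composes an orthogroup table from three interpretable
classes — universally core, mode-shared, strain-private — whose pan/core
sizes for all seven mode combinations follow analytically; tests compare
both the analytic truth and a brute-force set scan against the package's
algebra.

What the generator does *not* emulate: indels (the ploidy method is
defined on substitution pairs only), repeat families, read-quality scores,
higher-order sequence composition and real taxon mimicry. Passing
recovery tests therefore demonstrates algorithmic correctness under the
stated model, not robustness to every artefact of real libraries —
repeat-dense genomes in particular will populate the smudge plane with
paralogous pairs that this generator never produces.

## Numerical and scale choices

Determinism: every generator takes an explicit seed and restores the RNG
state afterwards; fixed seed means byte-identical output. The test suite
and the acceptance script run the ploidy pipeline at 200 kb x 20 seeds per
ploidy level, the pair-detection equivalence on 100 random tables of up to
2000 k-mers, and the set-algebra checks on tables of a few hundred
orthogroups — sizes chosen so the full suite completes in minutes on one
CPU while keeping every estimate's sampling error far from its decision
threshold. Known limitations: the smudge scorer assumes Poisson-like
coverage (overdispersed real libraries widen the smudges; the
negative-binomial noise option exists to study exactly that), haploid
assemblies yield no pairs at all (the caller's domain starts at 2), and
contamination is only modelled compositionally, not phylogenetically.
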