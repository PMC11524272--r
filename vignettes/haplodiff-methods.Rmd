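---
title: "Methods: comparing the two haplotypes of a heterozygous diploid"
author: "haplodiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the two haplotypes of a heterozygous diploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodiff)
```

# The problem

Highly heterozygous outbreeding plants — poplar hybrids are the motivating
case — carry two substantially different haploid genomes in every cell.
When both haplotypes are assembled separately, the pair of assemblies
supports questions a collapsed ("monoploid") assembly cannot answer: how
many positions differ between the haplotypes, which genes exist on only
one haplotype, which allele of a gene pair is expressed more, and whether
runs of neighboring genes are biased toward the same haplotype.
`haplodiff` implements that comparison end to end, together with a
synthetic diploid generator that plants every kind of event the pipeline
is supposed to find, so that each stage is testable against known truth
without any external data.

# Stages and models

## Synthetic diploid with planted truth

`generate_haplotype_a()` draws random chromosome sequences at a target GC
content (default 0.335, typical for poplar) and places non-overlapping,
strand-balanced gene models: 1–5 exons, 5'/3' UTRs, and a CDS whose start
and stop codons are written into the sequence.  Gene geometry (exon
120–500 bp, intron 60–800 bp) is a free design choice at desk scale; it
is not calibrated to any particular genome's feature-length tables, and
conclusions about real feature-length distributions should not be drawn
from it.  `mutate_to_haplotype_b()` derives the second haplotype by
planting:

* SNPs at a per-base rate (default 2%, the order observed in highly
  heterozygous poplar genomes),
* small indels (< 50 bp) at a lower rate,
* the five structural-variant classes — deletion, insertion, duplication
  (a tandem copy gained by B), contraction (a tandem copy lost by B,
  which requires a tandem pair pre-planted in A), and translocation (an
  intergenic segment moved to another chromosome),
* whole-gene deletions for a configurable fraction of genes, which become
  the haplotype-specific truth.

SV events are placed in intergenic space with a 1 kb guard zone and never
overlap (bounded retries, then an explicit error), so the truth record is
unambiguous.  The B annotation is the A annotation lifted through the
event offset map; genes overlapped by an SV deletion are dropped rather
than truncated.  All coordinates are 1-based inclusive (GFF3 convention);
BED-style exports are 0-based half-open.

The expression simulator assigns every allele pair a log-normal baseline
mean and draws negative-binomial counts per allele copy and replicate
(default dispersion 0.1, mean 200, 3 replicates, 4 experiments), with a
per-replicate library-size factor drawn log-normally (sd 0.1) so that
library-size normalization is genuinely exercised.  ASE pairs split the
baseline by the planted log2 fold change (default 2, i.e. a 4-fold
allelic ratio).  Planted ASE blocks are runs of consecutive pairs sharing
a direction; two generator details keep the planted blocks recoverable by
construction rather than by luck: the pairs immediately flanking a block
are kept non-ASE (otherwise random extra ASE pairs would extend the run
and change the block's extent), and block members get at least the
typical expression mean (otherwise a single weakly expressed member would
censor the whole block).  The same planted ASE set is active in every
experiment — allelic bias is modelled as a property of the locus, which
matches the empirical observation that most ASE calls are shared across
conditions.  Even with these guards, replicate count noise at dispersion
0.1 occasionally drags one block member's realized fold change below the
significance rule in one experiment, so exact recovery of every planted
block in every experiment sits around 75–100% across seeds rather than
at a guaranteed 100%; the strict run rule is kept regardless.

What the generator does **not** emulate: read-level sequencing (counts
are drawn directly, not mapped), repeat landscapes and transposons,
sequencing-error models beyond uniform substitution, and isoform
complexity (one transcript per gene).  Passing the recovery tests
therefore demonstrates correctness of the algorithms on clean planted
signal, not performance on repeat-rich real assemblies.

## k-mer spectrum: genome size and heterozygosity

`simulate_kmer_histogram()` produces the histogram a k-mer counter would
see at uniform coverage: every distinct canonical k-mer of the diploid
with genomic multiplicity $m$ receives a $\mathrm{Poisson}(m \cdot c
\cdot (1-e)^k)$ read count, where $c$ is per-haplotype coverage and $e$
the substitution error rate; the k-mer copies lost to errors reappear as
novel singletons.  This reproduces the observable histogram of a read
simulation at a fraction of the cost (read-level simulation is out of
scope by design).

`fit_spectrum()` models the non-error spectrum as a two-component Poisson
mixture with means $(\lambda, 2\lambda)$: heterozygous k-mers occur on
one haplotype (depth $\lambda$), homozygous k-mers on both (depth
$2\lambda$).  The error cutoff is the first local minimum of the
histogram.  With $D_{het}$, $D_{hom}$ the distinct k-mers assigned to the
components by posterior weight,

$$G = D_{hom} + D_{het}/2, \qquad a = \frac{D_{het}/2}{G}, \qquad
\text{het rate} = 1 - (1-a)^{1/k},$$

the last formula accounting for the fact that one isolated SNP covers $k$
k-mer windows; monoploid genome size is total above-cutoff k-mer mass
divided by $2\lambda$.  Numerical choices: EM on binned multiplicities,
200 iterations maximum, log-likelihood tolerance $10^{-8}$.  Because the
dominant peak of a highly heterozygous spectrum may be either the
heterozygous or the homozygous one, EM is started from both readings of
the main smoothed peak ($\lambda_0 = \text{mode}$ and $\text{mode}/2$)
and the higher-likelihood fit kept; a one-peak initialization alone can
converge to a locally optimal but wrong depth.  A fit in which either
mixture weight collapses below 2% is flagged unimodal: the peak is read
as homozygous and the heterozygosity reported as 0.

Recovery on 10 Mb synthetic diploids at 50-fold coverage over SNP rates
0.5–3% is within a fraction of a percent for both heterozygosity and
genome size (see `scripts/acceptance.R`), comfortably inside the ±20% /
±5% bands the package's tests assert.

## Collinearity blocks

Anchors are maximal exact matches seeded by k-mers (default seed 21)
occurring at most 10 times in each sequence and exactly once in at least
one; seeds on a shared diagonal are merged and extended to maximality on
both strands.  Chaining is a weighted collinear dynamic program on
A-order with per-strand B-order consistency, maximizing anchored length
minus a gap penalty of $0.05\,|g_A - g_B| + 0.01\,\min(g_A, g_B)$; chains
break at gaps above 100 kb on either axis.  The DP examines a bounded
window of predecessors (default 64) for near-linear behaviour on dense
anchor sets; the window is exact whenever it is at least the number of
anchors, which the oracle-equivalence tests rely on.  Maximally extended
anchors can overlap around an indel in repetitive context; the
inter-anchor gap accessor resolves this by trimming whichever flanking
anchor can absorb the overlap, so gap sides are never negative.

Blocks are chains with identity computed from the anchors plus
base-level alignment of the inter-anchor gaps (affine-gap global
alignment: match +1, mismatch −2, open −4, extend −1; equal-length gaps
up to 200 bp are compared column-wise directly).  Filtering mirrors the
classic whole-genome-aligner convention "minimum length 15 kb, minimum
identity 80%, maximum mutual overlap 80%": blocks under 15 kb span or
80% identity are removed, and among blocks overlapping more than 80% on
either axis only the best (aligned length × identity) is kept, giving a
one-to-one block set.

## Variants and structural variants

Small variants are read directly off the aligned inter-anchor gaps of
each block: mismatch columns become SNPs, gap runs shorter than 50 bases
become insertions/deletions with haplotype A as the reference, and indels
are left-aligned against A for reproducible coordinates.  No variant is
ever emitted outside a collinearity block.  The 50 bp boundary is
exclusive below: events of 50 bp and larger belong to the SV caller.

SV classification works on inter-anchor gaps whose side lengths differ by
at least 50 bases.  When both gap sides are non-empty the gap is
re-aligned at base level and the longest indel run taken as the event, so
nearby SNPs merged into the same gap do not smear the breakpoints.  An
event whose extra sequence matches the immediately flanking A sequence
(90% identity, alignment-based, so planted small variants inside the copy
do not defeat the comparison) is reclassified as a copy-number event:
gained flank copy = duplication, lost flank copy = contraction.
Translocations are detected at block level: a block whose partner
chromosome differs from the dominant partner of its A chromosome, or
whose B position deviates from the median offset of its five nearest
same-partner neighbors by more than max(100 kb, 10 spans).  Translocation
calls are deliberately conservative and excluded from gene-overlap
statistics, since order-breaking blocks in real assemblies are often
scaffolding artifacts; only insertion and deletion SVs enter the promoter
association test for the same reason.

Heterozygosity is reported as `100 * variants / genome size`, rounded
half away from zero to two decimals — the printed-report convention that
reproduces figures such as 2.76% (10,406,261 variants over a 377,691,676
bp haplotype).

## Variant annotation

Each variant receives exactly one of 12 location groups by fixed
precedence: splice-site acceptor/donor (the 2 intronic bases at each
junction, strand-aware) > splice-site region (exonic 1–3 bp or intronic
3–8 bp from a junction) > 5'/3' UTR > coding exon > intron > transcript
(inside the mRNA but no finer category; distinguishing "transcript" from
"gene" is a documented choice, since annotations in which the gene span
exceeds the mRNA span populate "gene") > upstream/downstream (strand-aware
5 kb windows, the snpEff default, configurable) > intergenic.  Effects
follow the genetic code: frameshift, stop gained/lost, start lost and
splice donor/acceptor variants are HIGH impact; missense and in-frame
indels MODERATE; synonymous LOW; everything non-coding MODIFIER.  For
multi-transcript inputs the most severe effect per gene is reported.

## Allele pairs and haplotype-specific genes

Two genes are alleles when each is the other's top similarity and at
least 90% of both gene bodies lies inside the same one-to-one
collinearity block (the fraction is configurable; the field convention
the rule descends from states no number).  When a gene qualifies in
several blocks the largest block wins.  Remaining genes pair by
reciprocal best hit alone when at least one lies on an unplaced scaffold.
Everything still unpaired is haplotype-specific.

Similarity is a global protein alignment (BLOSUM62, gap open 10, extend
0.5) normalized by the self-score of the longer protein.  A single
early frameshift can drive that score to zero for a true allele, so each
candidate is scored as the maximum of the protein similarity and 0.85 ×
CDS nucleotide identity: one consistent scale on which intact protein
evidence always outranks nucleotide-only evidence, while
frameshift-damaged alleles remain pairable — the behaviour a reciprocal
local-alignment search (BLAST) exhibits naturally.  Candidates are
pruned to those whose position inside the block projects within 20 kb of
each other, which is what collinearity means operationally.  Ties break
deterministically (higher coverage, then lexicographically smaller id
pair).

Feature statistics compare haplotype-specific, allelic and all genes:
means ± SD of gene/CDS/exon/intron length, mean RPKM, and the RPKM
coefficient of variation computed as `100 * sd/mean` over the pooled
per-gene × per-sample RPKM values of the class (the pooling is a
documented choice; the convention is not fixed by the reports this
mirrors).  Multiple comparisons use Tukey's HSD at α = 0.05 with a
compact letter display.

## Allele-specific expression

For each pair and experiment the test statistic is allele A's summed
count conditioned on the pair total.  Under the null the conditional
distribution is beta-binomial with mean equal to A's share of the library
sizes and an overdispersion ρ estimated by method of moments across
pairs, using

$$E[(\hat p - p_0)^2] = p_0 q_0\left(\rho\,(1 - 1/n) + 1/n\right).$$

Pairs whose allelic fold change already exceeds the decision boundary
(|log2 fold| > 1) are excluded from the moment pool — otherwise genuinely
imbalanced pairs inflate the very null dispersion they are tested
against, which in simulation costs essentially all power at realistic ASE
fractions.  When ρ ≤ 0 the test falls back to the plain binomial.  The
two-sided p-value sums all outcomes no more probable than the observed
one.  Fold changes are library-size normalized with pseudocount 0.5.  The
decision rule is exactly the published criterion: |log2FC| > 1 and
Benjamini–Hochberg FDR < 0.01.  Calibration on 10,000 null pairs
(negative-binomial dispersion 0.1, 3 replicates) gives an empirical
type-I error far below the 1% criterion, and power above 90% at a planted
log2FC of 2 and mean 200.

An ASE block is a maximal run of at least four consecutive allele pairs
("more than three genes"), all significant in the same direction; a
non-ASE or opposite pair breaks the run, and non-allelic genes between
pairs are ignored because ordering is over pairs.  Whether interior
non-ASE pairs may be tolerated is unspecified in the convention this
implements; the strict rule is the default and both the threshold and
strictness are exposed as arguments.  A block shared across experiments
is a set of same-direction blocks, one per experiment, every two of which
share at least three member pairs — the sharing rule is this package's
own definition (none is fixed by the reports it mirrors) and is
configurable.

The promoter association test asks whether pairs harboring an
insertion/deletion SV in the 2 kb upstream of either allele's translation
start ("start codon" anchor, strand-aware) are enriched among ASE pairs,
by a two-sided Fisher exact test on the 2×2 of {ASE, non-ASE} × {SV, no
SV}.  Promoter motif scanning accepts any IUPAC motif table, counts
occurrences on both strands with overlaps allowed, and ranks motifs by
total occurrences and by promoters hit, so that rank lists of different
gene classes can be compared by Spearman correlation.  No motif database
is redistributed.

## Report utilities

Assembly statistics use the standard N50 (smallest member of the minimal
set of longest sequences covering half the assembly) and GC over
unambiguous bases.  BUSCO-style percentages are `100 * count / total`
rounded half away from zero to one decimal with complete = single +
duplicated before division; heterozygosity and fraction reports use two
decimals.  These rounding conventions reproduce printed report figures
exactly (97.3%, 2.76%, 69.67%, …).  `report()` re-aggregates everything
from the stage files on disk and re-runs the internal conservation checks
(per-type variant counts sum to the total; 2 × pairs + specific = total
genes), so a stale cached summary can never drift from the data.

# Problem sizes used by the tests

The test-suite fixtures are two-chromosome 300 kb diploids with 30 genes
per chromosome (all SV classes, 1% SNPs), a 200 kb isolated-SNP diploid,
and 10 Mb single-chromosome diploids for the k-mer recovery grid; ASE
calibration uses 10,000 pairs × 3 replicates × 3 seeds.  These sizes were
chosen as the smallest at which every stage's behaviour is
distinguishable from noise.

# Known limitations

* The anchor finder assumes unique 21-mers exist at useful density; in
  repeat-saturated regions of real genomes it would fragment, and no
  repeat-aware rescue is attempted.
* The Poisson mixture for the k-mer spectrum matches uniform simulated
  coverage; real libraries are overdispersed and a negative-binomial
  extension would be needed (flagged, not implemented).
* The SV caller reports the five classes above only; inversions are out
  of scope.
* Gene-level statistics treat one transcript per gene; isoform-aware
  comparisons are not supported.
* The ASE test consumes counts that are assumed to be
  haplotype-uniquely assigned (zero-mismatch mapping upstream); mapping
  bias correction is out of scope.
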