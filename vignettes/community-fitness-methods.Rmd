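---
title: "Methods: RB-TnSeq community fitness estimation in barseqfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RB-TnSeq community fitness estimation in barseqfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqfit)
```

# Overview

`barseqfit` analyzes pooled-fitness experiments in which a randomly
barcoded transposon (RB-TnSeq) library of a focal bacterium is grown under
several community conditions and barcode abundances are sequenced at
inoculation (T0) and at harvest (day 3). This vignette documents the model,
the numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions taken where several reasonable options
existed.

# The fitness model

## Strain fitness

For a barcode $s$ with $n_{0}$ reads among $N_{0}$ total in the T0 sample
and $n_{3}$ reads among $N_{3}$ total in a day-3 sample, the raw strain
fitness is the log2 change in *relative* abundance

$$f_s = \log_2\!\frac{(n_{3} + \tfrac12)/N_{3}}{(n_{0} + \tfrac12)/N_{0}}.$$

Two choices are folded in here. Relative abundance (dividing by the sample
totals) makes fitness invariant to sequencing depth, which differs between
samples for purely technical reasons. The pseudocount of $\tfrac12$ keeps
fitness finite when a strain drops to zero reads; it biases extreme values
toward zero by design — a strain falling from 10 reads to 0 scores
$\log_2(0.5/10.5) \approx -4.39$, not $-\infty$. Any global bias the
pseudocount introduces is shared by all strains and removed later by mode
normalization.

## Gene fitness

A gene's raw fitness is the weighted mean of its retained strains,

$$f_g = \frac{\sum_s w_s f_s}{\sum_s w_s}, \qquad
  w_s = \frac{2}{\frac{1}{1 + n_{0,s}} + \frac{1}{1 + n_{3,s}}},$$

the harmonic combination of the two count-limited precision terms: the
sampling variance of a log count-ratio scales like $1/n_0 + 1/n_3$, so
well-sequenced strains carry more weight. Only strains inserted in the
central 10%–90% of a gene contribute; terminal insertions often leave gene
function intact and would dilute the signal (the boundaries are inclusive,
declared explicitly so the behavior at exactly 0.1 and 0.9 is testable).

## Two-stage normalization

Raw gene fitness carries a chromosomal trend: in growing cells, genes near
the replication origin are present in more copies than genes near the
terminus, inflating their apparent abundance. The first normalization
subtracts a **running median over a centered window of 251 genes** ordered
by chromosomal midpoint, with circular wrap-around (bacterial chromosomes
are circular). The median, unlike a mean, is not dragged by the sparse
genes with genuine large effects. When the genome has fewer genes than the
window, the window is truncated to the largest odd number available. The
251-gene default follows common practice in transposon-fitness pipelines
of smoothing over a scale much larger than operons but smaller than a
replichore; it is exposed as the `window` argument, and analyses of small
gene sets should scale it down with the gene count (the package's tests use
windows of 51–75 genes for 40–500-gene toys).

Second, **mode normalization**: assuming most insertions are neutral, the
mode of the gene-fitness distribution is the neutral point and is
subtracted. The mode is estimated as the center of the maximal-count
histogram bin with bin width 0.05 (bins centered on multiples of the
width, so a distribution modal at 0 shifts by at most half a bin), computed
over the central 95% of values so distribution tails cannot capture the
maximum. Ties between equally full bins break toward the center closest to
0 (then deterministically toward the more negative center). The 0.05 bin
width resolves shifts well below the smallest effect sizes of interest
(|f| ≥ ~0.5) while keeping enough points per bin at a few hundred genes.

This two-stage scheme makes the final fitness translation-invariant: adding
a constant to all raw values is absorbed by the mode subtraction (up to bin
resolution), which is why the pseudocount and relative-abundance choices
above are safe.

## Moderated t-score and effect calling

Each gene–replicate gets a moderated t-score

$$t = \frac{f_g^{\text{final}}}{\sqrt{\max\!\big(V_{\text{strain}},\,
V_{\text{floor}}\big)}}, \qquad
V_{\text{strain}} = \frac{\sum_s w_s (f_s - f_g)^2 / \sum_s w_s}
 {(\sum_s w_s)^2 / \sum_s w_s^2},$$

the weighted between-strain variance divided by the effective strain
number, floored by the count-limited term

$$V_{\text{floor}} = \frac{1}{(\ln 2)^2}\left(\frac{1}{1 + N_{0,g}} +
\frac{1}{1 + N_{3,g}}\right)$$

with $N_{\cdot,g}$ the gene's total reads per timepoint. The floor is the
variance a log2 ratio of Poisson counts cannot beat; it stops single-strain
genes and genes whose strains agree by chance from reaching arbitrarily
large t. This moderation is what makes $|t|$ comparable across genes with
very different strain support.

Fitness and t are averaged arithmetically across the biological replicates
of each condition — deliberately a mean of per-replicate t-scores, not a
pooled recomputation, so one aberrant replicate cannot silently dominate. A
gene has a *strong effect* when $|\bar t| \ge 3$ (boundary inclusive);
strong-positive additionally requires $\bar f > 0$. Genes that fail the
count filters in some replicates are averaged over the replicates where
they are defined, with the count reported.

# Count filters

Three rules precede fitness estimation, each logged in an audit:

* barcodes absent from the characterized insertion pool are dropped
  (they are PCR/sequencing artifacts or contamination, but they are counted
  and reported, never silently discarded);
* barcodes with fewer than 3 reads in the **raw** T0 sample are dropped
  (strict less-than: a count of exactly 3 is retained) — their log-ratios
  are dominated by shot noise; raw rather than normalized T0 counts are
  used, as the filter models absolute evidence of presence;
* genes whose retained central barcodes sum to fewer than 30 T0 reads are
  excluded (strict less-than). The read-sum is taken in the T0 sample,
  the common denominator of every condition, so a gene is either analyzed
  in all conditions or none.

Filtering is idempotent and order-independent, and the audit counts sum to
the number of rows removed — properties the test suite checks directly.

# Insertion-pool construction

Junction reads are laid out as `barcode | junction tag | genomic flank`,
with the 19-bp Tn5 mosaic end as the tag. Flanks are placed in the genome
by exact lookup of their first 20 bases against a k-mer index of both
strands; reads whose flank is absent or occurs at more than one site are
discarded with tallied reasons, alongside reads lacking the tag, the
barcode, or a full-length flank. Exact unique matching (rather than a
mismatch-tolerant aligner) is a deliberate choice: the contract that
matters downstream is *unique placement or discard*, and at the scale of a
single bacterial genome, 20-mers are essentially unique. Real data with
sequencing errors in the flank loses a fraction of reads, not placement
accuracy.

A barcode is retained at its modal (position, strand) when that location
holds at least 75% of its reads with at least 2 supporting reads; anything
else is ambiguous or chimeric (a PCR artifact joining one barcode to two
loci) and is dropped. The thresholds are conservative and, importantly,
exactly testable: the retained set equals brute-force application of the
rule, and an exact 50/50 tie always fails.

Coordinates are 0-based internally (junction coordinate = first flank
base); GFF3 I/O converts to and from 1-based inclusive. The relative
position of an insertion within a gene is measured along the coding strand:
offset/length for forward genes, (length − offset)/length for reverse
genes.

# Growth statistics

Titers are `count / (dilution × plated volume)` per ml; technical
replicates are averaged within each biological replicate *before* any
cross-replicate statistic, so pseudo-replication cannot tighten confidence.
Plates outside the countable range [30, 300] are QC-flagged but never
dropped (no such exclusion is part of the protocol being modeled). Tukey's
multiple comparisons run on biological-replicate means via the studentized
range (Tukey–Kramer for unequal sizes); the implementation is checked
against R's `TukeyHSD` to 10⁻⁶ on a textbook three-group dataset.
Efficiency of plaquing is the pfu ratio on mutant versus wild-type lawns
(0 = complete resistance); MOI is pfu/cfu at inoculation. QQ normality is
reported as a correlation diagnostic at plotting positions $(i - 0.5)/n$,
mirroring graphical usage, not a formal test.

The MOI helper makes one point of friction visible rather than resolving
it: a nominal MOI of 0.001 is commonly quoted for community experiments of
this design, yet typical printed inoculum sizes (4.18 × 10³ pfus against
2.4 × 10⁵ cfus) imply MOI ≈ 0.017. The package computes MOI from whatever
inocula it is given and leaves the scenario MOI as a free parameter.

# The synthetic community generator

`simulate_community()` generates the full experiment at a configurable
scale. Defaults define the desk-scale study conditions:

| parameter | default | rationale |
|---|---|---|
| genome length | 200 kb | large enough for unique 20-mers and a stable running median, small enough for fast tests |
| genes | 150, 85% coding | typical bacterial coding density |
| insertions | 10,000 | ~45 central strains/gene, matching the strain support of dense real libraries |
| barcodes | 20 bp, unique | standard BarSeq barcode length |
| conditions | alone, phage, fungi, phage+fungi | 2×2 community design |
| replicates × depth | 3 × 5 × 10⁵ reads | ~50 T0 reads/strain, comfortably above the count filters |
| planted effects | antagonistic +2 (phage) / −1.5 (fungi-only); phage-benefit +2; fungus-cost −1.5; deleterious −2; 84% neutral | signs follow the trade-off structure under study; magnitudes chosen so strong effects are unambiguous at default depth while remaining in the range seen in pooled-fitness studies |

Selection is the generative inverse of the estimator: day-3 abundance is
proportional to $a_0 \cdot 2^{f}$ with lognormal inoculum abundances
$a_0$ (sdlog 0.5, a mild inequality typical of transposon pools), and
sequencing is multinomial at fixed depth. The full study scale (Mb genome,
thousands of genes, 1.6 × 10⁵ insertions) is reachable through the same
configuration object.

What the generator deliberately does **not** emulate — and hence what
passing tests do not demonstrate about real data:

* **Insertion-site bias.** Tn5 is modeled as uniform; real libraries have
  hot and cold spots, which affect which genes are representable but not
  the estimator's arithmetic.
* **Strain-level heterogeneity within a gene.** All strains of a gene share
  its fitness; real polar effects, domain-specific truncations and
  second-site mutations create within-gene dispersion that the
  between-strain variance term absorbs statistically but the generator
  never produces.
* **PCR amplification noise and duplicates.** Counting noise is purely
  multinomial; real BarSeq overdispersion would widen null t-scores.
* **Phage/fungus population dynamics.** Planted fitness is a per-condition
  constant; there is no epidemiological feedback, no resistant-mutant
  sweep over time.
* **The copy-number trend itself.** The generator plants no positional
  trend by default; positional normalization is validated against
  constructed trends (sawtooth + spikes) in the tests instead.

Chimeric barcodes and junction-free junk reads *are* generated (at
configurable rates) because the mapping stage's discard rules need negative
cases.

# Determinism and numerical edge cases

Every generator takes a single integer seed and derives fixed offsets for
its stages; identical configuration and seed give byte-identical FASTA,
GFF3, FASTQ and TSV outputs. Degenerate inputs are handled explicitly:
empty read sets warn and return empty observations; a constant fitness
vector normalizes to exact zeros; a constant sample makes the QQ
correlation undefined (reported as `NA`, not an error); all-identical
Tukey groups give p = 1; a titer of zero at every dilution is reported as
0 with a lower-bound flag; infeasible gene packing and extinct libraries
are rejected with configuration errors.

Problem sizes in the test suite are chosen for depth of coverage per
second: oracle comparisons run on vectors up to length 1000, pool-rule
enumeration on 20-barcode sets, end-to-end recovery on the default
10,000-insertion community across ten seeds, and mapping round-trips on the
full default library once.

# Known limitations

* Gene-level analysis ignores operon structure; a polar insertion
  attributes downstream effects to the inserted gene.
* Essentiality is not called: genes absent from T0 (never cleared the
  30-read rule) simply drop out, and their absence is only visible in the
  audit.
* The pleiotropy classifier requires an explicit condition-composition
  declaration (`has_phage`, `has_fungi`); genes with opposite-sign strong
  calls that do not match the phage/fungi trade-off pattern fall into the
  residual class rather than being labeled antagonistic.
* Multi-contig assemblies are not supported; coordinates are per a single
  circular chromosome.
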