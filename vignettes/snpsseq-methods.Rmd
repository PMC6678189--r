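---
title: "Methods: allele-specific protein-DNA binding from SNP oligo sequencing"
author: "snpsseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific protein-DNA binding from SNP oligo sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsseq)
```

## The assay and the statistic

SNPs-seq screens many candidate regulatory SNPs at once for allele-dependent
protein binding. For every biallelic SNP a pair of 21-bp double-stranded
oligos is synthesized — identical except for the central base, which carries
either the reference or the variant allele. The pooled duplexes are
incubated with nuclear extract, the protein-bound fraction is recovered and
sequenced, and differential retention of the two alleles of a pair measures
how strongly the variant changes protein binding at that site. An aliquot of
the pool sequenced without selection (the *input*) provides the baseline
allele balance of the library.

For each SNP the package computes the **biased allelic binding (BAB)
score**, a log2 ratio of ratios:

$$\mathrm{BAB} \;=\; \log_2\!\left[
  \frac{\;\mathrm{RC}^{test}_{var}/\mathrm{RC}^{test}_{ref}\;}
       {\;\mathrm{RC}^{input}_{var}/\mathrm{RC}^{input}_{ref}\;}\right]$$

where RC are template read counts. Normalising the test-sample allele ratio
by the input ratio cancels both library-size differences and any synthesis
imbalance between the two oligos of a pair: multiplying all counts of one
sample by a constant leaves BAB unchanged, and swapping the allele labels in
both samples negates it exactly. BAB is therefore interpretable directly as
the log2 fold difference in binding affinity between the variant and
reference alleles.

A SNP is called significant when $|\mathrm{BAB}| \ge 0.58$, i.e. at least a
1.5-fold allelic difference ($\log_2 1.5 = 0.585$, conventionally printed as
0.58 and applied inclusively). With two treatment conditions (androgen, DHT,
versus vehicle, ETH) each SNP falls into one of four overlap classes:
`shared`, `dht_only`, `eth_only`, `nonsignificant`.

### Zero counts and replicates

The formula is undefined when any of the four counts is zero, and the assay
occasionally produces zeros for strongly disfavoured alleles. The scorer
adds a symmetric pseudocount (default 0.5) to all four counts. A symmetric
pseudocount is the only choice that preserves the allele-swap antisymmetry
above; it biases extreme scores slightly toward zero, vanishing as counts
grow. Setting `pseudocount = 0` restores the raw formula and makes zero
counts an error.

Technical replicates are combined by **pooling counts** within a condition
before the ratio is formed (default), which weights each replicate by its
depth and is the maximum-likelihood treatment under multinomial sampling.
The alternative `mean_bab` policy scores replicate pairs separately and
averages; it is offered because per-replicate scores are sometimes wanted
for QC, but it is noisier at low counts.

## Candidate selection

`select_candidates()` implements the two-stage eQTL/LD funnel: a *region*
enters the screen when its best eQTL p-value beats `region_p_threshold`
(default 1.97e-7); within live regions a SNP is retained when its LD with
the region's lead risk SNP exceeds r² = 0.5 **strictly** and its own eQTL
p-value is **strictly** below 3.02e-8. Both inequalities are strict as
printed in the thresholds' source; boundary values are excluded, and the
tests pin this behaviour. Two per-region override policies mirror how such
screens are run in practice: `all` keeps every eQTL-significant SNP of a
region (used where the LD filter would leave almost nothing), and
`external_evidence` additionally requires a ChIP-seq support flag supplied
as a logical column. How that evidence is derived is outside the package: it
arrives as data.

Coordinates are 1-based inclusive throughout; the BED exporter converts to
0-based half-open at write time. A 2.2-Mb gene-window filter is provided
(`filter_window()`) but off by default, since selection tables are normally
windowed upstream.

## Oligo design and the GC exclusion

`design_templates()` builds, per SNP, the four single-strand oligos (two
alleles × two strands): plus strand = 10-nt left flank + allele + 10-nt
right flank, minus strand = its reverse complement. Only plus-strand
sequences form the mapping template set — the minus strand is the same
duplex, and read matching handles orientation instead — so a library of
*n* SNPs with distinct flanks contains exactly 2*n* unique sequences, and
the reference/variant templates of a pair differ at exactly position 11.

GC-poor duplexes denature and capture poorly, so SNPs whose better allele
oligo falls below `min_gc` are excluded before synthesis. No universal
threshold exists for "low GC"; the default 0.33 (7 of 21 bases) is a
deliberate placeholder and should be set per protocol.

## Perfect-match read counting

Reads (50-bp single-end) contain a 21-bp template embedded in ligation
adapters, so alignment is unnecessary: a read is assigned to a template iff
one of its 21-mers equals the template sequence or its reverse complement
**exactly**. Exact matching doubles as an error filter — any substitution
in the template portion makes the read unmappable, which is why observed
mappable rates sit well below 1 even for clean libraries. Reads matching
two *distinct* templates are counted as `ambiguous` and discarded rather
than multi-counted (conservative; a read containing one template twice
still counts once). Because the two alleles of a pair differ at the central
base, an allele's 21-mer never matches its partner template, so ambiguity
is rare by construction.

QC per sample reports raw/matched/ambiguous/unmatched totals and the
mappable rate; `replicate_correlation()` reports the squared Pearson
correlation of log2(RC + 1) between technical replicates, the standard
count-reproducibility statistic. The +1 offset is a display/QC convention
only and is independent of the scoring pseudocount.

## MATCH-style motif scoring

To ask whether a significant SNP creates or destroys a transcription-factor
binding site, the package reimplements the MATCH similarity scores over
position weight matrices:

* per-position information $I(i) = \sum_b f(i,b)\,\ln(4 f(i,b))$ with
  natural logarithm and the convention $0 \ln 0 = 0$;
* window score $(\mathrm{Current}-\mathrm{Min})/(\mathrm{Max}-\mathrm{Min})$
  where $\mathrm{Current} = \sum_i I(i) f(i, b_i)$ over the scored
  positions and Min/Max substitute the per-position worst/best base — so a
  consensus window scores exactly 1 and an anti-consensus window exactly 0;
* the **core** is the 5 consecutive positions with maximal summed
  information (ties broken leftmost, a convention the original tool leaves
  unstated); the *core score* is evaluated on those positions, the *matrix
  score* on all of them.

A window set where Max = Min carries no information and scores 1 by
convention, with a warning. Zero frequencies may optionally be regularised
as $f = (\mathrm{count} + 0.25\,pc)/(\mathrm{total} + pc)$; the default
$pc = 0$ scores raw frequencies, which is what the published worked
examples assume. `compare_alleles()` scans both 21-nt allele oligos on both
strands and reports `gain` / `loss` / `no_change` per matrix, plus best
scores per allele. Matrices load from TRANSFAC-style text
(`load_transfac()`); no licensed matrix library ships with the package.

## Annotation funnel

`apply_funnel()` prioritises significant SNPs through ordered stages over a
locally supplied annotation snapshot (RegulomeDB-style rank plus a
controlled vocabulary of marks), guaranteeing nested survivor sets. All
annotation joins are local-table operations: no live database queries, so
runs are deterministic and offline.

One documented quirk: published funnels sometimes describe keeping SNPs
with "score higher or equal to 4" in the RegulomeDB scheme, where *lower*
class numbers mean *more* evidence — so the wording contradicts the intent.
Rather than resolve this silently, the comparator direction is explicit:
`rank_direction = "leq"` (default, class ≤ 4 keeps the evidence-rich
classes) or `"geq"`. Motif gain/loss calls from `compare_alleles()` can be
joined into the table as `motif_change`/`tf_bound` marks
(`join_motif_calls()`) to drive the final disruption stage.

## The synthetic experiment

Real SNPs-seq sequencing data is not redistributable, so every pipeline
stage is validated against a seeded generator with known truth
(`simulate_snps()`, `simulate_reads()`). The generative model is the
minimal one under which BAB is an unbiased estimator:

* per-template input abundance $\propto 2^{N(0,\delta^2)}$ — the pool is
  near-balanced, with δ (`input_log2_sd`) defaulting to 0.5 so that ~95% of
  templates lie within 2-fold of the mean, a typical synthesis-pool
  imbalance; at the default depth this also reproduces input replicate
  correlations of R² ≈ 0.98, the level expected of a well-behaved assay;
* in test samples the variant template's weight is multiplied by
  $2^\beta$, where β is the SNP's true log2 binding effect (log-additive
  binding); by default ~45% of SNPs carry a nonzero β drawn uniformly on
  [−5, 4], the span over which real allelic-binding effects are observed;
* per-sample counts are multinomial at the configured depth (default: input
  mappable counts average ≈1000 per template — read depths are rarely
  published for this assay, so this is a stated assumption, not a fit);
* each read is adapter + template (orientation 50/50) + adapter, truncated
  to 50 bp; a configurable fraction of reads per sample (defaults 24% test,
  7% input) is random background sequence, emulating the fragmented
  nuclear DNA that depresses test-sample mappable rates to ~75–78% while
  inputs sit near 93%; substitution errors occur per base at `error_rate`
  (default 0);
* all randomness flows from one integer seed; quality strings are constant
  placeholders because exact matching never reads them.

The generator deliberately omits PCR amplification bias, fragment-size
effects and GC-dependent capture bias. Passing tests therefore demonstrate
that the analysis recovers the truth of *this* model — unbiased estimation
under multinomial sampling with background and substitution error — not
that real libraries are free of those artefacts.

### Precision of BAB and what depth buys

Under multinomial sampling the delta method gives

$$\mathrm{SE}(\mathrm{BAB}) \approx \frac{1}{\ln 2}
\sqrt{\tfrac{1}{N^{test}_{var}} + \tfrac{1}{N^{test}_{ref}} +
      \tfrac{1}{N^{input}_{var}} + \tfrac{1}{N^{input}_{ref}}}$$

with $N$ the pooled per-allele counts. At ~1000 reads per allele per
condition (the default simulated depth) SE ≈ 0.09: comfortably small
against the 0.58 significance cutoff (≈6 SE), which is why
false-positive rates at the cutoff collapse with depth, but not small
enough to pin individual scores to ±0.1 — that requires roughly 3200 reads
per allele, i.e. about 3× the default depth. Depth should be chosen from
this formula and the precision the downstream question actually needs.

## Problem sizes and numerical choices

The test suite exercises the pipeline at 4–100 SNPs and depths of 10³–10⁵
reads per sample, with the template-arithmetic check run at the full
903-SNP library scale; these sizes were chosen to make the sampling
behaviour of every statistic visible while keeping the suite quick to run
routinely. Ties in the core search break leftmost; chromosome sorting uses
natural order (chr2 before chr10); empty samples report a mappable rate of
NA rather than 0; and all pipeline outputs are plain TSV/FASTA/FASTQ with
no timestamps, so a rerun under the same seed is byte-identical.

## Known limitations

* BAB has no attached p-value; significance is a fold-change cutoff, as the
  assay defines it. A count-based test could be layered on top but is not
  part of the method.
* The EMSA module quantifies band-intensity ratios; image densitometry is
  upstream of the package.
* The MATCH reimplementation covers the scoring scheme, not any
  profile-specific cutoff tables shipped with licensed matrix libraries.
* Selection treats eQTL p-values and LD r² as given; the package neither
  computes LD nor maps reads to a genome.
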