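---
title: "Methods and design notes for plaqomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for plaqomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`plaqomics` re-implements, as one coherent R package, the analysis chain
used to contrast stable and unstable atherosclerotic plaques across mRNA,
lncRNA, circRNA and protein layers. This vignette records the statistical
models, the parameter choices and the design decisions behind each stage,
and what the synthetic-data validation does and does not demonstrate.

## Study design emulated by the generator

All defaults mirror a two-group design of five stable versus five unstable
plaque samples. The generator produces every input the pipeline consumes:

* a uniform-composition random genome (default 100 kb, one chromosome) —
  long enough that 20-mers are essentially unique, which is what the anchor
  method relies on in real genomes at realistic anchor lengths;
* non-overlapping multi-exon coding genes on alternating strands (3–5 exons
  of 80–200 bp, introns 300–600 bp, intergenic gaps 400–800 bp). These sizes
  are compressed relative to mammalian genes so that a desk-scale genome can
  carry tens of genes, while preserving the interval topology (exon/intron/
  intergenic) every downstream rule depends on;
* planted lncRNAs, one set per class code: antisense (`x`, one exon inside a
  coding exon on the opposite strand), intronic (`i`, two exons strictly
  inside intron 1 of a host gene) and intergenic (`u`, in a desert more than
  2 kb from any gene). All planted lncRNAs satisfy the expressed-lncRNA
  filter (spliced length > 200 nt, ≥ 2 exons, coverage > 3) by construction,
  and optional decoys violate exactly one rule each (length exactly 200,
  mono-exonic, coverage ≤ 3, same-strand exonic overlap);
* planted circRNAs spanning two consecutive exons of distinct coding genes.
  The four genomic bases flanking each circle are rewritten to the canonical
  splice signal, and the junction-read anchor 20-mers are checked for
  genome-wide uniqueness (the circle is moved to the next exon pair on a
  collision, which makes recovery deterministic rather than probabilistic);
* reads: linear 100 nt reads sampled uniformly over spliced transcript
  positions, plus exactly `junction_reads_per_circ` back-splice-spanning
  reads per circle (first half = 3' end of the circle, second half = its 5'
  start, in transcript orientation). Reads are single-end, error-free by
  default (an `error_rate` knob exists), and strand-agnostic: library
  strandedness is not modelled, so a junction is reported on the strand its
  anchors hit;
* counts: feature-wise negative binomial with `var = mu + alpha mu^2`,
  baseline means log-normal around 100, dispersion 0.1 by default; a
  fraction `frac_de` (default 10%) of features receives a ±`planted_lfc`
  (default 2) log2 shift of the unstable-group mean;
* proteins: log-normal LFQ-like intensities (log2 scale, baseline N(25,
  1.5), residual sd 0.25) for a subset of the count features;
  `n_concordant` of the planted protein changes (default 2) fall on
  mRNA-differential features with the same sign, the rest on features that
  are not differential at the mRNA level — emulating the empirically small
  transcriptome–proteome overlap.

What passing tests on these data do **not** show: robustness to sequencing
error, multi-mapping in repeat-rich genomes, isoform mixtures, paired-end
evidence, missing-not-at-random protein dropout, or batch structure. The
generator validates the *logic* of each stage under its stated assumptions,
not performance on real libraries.

## Back-splice junction calling

A read is first triaged by `map_linear`: exact contiguous placement found by
k-mer seeding (k = 20) and full-length verification against the genome or
its reverse complement. Ambiguous bases never match; mismatches are not
allowed (the generator's reads are error-free, and read alignment proper is
out of scope). Unmapped reads enter `call_backsplice`:

1. the first and last 20 bp of the read (5' and 3' anchors) are mapped;
2. each anchor must have exactly one hit, both on one chromosome and strand
   (rejections: `unmapped-anchor`, `ambiguous`, `discordant`);
3. the anchors must be in *reversed* genomic order — on the plus strand the
   5' anchor lies downstream of the 3' anchor, mirrored on the minus strand.
   Genomic order means a linear or spliced read and rejects as `collinear`;
4. both anchors are extended base-by-base toward the read interior against
   the genome; every split position consistent with the read defines a
   candidate breakpoint (none: `no-extension`). Because the genomic span of
   the circle is the same for every candidate split, the span filter
   (`max_span`, default 100,000 bp) is applied once;
5. among candidate breakpoints, the one whose flanking genomic dinucleotides
   match the splice signal is chosen; if several qualify, the smallest
   5'-anchor extension wins (a deterministic tie-break). With
   `signal = "AG-GT"` (default) the circle must show AG immediately upstream
   of its first base and GT immediately downstream of its last base on the
   annotated strand — the canonical GT–AG intron written acceptor-first.
   The orientation is configurable (`"GT-AG"` swaps the pair, `"off"`
   disables the requirement but still reports the flag) because the
   acceptor-first phrasing is ambiguous in common use. On the minus strand
   the forward genome shows the reverse-complemented, swapped pair
   (AC ... CT).

Junctions are reported with `acceptor` = leftmost circle base and `donor` =
rightmost (1-based, both inclusive), collapsed per identical coordinates
with a read-support count, and filtered at `min_support` (default 1 — no
threshold, since common ≥ 2-read practice is not assumed). TPM uses the
genomic span as the effective length by default; the length term for a
circRNA is genuinely underdetermined (the internal structure of the circle
is unknown to the caller), so a `effective_lengths = 1` mode making TPM
proportional to junction support is provided. TPM conservation
(Σ TPM = 10^6 whenever any support is positive) is exact up to floating
point and tested at relative tolerance 1e-9; all-zero support yields
all-zero TPM rather than 0/0.

## lncRNA class codes and filter

Class precedence is fixed for determinism: same-strand exonic overlap
forces `other`; otherwise opposite-strand exonic overlap gives `x`; else
containment of the transcript span within a single intron of one reference
transcript gives `i` (straddling an exon–intron boundary disqualifies —
the strictest reading of "intronic"); else no overlap with any gene span
gives `u`; anything else is `other`. A transcript on a chromosome absent
from the reference is `u` with a warning. "Length" in the filter is spliced
(summed-exon) length, not genomic span — the natural reading for a
transcript-level threshold; thresholds are strict for length (> 200) and
coverage (> 3) and inclusive for exon count (≥ 2). Overlap queries go through `GenomicRanges::findOverlaps`; the
test suite checks them against a hand-written all-pairs interval scan.

## Differential expression

Counts are normalised by median-of-ratios size factors (geometric-mean
reference over features positive in all samples; library-size ratios as a
guarded fallback), rescaled to geometric mean 1. The two-group test is a
Wald statistic on the difference of log normalised group means with
delta-method standard error under the NB variance model; dispersion is
estimated per feature by method of moments within each group, pooled with
degrees-of-freedom weights, and floored at 1e-8. One numerical choice
matters at this sample size: the statistic is referred to a **t
distribution with n1 + n2 − 2 degrees of freedom** rather than the normal.
With five samples per group the plug-in dispersion is noisy and a normal
reference is anti-conservative (empirical null rejection at p < 0.05 near
0.086 in simulation); the t reference brings the null fraction to
0.045–0.057 across seeds and dispersions 0.05–0.2, which the acceptance
suite verifies against the 99% binomial band around 0.05 at 5,000 features.
Power at the planted |log2FC| = 2, dispersion 0.1, exceeds 99%.

Fold changes use a pseudocount of 0.5 normalised counts in both group means
(configurable), so group-exclusive features get large finite fold changes
rather than infinities; all-zero features get p = 1 and log2FC = 0. The
differential flag is exactly |log2FC| > 1 and **raw** p < 0.05, strict
inequalities; BH q-values are reported alongside for transparency but take
no part in the flag (the selection criterion is deliberately on raw p). Proteins are tested
on log2 intensities with Welch's t (the original protein test is
unspecified; Welch is the declared stand-in), zeros treated as missing at
random, fewer than two observations per group giving p = 1 with a `low_n`
flag, and all-missing proteins excluded from the BH family.

The qPCR calculator implements 2^(−ΔΔCt) with the stable group as the
reference level (fold 1); per-sample ΔCt makes the result invariant to
sample-wide Ct shifts, and samples missing the reference gene are dropped
with a warning.

## Feature links and integration

Cis targets are coding genes whose genomic span lies within ±1 kb of the
lncRNA span, strand-ignored (no strand or anchor-point rule is assumed; the
whole span is used rather than the TSS). Distance follows the
`GenomicRanges::distance` convention — the number of bases strictly between
the two spans, 0 on overlap — so a gene starting 1,001 bp past the lncRNA
end is at distance 1,000 and is the last linked position with the default
window. Origin genes are coding genes with ≥ 1 bp of exonic overlap with
the circle interval, strand-agnostic by default (junction strand may be
unreliable for unstranded libraries) with a `stranded` switch; a circle
spanning exons of two genes yields two links, which is how more origin
genes than circRNAs can arise. Both operations have set semantics with a
deterministic sort on emission and are tested against brute-force all-pairs
comparison.

Integration intersects the differential proteins with differential mRNAs,
cis-target genes and origin genes after case-insensitive symbol
harmonisation (no alias resolution — deliberately no external database
dependency), flagging per-gene sign concordance where both layers carry a
fold change. Enrichment is the hypergeometric upper tail
`P[X >= k]` over a user-supplied GMT collection, sets intersected with the
universe first, BH across the collection, significance reported at raw
p < 0.05 with q alongside. The universe defaults to the genes present in
the expression matrix, the standard over-representation background choice.

## ceRNA networks and PPI clustering

Machine-learned miRNA target scores cannot be reproduced without the
underlying model, so binding is operationalised as canonical seed matching:
the target is scanned for the reverse complement of miRNA positions 2–8
(7mer-m8), promoted to 8mer when the base opposite position 1 is A, with
7mer-A1 as the third class; U and T are interchangeable, and any other
character in a window prevents a match. This is deterministic and testable,
and the network layer (lnc/circ → miRNA → mRNA, edges requiring ≥ 1 site,
duplicate sites collapsing to a site count) is independent of the site
model plugged in. Specific miRNA partners reported by database-dependent
predictions are not reproduction targets.

The PPI clusterer follows the MCODE scheme: each vertex is weighted by the
highest k-core of its closed neighborhood times that core's density;
complexes grow greedily from the highest-weighted unassigned seed,
admitting neighbors with weight ≥ (1 − cutoff) × seed weight (cutoff 0.2);
haircut (iterative removal of vertices with < 2 in-cluster connections) is
on and fluff is off, the usual defaults; complexes need ≥ 3 members. All
tie-breaks are by vertex name, so output is invariant to edge-list
permutation. The test oracle re-derives weights by subset enumeration of
neighborhood cores and clusters by set-based fixed-point expansion on
adjacency matrices, and checks equality on a seeded suite of random graphs
with ≤ 8 nodes; the greedy expansion is not a global densest-subgraph
optimiser and is not claimed to be.

## Pipeline, determinism, problem sizes

`run_pipeline()` executes simulate → index → circ → lncrna → de → links →
integrate → cerna from one `sim_config`, writes each stage's table
(FASTA/GTF/FASTQ/TSV/BED/JSON) and a manifest (package version, seed,
per-stage counts, file checksums). Every random stream derives from the
single seed via fixed offsets, so reruns are byte-identical. Degenerate
inputs are defined rather than fatal wherever the field's tools behave that
way: empty read sets, empty junction sets, all-zero supports, empty DE
tables and empty graphs all produce empty outputs; malformed GTF lines
abort with the offending line number.

Validation sizes were chosen to exercise each property at the scale the
design targets while keeping a full run in seconds-to-minutes: 100 kb
genomes with 20 genes and up to 20 planted circRNAs (3 junction reads each,
2,000 linear reads) for recovery; 1,000 random reads against a brute-force
scan for the mapper; 60 planted lncRNAs plus 20 decoys for classification;
5,000 features for null calibration and power; 500 × 500 random intervals
for the link oracle; exhaustive enumeration up to N = 25 for the
hypergeometric test; ~40 random graphs for the clustering oracle.

## Known limitations

* Exact matching only: one mismatch makes a read (or anchor) unmappable, so
  the caller is not usable on error-containing reads without an upstream
  corrector.
* The breakpoint chosen among signal-consistent splits is the smallest
  5'-extension one; with adversarial sequence (a second AG/GT pair aligned
  with a coincidental extension) a shifted breakpoint could be preferred.
  Anchor-uniqueness planting makes this vanishingly rare in the synthetic
  setting but it is not impossible in principle.
* The NB test is per-feature; no information sharing across features
  (no dispersion shrinkage), no covariates, no batch correction.
* Seed matching ignores site context (AU content, position in UTR) and
  thermodynamics; it is a declared stand-in, not a target predictor.
* Identifier harmonisation is by uppercased symbol equality only.
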