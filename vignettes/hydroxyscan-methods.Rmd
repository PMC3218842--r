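---
title: "hydroxyscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hydroxyscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

hydroxyscan analyses hydroxymethyl-DNA immunoprecipitation sequencing
(hmeDIP-seq) of 5-hydroxymethylcytosine (5hmC). The pipeline consumes
*aligned* reads (BED intervals; alignment and base calling are upstream) for
an IP library and two background controls — input DNA and a no-antibody
mock IP — from each of two independent antibody experiments. It produces
consensus 5hmC regions and their downstream characterisation: normalized
density tracks, gene- and feature-anchored metaprofiles, permutation
overlap enrichment, closest-gene and cell-specific gene-set tests,
Watson-strand base composition and GC-skew profiles, and per-locus
5hmC/5mC quantification from glucosyltransferase + MspI/HpaII qPCR.

All interval coordinates on disk are BED convention (0-based, half-open);
conversion to the 1-based GRanges representation happens only at the I/O
boundary.

# Read processing

Identical reads are collapsed to one read. Read identity includes strand by
default: a read at the same coordinates on the opposite strand is the other
end of a distinct fragment, so collapsing it would discard real library
complexity. `deduplicate_reads(strand_aware = FALSE)` provides the
alternative reading.

Because reads are the sequenced ends of larger fragments, each read is
extended to the library's average fragment size: plus-strand reads keep
their 5' coordinate and grow 3', minus-strand reads keep their 3'
coordinate and grow leftward, clamped at chromosome bounds. No fragment
size is universal; the default of 200 bp is a typical sonicated-library
value and is configurable everywhere it is used.

Density tracks report reads/bp/million uniquely mapping reads: per-base
fragment coverage divided by the library size in millions, written as
bedGraph with equal-value runs merged.

# Region calling

The caller is a fixed-window Poisson island caller in the SICER tradition,
with SICER's canonical window (200 bp) and gap (600 bp) defaults:

1. Fragments are assigned to windows by midpoint (each fragment counts
   once).
2. Windows with at least `min_reads_per_window` (default 2) IP fragments
   that lie within the gap of each other are merged into candidate islands;
   interior below-threshold windows are absorbed into the span.
3. Per island, IP and control fragments are summed over the span, and the
   p-value is the upper-tail Poisson probability of at least the IP count
   at rate `lambda = max(control_count, 1) * ip_library / control_library`.
   The floor of one control read prevents a zero rate in sparse windows
   from producing p = 0.
4. Benjamini-Hochberg correction is applied across all islands of each
   (experiment, control) run independently.

A region is accepted only if it passes FDR < 0.05 against *both* the input
and the no-antibody control (base-pair intersection of the two passing
sets), and the final consensus is the base-pair intersection of the two
antibody experiments, merged when adjacent. This consensus is symmetric in
the experiments by construction, and lowering the FDR can only shrink it.

Two caveats are worth stating plainly. First, island spans are *selected*
on IP-rich windows, so island p-values are not uniform under the null and
the per-run BH step does not control the per-run FDR exactly; the
two-control, two-experiment consensus is what makes the final set specific,
exactly as in the original two-control design. Second, the caller is a
stand-in with the published contract (significant vs both controls at BH
FDR < 0.05, present in both experiments), not a reimplementation of SICER's
clustering score or effective-genome correction; window, gap, eligibility
floor and FDR are all configurable and recorded in output headers.

# Metaprofiles

Gene metaprofiles use fixed 300-bp flank bins and a gene body rescaled to
50 bins (fractional coordinates handle genes shorter than the bin count).
Minus-strand genes are flipped so the TSS is always on the left. The
per-bin statistic is the mean fraction of bin bases covered by at least one
region — the "peak density" reading we adopt; a count-of-region-midpoints
estimator is available via `stat = "midpoints"`. Flank extent defaults to
15 kb and the expression stratification to 5 quantile groups (ranked by
RPKM, ties broken by gene id); neither value is canonical, both are
arguments. Feature-centered profiles use 100-bp windows over +/- 2 kb of
feature midpoints.

Profiles are smoothed by a moving average over +/- 2 bins. At the profile
ends the window is truncated and its weights renormalized, which preserves
constant profiles exactly; the cost is that the first and last two bins
borrow from fewer neighbours, so total profile mass is conserved exactly
only away from the boundary (a local smoother cannot preserve both
constants and the global mean at a truncated edge — that would require a
doubly stochastic kernel). Bins that fall beyond a chromosome end are
excluded from the per-bin denominator rather than imputed as zero.

# Overlap enrichment and gene-set tests

Observed overlap is the fraction of regions with at least 1 bp of overlap
with the feature set (the fraction-of-features direction is available,
since published legends are ambiguous about which side was counted). The
null is built from random interval sets matched to the regions in number
and length: chromosome chosen proportional to length among chromosomes
that fit, start uniform. One hundred draws is the published convention; we
additionally report a z-score and the conservative empirical p-value
(1 + #{null >= observed}) / (n_perm + 1), which is well defined at
n_perm = 100 and never returns 0. Random placement ignores mappability by
default — the toy genome has no gaps — and accepts a mask BED to exclude
regions from placement on real genomes.

Closest-gene assignment measures distance from the nearest region base to
the TSS (0 if the TSS is inside the region), caps assignment at 100 kb,
and breaks exact ties by lexicographic gene id. Note this is a base
distance, not the gap convention of `GenomicRanges::distance()` (which
calls adjacent intervals distance 0); the two differ by one at the
boundary.

Cell-specific genes are those with RPKM >= 0.5 in the cell of interest and
RPKM = 0 in the comparison cell (both boundaries inclusive). The overlap
test builds the {specific, other} x {overlaps regions, does not} table over
gene bodies and reports both percentages with a two-sided Fisher exact
p-value; the published comparison ("specific" vs "all" genes) is reported
as the two percentages, while the test itself uses disjoint groups.

# Sequence composition

Base composition profiles tally Watson-strand base frequencies at each
offset around region anchors (5' boundary = lower coordinate of the
unstranded region, 3' boundary, or midpoint). GC skew is |G - C| / (G + C)
computed from G and C counts pooled over a 100-bp sliding window — pooling
is more stable than averaging per-region ratios when regions are short;
a signed variant (G - C)/(G + C) serves directionality analyses, and is
antisymmetric under reverse complement. N bases are excluded from numerator
and denominator and reported per offset; G + C = 0 yields skew 0 with an
`undefined` flag. The smoothing window is not documented for the published
figures; 100 bp is our default.

# EpiMark quantification

Beta-glucosyltransferase glucosylates 5hmC, which blocks MspI; HpaII is
blocked by any CpG modification. Copy numbers therefore decompose as:
glucosylated+MspI measures 5hmC, HpaII measures 5hmC + 5mC, and
the mock-treated MspI digestion — fully cuttable DNA — defines the
background B of uncut residue (the published description says only
"background signal"; a user-supplied constant can replace this choice).
With D the undigested glucosylated copy number:

    hmc       = (copies[BGT, MspI]  - B) / (D - B)
    resistant = (copies[.,  HpaII]  - B) / (D - B)
    mc        = resistant - hmc
    unmodified = 1 - resistant

HpaII may come from either treatment (glucosylation does not affect HpaII
in this model); if both are present they are averaged. Negative
intermediates are clamped to zero *with flags* so assay failures stay
visible, fractions are renormalized to sum to one, and a denominator at or
below zero is an error, not a number. Replicate standard deviations come
from recomputing the estimate per replicate index. The estimator is
scale-invariant, so units of the copy numbers do not matter.

# The synthetic world

The generator exists so every stage is testable without external data. Its
defaults are a stated world, fixed once:

* **Genome**: 4 chromosomes x 25 Mb, i.i.d. uniform bases outside skewed
  segments. 5% of the genome is planted as 10-kb GC-skewed segments whose
  Watson strand is G-biased in the 5' half and C-biased in the 3' half
  (P(G) = 0.25(1 + b) with b = 0.2, mirrored), so the expected signed skew
  is +b then -b with the sign change at the segment midpoint.
* **Regions**: 200 planted 5hmC regions, normal lengths with mean 1.5 kb
  (the average length reported for real consensus 5hmC regions) and sd
  375 bp; half are centered on skewed-segment midpoints and a fifth on
  enhancer midpoints, the rest uniform, all disjoint.
* **Reads**: 2e5 reads per library. IP read 5' positions follow a
  two-component mixture with density exactly `ip_enrichment` (default 8)
  times the background inside planted regions; the background component
  excludes the regions so the closed-form in-region read fraction
  eR / (eR + G - R) holds exactly. Controls are uniform. Reads are 50 bp,
  random strand, clamped in bounds; each library has exactly `depth` reads.
* **Why 100 Mb**: the genome size sets background occupancy to ~0.4 reads
  per 200-bp window. A fixed eligibility floor of 2 reads/window needs
  sparse background — when occupancy approaches the floor, background
  windows chain into islands whose selected-high IP counts defeat the
  Poisson test. At these defaults the caller recovers 95-97% of planted
  regions with 5-9% false islands across seeds; the depth-to-genome ratio
  is the regime that matters, mirroring tens of millions of reads against
  3 Gb in the real assay.
* **Annotations and expression**: lognormal gene lengths (capped so toy
  genomes can place them), enhancers, TFBS midpoints, and two histone-mark
  sets jittered around enhancers to emulate the enhancer-chromatin
  correlation. RPKM values are lognormal in both cells; 10% of genes are
  made hESC-specific (forced RPKM >= 0.5 / 0).
* **qPCR**: peak loci draw true 5hmC fractions in 9.6-36.4% and control
  loci in 0.5-2.7% (the published locus-level ranges); copies follow the
  EpiMark decomposition with an additive background rate (default 0.05 of
  baseline) and a (1 - background) signal scale, which makes the estimator
  exactly correct at zero noise — the generator is *defined* so that the
  published normalization inverts it. Multiplicative lognormal noise with
  CV 0.1 (mean-one parameterisation) models well-to-well variability.

What the generator does **not** emulate: mappability gaps, CpG islands,
chromatin structure, sequencing error, diploidy, fragment-size variance, or
any correlation between 5hmC and expression. A green recovery test
establishes that the caller finds planted enrichment of the stated strength
against Poisson background — not that it would match SICER on real data.

# Numerical and degenerate-input choices

* Poisson tails via `ppois(x - 1, lambda, lower.tail = FALSE)`; BH via
  `p.adjust`; Fisher via `fisher.test` — each checked in the test suite
  against brute-force summation/enumeration oracles.
* Empty inputs: empty read sets and empty region sets flow through
  (empty islands, zero profiles); an empty *query* set for an overlap
  fraction and an empty control library are errors, because the statistic
  is undefined.
* Degenerate Fisher margins report p = 1 with a flag instead of erroring.
* Seeds: every stochastic entry point takes a seed; the dataset simulator
  derives per-stage sub-seeds (below 2^31) from the config seed, so
  generation is reproducible component-wise and whole-dataset.
* Gene bodies shorter than the body-bin count use fractional bin edges with
  linear interpolation of cumulative coverage, not an error.

# Limitations

The island caller is deliberately simplified (no SICER clustering score,
no effective-genome fraction); its per-run FDR is approximate and the
consensus carries the specificity. Permutation enrichment reports raw
per-feature-set p-values without cross-set multiplicity control. The
closest-gene rule uses TSS distance only, ignoring transcript structure.
GC-skew profiles describe composition; they do not predict replication
origins or R-loops.
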