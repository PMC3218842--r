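# hydroxyscan

Genome-wide mapping of 5-hydroxymethylcytosine (5hmC) from hmeDIP-seq data.

5hmC is the oxidation product of 5-methylcytosine generated by TET enzymes,
abundant in embryonic stem cells and implicated in gene regulation.
hmeDIP-seq enriches 5hmC-containing DNA fragments with an antibody and
sequences them; the analytical problem is to decide which genomic intervals
are genuinely enriched over background and to characterise where those
intervals fall. hydroxyscan is an R package for that analysis, aimed at
epigenomics analysts who have aligned reads in hand.

## What it computes

**Region calling.** After collapsing identical reads and extending each
read to the library fragment size, a SICER-style fixed-window island caller
tests each candidate island against a Poisson background scaled from a
control library:

    p(island) = P( X >= ip_count ),
    X ~ Poisson( max(control_count, 1) * ip_library / control_library )

with windows of 200 bp merged across gaps up to 600 bp and
Benjamini-Hochberg FDR < 0.05 per (experiment, control) run. A region is
kept only if it is significant against **both** the input and the
no-antibody control, and the final set is the base-pair intersection of two
independent antibody experiments.

**Characterisation.** Normalized density tracks
(reads/bp/million uniquely mapping reads, bedGraph); gene metaprofiles in
300-bp bins with a 50-bin scaled body, stratified by expression (RPKM);
feature-centered profiles in 100-bp windows; permutation overlap enrichment
against feature sets using random intervals matched in number and length
(z-score and conservative empirical p = (1 + #{null >= obs})/(n_perm + 1));
closest-gene assignment by TSS distance capped at 100 kb; Fisher's exact
test for cell-specific gene sets (RPKM >= 0.5 vs = 0); Watson-strand base
composition and GC-skew |G - C|/(G + C) around region boundaries; and
EpiMark-style qPCR quantification, where glucosylation blocks MspI at 5hmC
so that

    hmc = (copies[BGT,MspI] - B) / (copies[BGT,undigested] - B),

B being the mock+MspI background, HpaII giving 5hmC + 5mC.

**Synthetic data.** A fully specified generator (toy genome with planted
GC-skewed segments, planted 5hmC regions, matched IP/input/no-antibody
libraries, annotations, expression, qPCR) makes the entire pipeline
testable offline; see the methods vignette for the stated defaults and
their rationale.

## Worked example

```r
library(hydroxyscan)

cfg <- synthetic_config(seed = 42)          # 100-Mb toy genome, 2e5 reads/library
sim <- simulate_hmedip_dataset(cfg)

called <- call_hmedip_regions(sim$experiments$expA, sim$experiments$expB,
                              sim$chrom_sizes)
s <- region_summary(called$regions, sim$chrom_sizes)
# consensus regions: 200, mean length 1364 bp

truth <- sim$truth$regions
mean(IRanges::overlapsAny(truth, called$regions))    # 0.935
mean(!IRanges::overlapsAny(called$regions, truth))   # 0.065

permutation_enrichment(called$regions, sim$truth$enhancers,
                       sim$chrom_sizes, n_perm = 100, seed = 42)
# permutation enrichment (fraction_of_regions, greater): observed 0.1900,
#   null 0.0043 +/- 0.0053, z = 35.23, p = 0.009901 (n_perm = 100)

head(estimate_modifications(sim$qpcr)[, 1:4], 3)
#     locus hmc_fraction mc_fraction unmodified_fraction
# 1 peak_01        0.127       0.318               0.555
# 2 peak_02        0.181       0.179               0.640
# 3 peak_03        0.159       0.406               0.435
```

Reading the output: the caller recovered 93.5% of the planted regions with
6.5% false islands; called regions overlap enhancers 19% of the time where
matched random intervals overlap 0.4 +/- 0.5% (the planted
enhancer preference); and the qPCR estimator returns per-locus 5hmC/5mC
fractions from raw copy numbers.

## Acceptance script

`scripts/acceptance.R` re-runs the package's full synthetic end-to-end
analysis from scratch — simulate the dataset, write it to plain-text files,
run every pipeline stage from those files — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The run takes about a minute on one CPU; per-stage outputs (region BED,
profile/enrichment/skew TSVs, manifest) land in a temporary working
directory, and the script logs the consensus-region count it computed.
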