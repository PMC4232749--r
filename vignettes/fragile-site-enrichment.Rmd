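---
title: "Fragile-site catalogues, feature enrichment and signal deltas: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragile-site catalogues, feature enrichment and signal deltas: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsites)
library(dplyr)
```

## The problem

Common fragile sites (CFSs) are chromosomal regions that preferentially form
gaps and breaks under replication stress, classically after aphidicolin
treatment of cultured lymphocytes. They are named `FRA` + chromosome +
letter (FRA3B, FRA16D, ...), and exist in two catalogues of very different
precision: a *cytogenetic* catalogue whose boundaries are chromosome bands
(megabase precision, 125 sites bundled here), and a *molecular* catalogue
anchored by BAC clones and STS markers on GRCh37 (kilobase precision, 26
sites). Because a number of oncogenes, tumour suppressors and non-coding
RNAs fall inside these regions, a recurring question is whether
cancer-relevant features are merely present in CFSs or actually concentrated
in them.

`fragsites` implements that analysis as a reusable, testable pipeline:

1. **Catalogue handling** -- parse and normalize the site tables, merge them
   into disjoint region sets, and compute genomic extents and haploid-genome
   fractions.
2. **Feature enrichment** -- overlay feature catalogues (cancer-pathway
   genes, miRNA precursors, CTCF ChIP-seq peaks) on the region sets and
   compute inside/outside densities.
3. **Signal summaries** -- reduce a histone-mark signal track to one number
   per site: the site mean minus its chromosome mean, with per-site
   distribution summaries and a grouped one-way ANOVA across cell lines.
4. **Synthetic data** -- generate genomes, fragile-region sets, feature
   catalogues with a planted enrichment ratio and signal tracks with a
   planted per-region shift, so each stage can be checked against known
   truth without any downloads.

## Coordinate and rounding conventions

All internal coordinates are **0-based half-open**, the BED/bedGraph
convention, so interval length is always `end - start`. Printed catalogue
tables use 1-based inclusive coordinates, often with thousands separators;
`read_fragile_sites()` strips separators and decrements start by one on
ingest. This is what makes the per-kb densities of the published per-site
CTCF table reproduce at all three printed decimals (e.g. FRA16D: 378 sites
over 311,195 bp gives 1.215 per kb).

Report-time rounding is **half away from zero** (`round_half_up()`), not
R's default round-half-to-even, because that is how the printed tables were
rounded (44/1871 = 2.35 % must print as 2.4). All statistics are computed
at full precision and rounded only in reports.

The genome-length denominator is G = 3,095,677,412 bp, the sum of the
GRCh37 chr1-22, X and Y sequence lengths bundled as `grch37.chrom.sizes`.
Mitochondrial and unplaced contigs are excluded: haploid-genome fractions
are only consistent with the primary assembly. The catalogue's source
analysis did not state which total it used; this constant is adopted
because it reproduces every printed percentage (27 %, 2.6 %, 37.2 %,
56.7 %) at printed rounding, and it is a config-visible input, not a burned
in constant, everywhere it matters.

## Catalogue quirks and how they are handled

The published tables contain several rows that need explicit policy rather
than silent guessing:

* **Irregular digit grouping.** Several rows print coordinates with
  non-standard comma grouping ("2,8000,000"). Where stripping separators
  yields a unique number the value is used. One row (FRA19B) prints a
  single run of digits that cannot be split into two coordinates
  unambiguously; it is **quarantined** -- excluded from all interval
  computations and surfaced in the exceptions report. Its printed gene and
  miRNA lists still count toward catalogue-level feature totals, which is
  how the published deduplicated counts (110 genes, 686 miRs) are stated.
* **Telomeric sites.** A site whose printed start is a telomere anchor or a
  bare "1" (FRA7B in both catalogues) starts at position 0 of its
  chromosome -- the only consistent reading of the printed rows.
* **Duplicate coordinates.** Seven site pairs (FRA16B/FRA16C, FRA9A/FRA9C,
  FRA8C/FRA8E, FRA5B/FRA5D, FRA10A/FRA10AC1, FRAXE/FRAXF, FRA11C/FRA11I)
  print identical coordinates under distinct codes. They stay distinct for
  per-site reporting but contribute one interval to unions, so extents and
  deduplicated counts are never double-counted.
* **Two-block sites.** FRA10A (and FRA10AC1) span two separate printed
  intervals; they are stored as two rows sharing one site id, with no
  invented bridging interval.

```{r quarantine}
cyto <- read_fragile_sites(fragsites_extdata("cfs_cytogenetic_table.tsv"),
                           "cytogenetic")
site_exceptions(cyto)
```

## The enrichment statistic

For a feature category with `n_in` of `N` features inside a merged fragile
region set of length `L_in`, on a genome of length `G`, the densities per
Mb are `d_in = n_in / L_in` and `d_out = (N - n_in) / (G - L_in)`, and the
headline statistic is the relative increase
`100 * (d_in / d_out - 1)`. It is a descriptive ratio: the analysis it
reproduces reported no significance test for it, and a permutation p-value
is deliberately out of scope here.

```{r enrichment}
G <- genome_length(read_chrom_sizes(fragsites_extdata("grch37.chrom.sizes")))
density_enrichment(110, 327, 835.22e6, G, category = "cancer_gene")
```

Membership is decided by **any-overlap** (>= 1 bp) by default. The source
tables say features are "located within" sites without defining the rule;
any-overlap is the only choice under which very large genes (FHIT at
~1.5 Mb in FRA3B, WWOX in FRA16D, PARK2 in FRA6E) are associated with
their sites regardless of exact boundary placement. `containment` and
`midpoint` are available as config switches, and the assignment is checked
against a per-base brute-force oracle in the test suite.

Deduplicated inside-counts are computed against the merged union per
resolution class: a feature overlapping two same-coordinate sites counts
once at catalogue level while being listed under both site codes.

**Union lengths vs printed totals.** The recomputed union of the bundled
cytogenetic catalogue is 817.7 Mb against the published 835.22 Mb; whether
the original total was overlap-deduplicated is not stated, so the pipeline
reports the union and the naive row-sum side by side and never asserts
agreement (the quarantined FRA19B also cannot contribute). The molecular
union recomputes to 79.37 Mb against the published 79.3 Mb. The
worked-example enrichments (+37.2 %, +56.7 %) therefore take the published
835.22 Mb as their fragile-length input, exactly as the published numbers
were computed.

## The signal delta

For a track S (one histone mark in one cell line) and site *i*, the
statistic is

```
delta_i = mean(S over site_i) - mean(S over the chromosome of site_i)
```

`interval_mean()` is the length-weighted mean of the piecewise-constant
segments covering the interval -- the same quantity a bigWig summary
utility reports. Two conventions exist for uncovered bases: excluded from
the weighting (the default) or counted as zeros (`gaps_as_zero = TRUE`);
the choice is recorded in output metadata. An interval with *no* covered
base has an undefined mean and raises a typed condition -- deliberately
distinct from a mean of zero. Chromosome baselines are computed once per
(track, chromosome) and cached; a globally shifted track (value + c
everywhere) yields identical deltas.

Per-site distributions are summarised by the five-number summary with
1.5 x IQR whiskers. The quartile rule defaults to linear interpolation
(type 7), with Tukey hinges as an option; the source analysis did not state
a rule, so it is explicit and recorded.

Cell-line groups are compared by one-way fixed-effects ANOVA on the
deltas. The default grouping ships as an editable config:
K562, GM12878 and H1-hESC as the cancer/embryonic class, NHEK as normal
epithelial, and HSMM, HUVEC, NHLF as normal mesenchymal. Whether a
lymphoblastoid line (GM12878) belongs with the cancer-like class is an
assumption carried over from the grouping that analysis described, flagged
here rather than hidden.

Reproducing the original ENCODE-scale numbers (per-cell-line H3K27ac and
H3K4me3 deltas for every site) requires multi-gigabyte bigWig downloads and
is a documented optional workflow, not part of the test surface; the
published per-site mean H3K27ac column is carried through reports verbatim
as a pass-through column, never recomputed.

## The synthetic generator

The generator emulates the statistical structure the analysis rests on,
with every planted parameter recoverable:

* `simulate_regions(chrom_lengths, fragile_fraction, n_sites, seed)` --
  disjoint equal-length sites totalling the target coverage within 1 %.
  The default study condition mirrors the real geometry: fragile fraction
  0.27 (the cytogenetic catalogue's share of the genome).
* `plant_features(assembly, merged, lambda, rho, seed)` -- Poisson feature
  counts at rate `rho * lambda` per Mb inside and `lambda` outside,
  positions uniform within their stratum. Features are 1 bp points on the
  integer grid so planted inside/outside counts are exact; the expected
  relative increase is `100 * (rho - 1)`. The reference planted value
  `rho = 1.372` echoes the cancer-gene enrichment the pipeline reproduces.
* `simulate_track(assembly, sites, mu, delta, sigma, bin, seed)` -- binned
  track with value `mu + delta` in bins whose midpoint falls inside a site,
  plus Gaussian noise. The truth file records both the analytic expectation
  `delta * (1 - L_site / L_chrom)` and the exact noise-free delta under the
  realized binning (identical when site boundaries align with bins).

All draws come from R's seeded generator; identical config and seed give
byte-identical output bundles, and each emitted file records the seed and
coordinate convention in its header.

What the generator does **not** emulate: sequence composition (AT-rich
stretches, Alu density), replication timing, non-uniform real feature
clustering (miR clusters), or correlated noise in ChIP-seq tracks. Passing
the recovery tests therefore demonstrates the estimators are unbiased under
the declared sampling model, not that real ENCODE tracks would behave this
way.

## Verification problem sizes

The test suite checks interval merging and feature assignment against a
per-base boolean-array oracle on 1,000 random toy instances (genomes up to
100 kb); recovers the planted `rho = 1.372` as a mean relative increase
within 3 Monte-Carlo standard errors of +37.2 over 200 replicates (and a
planted null within 3 SE of 0); recovers planted signal shifts within 3 SE
of the closed form over 100 replicates; and verifies the ANOVA holds its
nominal size (type-I error within [0.03, 0.07] at alpha = 0.05 over 2,000
null simulations of 4 groups) and detects a 5-sigma group shift at
p < 0.001. These sizes were chosen to give stable Monte-Carlo verdicts at
desk scale.

## Known limitations

* Printed coordinates are authoritative: no re-derivation of molecular
  boundaries from BAC/STS sequences, no liftover, no FASTA handling.
* The enrichment is descriptive; no permutation or analytic significance
  test is attached to the density ratio.
* Independently published per-kb densities can differ in the third decimal
  where the original scripts used slightly different site boundaries; the
  per-site report carries a `coords_source` provenance column for this
  reason.
* Real-data runs (miRBase GFF3, ENCODE peak and signal files) are supported
  through the file readers but are not reproduced in tests, which rely on
  bundled tables and synthetic data only.
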