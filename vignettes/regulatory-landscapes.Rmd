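---
title: "Methods: defining H3K27ac regulatory landscapes and their target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defining H3K27ac regulatory landscapes and their target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

# Overview

`regland` turns replicate H3K27ac ChIP-seq peak sets from two cell
populations into a catalogue of promoters, enhancers and super-enhancers,
labels each region as cell-specific or shared, and nominates target genes
whose differential expression is concordant with that specificity. This
vignette is the package's account of the method: the procedure and its
assumptions, every tunable parameter with its default and rationale, the
design of the synthetic-data generator, and the numerical conventions and
known limitations.

The pipeline consumes data *downstream* of peak calling and differential
expression modelling: per-peak IP and input signal summaries, a TSS
annotation, a normalized expression matrix, and a DE table
(gene, log2 fold change, p, adjusted p). Read alignment, peak calling and
count-model fitting are out of scope by design — the package analyses their
outputs.

# Coordinates and interval algebra

All coordinates are 0-based, half-open (the BED convention), everywhere
internally: the length of `[start, end)` is `end - start`, abutting
intervals overlap by zero bases, and overlap arithmetic has no ±1
corrections. One-based annotation dialects must be converted at the reader
boundary. Chromosome names are compared as exact strings; no "chr" prefix
normalization is applied, because silent renaming hides input errors.

Two interval primitives carry the whole workflow:

* `merge_intervals(x, gap)` — connected components under "separated by at
  most `gap` bases". The distance between sorted non-overlapping intervals
  is `start2 - end1`, and "within distance d" means `start2 - end1 <= d`
  (so `gap = 0` merges overlapping *and* abutting intervals). Merging is
  idempotent and independent of input order.
* `reciprocal_overlap(a, b)` — the overlap length as a fraction of each
  interval's own length.

The per-peak signal used throughout is the input-subtracted density
`max(ip - input, 0)`: densities below the matched control carry no evidence
of activity, so negative differences are clamped to zero rather than
propagated.

# Consensus regions and classification

`consensus_regions()` merges all replicate peaks of one condition at gap 0
and keeps components touched by at least `min_replicates = 2` distinct
replicates. Support is evaluated on the merged component as a whole: a chain
rep1–rep2–rep3 counts all three replicates even where single bases are
covered by one replicate only. This region-level reading of "present in at
least 2 replicates" is the default; a base-wise notion of support would
fragment regions at replicate boundaries and is deliberately not the
default. The aggregated region signal is the *sum* of the contributing
peaks' input-subtracted signals — the simplest convention when replicate
peaks overlap partially, isolated in one place so a length-normalized
variant can be swapped in.

`classify_regions()` measures the distance from the region *centre*
(`floor((start + end)/2)`) to the nearest TSS on the same chromosome:
promoter if strictly less than `promoter_dist = 2000` bp, enhancer
otherwise. The centre is the reference point for both classification and
promoter annotation, keeping the two consistent; the measure-zero case of a
centre exactly 2 kb from the nearest TSS is assigned to the enhancer class
(the thresholds are strict "< 2 kb" / "> 2 kb"). Promoters are annotated to
the gene whose TSS is nearest the centre, ties broken by lexicographically
smallest gene id so results are deterministic. Regions on chromosomes
without any annotated TSS are classified as enhancers and flagged
(`no_tss_chrom`).

`assign_window_genes()` links enhancers (and stitched super-enhancers) to
candidate target genes: all genes whose TSS falls in
`[start - w, end + w)` for `w` in 100, 200, 400 kb. The lower bound is
closed and the upper open, mirroring half-open intervals; gene sets are
nested across window sizes by construction. Linear windows are a deliberate
simplification — no chromatin-contact (Hi-C/TAD) information is used, so
"window gene" means *potentially* contacted, not demonstrated target.

# Cell specificity by reciprocal overlap

`call_specificity()` compares the regions of two conditions class by class.
A region is **shared** when some region of the other condition overlaps at
least `min_fraction = 0.3` of *both* intervals — the stricter, both-ways
reading of "reciprocal overlap", equivalent to `bedtools intersect -f 0.3
-r`. The threshold comparison is `>=` for shared. A one-way reading (either
interval covered to 0.3) is available as `mode = "any"`. When a region
overlaps several partners, candidate pairs are evaluated pairwise and the
best pair (largest minimum of the two fractions) decides; aggregating
overlap across partners was considered and rejected as the default because
the pairwise rule is the simplest falsifiable reading of a two-set
comparison. Labels partition each input set, the comparison is symmetric
under swapping the two sets, and raising the threshold can only increase
the number of specific regions.

# Super-enhancers

Following the ROSE procedure, enhancers wholly contained in a window of
±`tss_exclusion = 2500` bp around any annotated TSS (a total 5,000 bp
promoter exclusion zone) are removed; partial overlap does not exclude.
Remaining enhancers are stitched at `stitch_distance = 12500` bp (boundary
to boundary, `<=` at the boundary), summing constituent signals.

Stitched enhancers are ranked by ascending signal; ranks and signals are
scaled to [0, 1]. The classical separation point is where the tangent to
the convex rank-signal curve has slope 1. `call_superenhancers()` computes
it parameter-free as the point maximizing `scaled_rank - scaled_signal` —
the point furthest *below* the diagonal, which on a convex ascending curve
is exactly the slope-1 tangent point (the increments of
`scaled_rank - scaled_signal` change sign where the local slope crosses 1).
This avoids the numerical differentiation and smoothing of the reference
implementation, which are not reproducible from their description, and is
validated in the tests against an exhaustive secant-slope search. Ties in
the maximized quantity resolve to the higher-signal point, a conservative
cutoff. Everything with signal strictly above the cutoff signal is a
super-enhancer: the separation is contiguous in rank, monotone
(every super-enhancer outsignals every typical enhancer) and scale-invariant.

Degenerate inputs take a defined path: fewer than 3 stitched enhancers, or
all signals identical (a flat curve has no slope-1 tangent), yield no
super-enhancers, with a warning in the first case.

Super-enhancer specificity and window genes reuse `call_specificity()` and
`assign_window_genes()` on the stitched intervals, so conventions cannot
drift between region classes.

# Expression integration

The DE table's `log2fc` must be oriented numerator-over-denominator in the
order the comparison is run (`A_vs_B`: positive means higher in A); all
directional logic derives from this single convention. For a region
specific to the numerator condition, window genes with
`log2fc >= +threshold` are concordant; for denominator-specific regions,
`log2fc <= -threshold`; both require BH-adjusted p < `padj = 0.05`. The
fold-change gate is inclusive (`>=`) and the padj gate strict (`<`) — a
documented measure-zero boundary convention. Default thresholds are 1.5 for
enhancer-linked genes and 1.0 for super-enhancer-linked genes. Genes linked
by several specific regions are counted once per set; linked genes missing
from the DE table are excluded and reported, not silently dropped.
`bh_adjust()` is the step-up false-discovery-rate correction
(a validated wrapper over `stats::p.adjust(method = "BH")`, cross-checked
in the tests against a hand-written step-up implementation).

Two validations probe the biological claim behind the integration:

* `near_vs_global_expression()` — one-sided two-sample Wilcoxon rank-sum
  test of per-gene within-condition mean expression, region-linked genes
  versus all *other* genes. The comparison group is the complement rather
  than the whole genome so the two samples are independent and the test is
  exactly calibrated under the null; with linked genes a small fraction of
  the genome the two readings are numerically indistinguishable.
* `cross_population_validation()` — paired one-sided Wilcoxon signed-rank
  test of per-gene mean expression in the matching condition minus the
  other condition, over genes linked to condition-specific regions.

Both use per-gene within-condition means (rather than per-sample values),
treating the gene as the sampling unit. Exact null distributions are used
for small samples (both groups ≤ 8, no tied ranks; for the paired test no
zero or tied absolute differences), the normal approximation with
continuity correction otherwise; the two branches agree to well under 0.01
at the switch point. One-sided alternatives match the directional claims;
two-sided tests are available by argument.

# The synthetic-data generator

`simulation_config()` + `simulate_landscape()` generate a genome with known
planted structure so that every stage is testable without external data.
What it emulates:

* **Replicate structure** — each planted region emits a peak per replicate
  with probability `replicate_reproducibility` (default 0.9, 4 replicates),
  with Gaussian boundary jitter (`peak_jitter_bp = 50`) and multiplicative
  log-normal IP noise (`signal_noise_sd = 0.2`); input signal is a uniform
  fraction (5–20%) of IP. Spurious background peaks arise in single
  replicates at `background_fp_rate = 0.5` per Mb, placed clear of planted
  regions so they can only form single-replicate components.
* **Region classes** — shared enhancers (40), condition-specific enhancers
  (30 per condition), and promoter regions centred on gene TSSs (30,
  shared). A fraction `se_fraction = 0.1` of enhancer regions is flagged
  super-enhancer.
* **A long-tailed signal distribution** — typical regions draw log-normal
  signals (`meanlog 2.5`, `sdlog 0.8`), super-enhancer regions from an
  upper tail shifted by `se_signal_factor = 25` with half the dispersion.
  This yields the convex rank-signal curve the cutoff assumes, with the
  flagged regions separable at the inflection point.
* **Concordant expression** — each condition-specific region gets one
  linked gene placed 10–80 kb away, whose log2 expression is raised by
  `effect_log2fc = 2` in the matching condition; per-sample Gaussian noise
  has `expr_noise_sd = 0.5`. The DE table is fabricated the way consumed
  tables are produced in practice: the difference of condition means with a
  variance-moderated two-sample t-statistic (limma `lmFit`/`eBayes` on the
  normalized matrix) and BH adjustment. An unmoderated 4-vs-4 t-test would
  understate the power of the count models these tables come from and is
  not what any practitioner would feed this pipeline.

The layout places every element on genomic slots 500 kb apart (order
shuffled, positions jittered). This guarantees planted regions never merge
at the 12.5 kb stitching distance, linked genes stay outside the promoter
zone of their region but inside its 100 kb window, all TSSs respect a
minimum spacing, and — because the spacing exceeds the largest gene window
(400 kb) — the window genes of a planted region are exactly its own planted
gene(s), making every region-to-gene link identifiable. An explicit
`chrom_length` too small for the requested counts is rejected
("infeasible spacing").

Determinism: one master seed with fixed per-component sub-streams
(truth / peaks / expression), so outputs are bitwise reproducible and
changing one component's parameters does not perturb the others' draws.

What the generator does **not** emulate: read-level sampling (no
FASTQ/BAM), fragment-length or GC effects, copy-number distortion,
overlapping or nested true regions, chromatin-contact structure, and
count-distribution artefacts of real RNA-seq. Passing the recovery tests
therefore shows the *logic* of the workflow is correct under its stated
assumptions, not that the thresholds are optimal for any particular real
dataset.

With all noise switched off (`replicate_reproducibility = 1`,
`peak_jitter_bp = 0`, `background_fp_rate = 0`, `expr_noise_sd = 0`,
`signal_sdlog = 0`, `signal_noise_sd = 0`, a fixed input fraction) every
stage becomes an identity: consensus regions equal planted regions,
specificity labels equal planted specificity, the super-enhancer set equals
the flagged set (a flat signal body plus outliers has its tangent point
exactly at the last typical enhancer), estimated log2 fold changes equal
the planted effect exactly, and reruns are byte-identical.

# Problem sizes and expected recovery

The default simulated landscape (two chromosomes, ~136 Mb each, 500 genes,
~100 regions per condition) runs end-to-end in a few seconds, and the
package's own checks use: 200 random instances (≤ 100 peaks/regions) for
oracle equivalence of the interval layer, 100 random convex curves
(20–500 points) for the cutoff, 1,000 random vectors for the BH
cross-check, 2,000 Monte-Carlo draws for rank-test calibration, and ten
landscapes at the default conditions for end-to-end recovery. At those
conditions the pipeline recovers ≥ 95% of planted condition-specific
regions, ≥ 90% of planted super-enhancers, and ≥ 90% of planted
region-to-gene links; link recovery is capped near 92% by design, because
an estimated log2FC of a gene with true effect 2 and noise SD 0.5 over
4 + 4 samples is distributed N(2, 0.354) and the enhancer threshold keeps
only estimates ≥ 1.5.

# Known limitations

* Specificity is pairwise; multi-way contrasts are composed from pairwise
  runs rather than called jointly.
* The signal aggregation across replicate peaks (summation) weights deeply
  sequenced replicates more; a length- or replicate-normalized variant
  would change super-enhancer ranks.
* Window-based gene assignment nominates candidates only; concordance
  filtering reduces, but cannot eliminate, bystander genes.
* The rank-signal cutoff assumes a convex curve; on non-convex empirical
  curves the argmax rule still returns a deterministic, scale-invariant
  cutoff, but it is no longer a slope-1 tangent.
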