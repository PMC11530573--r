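# regland

Defining active regulatory regions from H3K27ac ChIP-seq and linking them to
the genes they regulate.

## The problem

Acetylation of histone H3 at lysine 27 (H3K27ac) marks active promoters and
enhancers. Given broad-peak calls from replicate H3K27ac ChIP-seq experiments
in two cell populations, a recurring analysis in regulatory genomics is:

1. **Consensus regions** — merge each condition's replicate peaks and keep
   regions supported by at least 2 replicates.
2. **Promoters vs enhancers** — a consensus region whose centre lies < 2 kb
   from the nearest annotated TSS is a putative promoter (annotated to that
   gene); > 2 kb, a putative enhancer. Enhancers are linked to candidate
   target genes through 100/200/400 kb windows around their boundaries.
3. **Cell specificity** — a region is specific to its condition if no region
   of the other condition reciprocally overlaps it by a fraction of at least
   0.3 of both intervals; otherwise shared.
4. **Super-enhancers** — enhancers outside a ±2.5 kb TSS exclusion zone
   (a 5,000 bp promoter exclusion zone) are stitched when within 12,500 bp,
   ranked by input-subtracted signal, and split into typical and
   super-enhancers at the inflection point of the rank-signal curve
   (ROSE-style).
5. **Concordant target genes** — window genes of condition-specific regions
   are kept when their differential expression agrees with the region's
   specificity: |log2FC| ≥ 1.5 (enhancers) or ≥ 1.0 (super-enhancers), with
   Benjamini–Hochberg adjusted p < 0.05, signed toward the condition the
   region is specific to. Gene lists are exported for downstream enrichment
   tools.
6. **Validation** — one-sided Wilcoxon tests check that region-linked genes
   are more expressed than the rest of the genome within the matching
   condition, and (paired, per gene) more expressed in the matching condition
   than in the other one.

`regland` implements this workflow as composable, pipe-friendly functions
(tibbles in, tibbles out), plus a seeded synthetic-data generator that plants
a known regulatory structure — shared/specific regions, a long-tailed signal
distribution with a super-enhancer upper tail, and expression effects on
genes near specific regions — so every stage can be validated against ground
truth.

## The super-enhancer cutoff

Stitched enhancers are sorted by ascending input-subtracted signal
s₍₁₎ ≤ … ≤ s₍ₙ₎; ranks and signals are scaled to [0, 1]:
xᵢ = i/n, yᵢ = (s₍ᵢ₎ − s₍₁₎)/(s₍ₙ₎ − s₍₁₎). On the convex "hockey-stick"
curve this produces, the cutoff is the point where the tangent has slope 1,
found parameter-free as

  i\* = argmaxᵢ (xᵢ − yᵢ)

(the point furthest below the diagonal). Everything with signal strictly
above s₍ᵢ\*₎ is a super-enhancer, so super-enhancers occupy the top ranks
contiguously; the separation is invariant to rescaling the signals.

## Worked example

```r
library(regland)

cfg <- simulation_config(seed = 11)   # two conditions, 4 replicates each
sim <- simulate_landscape(cfg)        # peaks, TSS, expression, DE, truth

res <- run_pipeline(pipeline_config(
  conditions = cfg$conditions,
  peaks = sim$peaks, tss = sim$truth$tss, de = sim$de, expr = sim$expr
))

str(res$report$counts$regions)
#> List of 2
#>  $ condA:List of 5
#>   ..$ consensus     : int 100
#>   ..$ promoters     : int 30
#>   ..$ enhancers     : int 70
#>   ..$ stitched      : int 70
#>   ..$ superenhancers: int 10
#>  $ condB:List of 5
#>   ..$ consensus     : int 99
#>   ..$ promoters     : int 30
#>   ..$ enhancers     : int 69
#>   ..$ stitched      : int 69
#>   ..$ superenhancers: int 8
```

Each condition recovers its ~100 planted regions (40 shared enhancers, 30
condition-specific enhancers, 30 promoters; one region in condB fell below
the 2-replicate support filter at reproducibility 0.9). The concordant genes
are the planted targets, ranked by effect size:

```r
head(res$concordant, 4)
#> # A tibble: 4 x 7
#>   comparison     region_class window_kb condition gene_id  log2fc     padj
#>   <chr>          <chr>            <int> <chr>     <chr>     <dbl>    <dbl>
#> 1 condA_vs_condB enhancer           400 condA     gene0021   2.59 1.31e-11
#> 2 condA_vs_condB enhancer           400 condA     gene0085   2.43 1.87e-10
#> 3 condA_vs_condB enhancer           400 condA     gene0086   2.31 1.27e- 9
#> 4 condA_vs_condB enhancer           400 condA     gene0057   2.31 1.27e- 9
```

Genes linked to condition-specific enhancers are significantly more
expressed in the matching condition (paired one-sided Wilcoxon):

```r
dplyr::filter(res$validation, class == "enhancer", test == "cross_population")
#>   condition statistic     p.value median_diff     n
#> 1 condA           495 0.000000681        1.91    31
#> 2 condB           496 0.000000617        2.03    31
```

and the run can be scored against the planted truth:

```r
str(evaluate_recovery(sim, res))
#> $ specific_recovery : num 1
#> $ se_recovery       : num 0.933
#> $ link_recovery     : num 0.967
#> $ cross_population_p: Named num [1:2] 6.81e-07 6.17e-07
```

`autoplot()` on `res$se_calls` (or any `call_superenhancers()` result) draws
the rank-signal hockey-stick with the cutoff line. With `out_dir` set,
`run_pipeline()` also writes every stage as TSV (`regions.tsv`,
`specificity.tsv`, `superenhancers.tsv`, gene lists, `validation_report.tsv`)
plus a deterministic `report.json`.

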