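# srnasig

Small-RNA sequencing signatures of exogenous dsRNA processing in plants.

When dsRNA is sprayed onto leaves (spray-induced gene silencing), does the
plant RNAi machinery actually process it into siRNAs, or is it merely
degraded by nucleases? `srnasig` decides this from small-RNA read size,
strand and position signatures, comparing three conditions: dsRNA-sprayed
plants carrying the target transgene (`target_ds`), dsRNA-sprayed wild-type
plants with no target (`wildtype_ds`), and water-sprayed target plants
(`target_water`). It is aimed at researchers evaluating topical RNA
delivery (crop protection, transgene silencing assays) who need a
reproducible, testable alternative to eyeballing read-length histograms.

## What it computes

Genuine DCL processing leaves fingerprints that random degradation cannot:

- **size-class enrichment** of 21/22/24-nt reads in `target_ds` vs
  `wildtype_ds` — per-length pooled-variance Student *t* on raw counts, plus
  one-way ANOVA with Bonferroni letters on water-control-normalized ratios,
  plus miR159 / total-24-nt functional normalizations;
- **transitivity** — antisense reads in the regions flanking the sprayed
  trigger interval, tested against a Poisson background estimated from the
  wild-type condition (which cannot contain secondary siRNAs);
- **phasing** — the maximal fraction of 5' ends on one of the *L* phase
  offsets of the trigger register, with a Bonferroni-corrected binomial
  p-value;
- **exponential length decay** — OLS of log counts on read length; pure
  degradation gives |r| ≈ 1, diced read sets do not;
- a 2×2 **Fisher exact test** of long/short read ratios inside vs outside
  the trigger.

A classifier combines these into `DCL_PROCESSED`, `DEGRADATION_ONLY` or
`INCONCLUSIVE`. A seeded synthetic-read generator emulates the 7-sample
spray design (degradation, dicing, phasing, transitivity and background
knobs), so the whole pipeline is testable without sequencing data. A dose
calculator converts mass concentrations to molarities (660 g/mol per duplex
bp, 330 g/mol per ss nt) and computes phased-siRNA yields
(`floor(length/22)`) and effective-molarity ratios between treatments.

## Worked example: the published seven-sample count table

The package embeds the published per-sample totals and 20–25-nt
target-region counts of the spray experiment it emulates:

```r
library(srnasig)
tab <- load_published_counts()
rep <- analyze_counts(tab)
tibble::as_tibble(rep$enrichment)
#> # A tibble: 6 × 7
#>   length mean_a mean_b statistic p_value significant direction
#>    <int>  <dbl>  <dbl>     <dbl>   <dbl> <lgl>       <chr>
#> 1     20   246.   262     -0.487   0.652 FALSE       depleted
#> 2     21   225.   256     -0.877   0.430 FALSE       depleted
#> 3     22   221.   243.    -0.654   0.549 FALSE       depleted
#> 4     23   185    205.    -1.23    0.287 FALSE       depleted
#> 5     24   169.   197.    -0.752   0.494 FALSE       depleted
#> 6     25   161.   171     -0.363   0.735 FALSE       depleted
rep
#> <signature_report> classification: DEGRADATION_ONLY
#>   silencing-size enrichment: FALSE | transitivity: FALSE | phasing: FALSE
#>   decay consistent (condition mean |r| >= 0.90): TRUE [target_ds=0.938, wildtype_ds=0.923]
#>   note: no flank data: transitivity not assessed
#>   note: no position data: phasing not assessed
#>   note: single-replicate water control: normalization denominator is statistically fragile
```

No length class is significantly different between the sprayed target line
and the sprayed wild type (`mean_a` vs `mean_b`, all p ≥ 0.29), and every
sprayed sample's length histogram is decay-shaped — so the sprayed dsRNA
shows no evidence of DCL processing and the verdict is degradation only.

The dose arithmetic for the sprayed solution:

```r
molar_result(dose_spec(20, 139, "duplex", label = "sprayed dsRNA"))
#> # A tibble: 1 × 4
#>   label         molarity sirna_yield effective_molarity
#>   <chr>            <dbl>       <int>              <dbl>
#> 1 sprayed dsRNA    0.218           6               1.31
```

i.e. 20 ng/µl of a 139-bp duplex is 0.22 µM, worth six phased 22-nt siRNA
units per molecule.

Simulated experiments run end to end from one config:

```r
res <- run_pipeline(list(mode = "simulate", scenario = "positive", seed = 1),
                    outdir = "run_out")
res$report$classification
#> [1] "DCL_PROCESSED"
```

A thin CLI over the same functions lives in `inst/cli/srna-signature.R`
(`simulate`, `count`, `stats`, `classify`, `dose`, `run` subcommands).

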