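# phenocount

Counting reproductive structures — buds, flowers, and fruits — on digitized
herbarium sheets, from point annotations to evaluated counts.

Herbaria hold hundreds of millions of pressed specimens whose phenological
state (is the plant budding, flowering, fruiting — and how intensely?) is a
key trait for studying responses to climate change. Scoring that state by
hand does not scale. `phenocount` implements a two-phase pipeline for
automating it:

1. **Weak labels to instance masks.** Human annotators (experts or
   crowd-sourcers) place a single dot at the center of each visible
   reproductive structure. Dots alone cannot train an instance-segmentation
   detector, so the package converts each dot into a *dodecagon mask*: a
   regular 12-gon inscribed in the circle of radius r̄ calibrated per genus
   and organ from a handful of manually segmented structures (the mean
   enclosing-circle radius). Images are resized to fit 1,024 px (long edge)
   × 600 px (short edge), masks are clipped at sheet borders, and the result
   is exported as a standard COCO instance-segmentation dataset together
   with anchor sizes that guarantee every mask is covered.
2. **Counting by detection.** A detector backend returns one instance per
   detected structure; the predicted count of organ k on specimen i is
   simply the number of detected instances, ĉ_{i,k}. The package defines
   the backend contract, ships a deterministic color-threshold +
   connected-components baseline (so the whole pipeline runs on a CPU in
   seconds), and evaluates counts with:

   - counting error  e_{i,k} = ĉ_{i,k} − c_{i,k} (signed; positive =
     over-count),
   - MAE — the mean of |e| per organ, with the "All" column the unweighted
     mean of the three per-organ MAEs,
   - R² = 1 − Σ(c − ĉ)² / Σ(c − c̄)² (can be negative; undefined for
     constant truth),
   - letter-value summaries (median, fourths, eighths, …) of the error
     distribution,
   - presence and dominance accuracy (e.g. "flowers ≥ buds"), reported as
     prevalence-weighted TP/TN rates,
   - crowd-vs-expert-vs-model comparisons with paired signed-rank tests.

A synthetic herbarium-sheet generator (beige sheet, green clutter, organ
blobs with controlled zero-inflated Poisson counts mirroring the strong
flower ≫ fruit ≫ bud imbalance of real collections) provides full ground
truth, so every stage is testable without downloading specimen imagery.
A scenario harness runs per-species, global, and cross-species transfer
experiments over any backend.

## Worked example

```r
library(phenocount)

dir <- file.path(tempdir(), "demo")
generate_dataset(12, sheet_params(), dir, seed = 42)
specimens   <- read_specimens(file.path(dir, "manifest.csv"))
annotations <- read_annotations(file.path(dir, "annotations.csv"), specimens)

composition_summary(count_truth(annotations, specimens))
#> # A tibble: 3 × 3
#>   organ  total percent
#>   <fct>  <int>   <dbl>
#> 1 bud        3    10.3
#> 2 flower    22    75.9
#> 3 fruit      4    13.8

report <- run_scenario(scenario_config("global", "Fictularia prima"),
                       annotations, specimens, image_dir = dir)
report
#> <scenario_report> global/train=Fictularia prima/test=Fictularia prima/seed=1/tau=0.5/backend=baseline-color-threshold
#>   specimens: 12 train / 12 test
#>   MAE (all): 0.000 | R^2 (all): 1.000

tidy(report)
#> # A tibble: 4 × 4
#>   organ    mae r_squared     n
#>   <chr>  <dbl>     <dbl> <int>
#> 1 bud        0         1    12
#> 2 flower     0         1    12
#> 3 fruit      0         1    12
#> 4 all        0         1    36
```

The composition table shows the generator reproducing the imbalance of real
collections (flowers dominate, buds are rare). The scenario report says the
baseline detector, "trained" (palette-fitted) on these noiseless sheets,
recovered every count exactly: MAE 0 and R² 1 for all three organs. On real
imagery a learned backend replaces the baseline through the same contract,
and `autoplot(report)` draws the letter-value plot of its counting errors.

A thin command-line wrapper exposes the same stages
(`inst/cli/phenocount simulate | calibrate | export-coco | detect | count |
evaluate | compare-crowd | run-scenario`).

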