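# biocogs

Cost-of-goods modelling for uricase bioprocesses under uncertainty.

Uricase, the gout therapeutic enzyme, is produced in *E. coli* and purified
either over three sequential chromatography columns or in a single aqueous
two-phase extraction (ATPS) step — optionally followed by a back-extraction
stage that recycles 60% of the PEG and 20% of the salts into the next batch.
`biocogs` provides a transparent, calibratable cost engine for comparing the
three flowsheets, replacing black-box commercial costing software with an
explicit structure that can be audited and tested.

For a flowsheet running `B = target_output / (V·T·Y)` batches per year
(fermenter volume `V`, titer `T`, composite downstream yield `Y`), the annual
cost in each of five categories (capital, materials, consumables, labor,
other) is

```
C_k = F_k + B · v_k
```

— an annual fixed cost plus a per-batch variable cost — and CoG/g is the
total divided by the annual product mass. Materials carry named per-batch
line items (media, PEG2000, ammonium sulfate, NaCl), UF/DF filter consumables
follow a ceiling rule on the processed volume, and labor is a wage set times
a headcount-equivalent. `calibrate_fixture()` anchors the engine to the
published base cases ($9,396.97/g chromatographic, $5,452.00/g ATPS, labor at
13%); the recycle flowsheet is deliberately **not** calibrated — its CoG/g
emerges from the back-extraction mass balance (fresh-demand credits of
`(1−r)·inventory` on the chemicals versus a 10x-diluted UF/DF feed) and lands
at $5,431.66/g against the published $5,430/g.

On top of the engine the package provides one-at-a-time tornado sensitivity
analysis, Monte Carlo propagation of triangular titer/yield uncertainty with
moving-average convergence, linear response-surface surrogates
(`CoG/g = β₀ + β_T·T + β_Y·ΔY`, fitted by OLS with per-coefficient t-tests),
and an overlap analysis of the two processes' cost ranges.

## Worked example

```r
library(biocogs)

cfg <- uricase_config()            # packaged flowsheets, costing, scenarios
fs  <- uricase_flowsheets(cfg)
cm  <- uricase_costing(cfg, "atps")

cog_per_gram(fs$atps, cm)
#> <cog_result> atps: $5452.00/g (100.2 batches, 800 g/yr)
#> # A tibble: 5 × 4
#>   category    annual_cost per_gram share
#>   <chr>             <dbl>    <dbl> <dbl>
#> 1 capital         1439328    1799.  0.33
#> 2 materials        741472     927.  0.17
#> 3 consumables      436160     545.  0.1
#> 4 labor            567008     709.  0.13
#> 5 other           1177632    1472.  0.27
```

The base ATPS gram costs $5,452, of which 13% is labor. Sensitivity spans
rank the cost drivers:

```r
run_scenarios(fs$atps, cm) |> tornado_rank()
#> # A tibble: 4 × 5
#>   variable       cog_best cog_base cog_worst  span
#>   <chr>             <dbl>    <dbl>     <dbl> <dbl>
#> 1 titer             5215.     5452     5797.  583.
#> 2 dsp_yield         5258.     5452     5715.  457.
#> 3 material_cost     5284.     5452     5620.  336.
#> 4 labor_location    5650.     5452     5400.  250.
```

Titer dominates the ATPS tornado (for the chromatographic flowsheet the
order flips and DSP yield leads); materials outrank labor because ATPS
consumes its phase-forming chemicals by the hundred kilograms. Propagating
both top drivers jointly:

```r
mc <- run_monte_carlo(fs$atps, cm, uricase_distributions(cfg), seed = 1)
glance(mc)
#> # A tibble: 1 × 9
#>   process n_runs  seed converged_at n_rejected  mean    sd   min   max
#> 1 atps      1000     1           52          0 5468.  149. 5111. 5966.

s <- uricase_surrogates()          # published slopes, recentred at base
overlap_analysis(s$chromatography, s$atps, uricase_distributions(cfg))
#> <overlap_result> overlap $5278-$7328/g: top 25.0% of the first range,
#>   bottom 54.5% of the second (support bounds)
```

The running mean stabilises (0.5% over a 50-run window) after 52 runs here;
the two cost distributions overlap between ~$5,280 and ~$7,330/g, meaning
chromatography competes only in the cheapest quarter of its attainable range
while ATPS can be beaten in the dearest half of its own.

A thin command-line wrapper over the same functions ships in
`inst/cli/biocogs`:

```sh
Rscript inst/cli/biocogs all --seed 1 --out results/
```

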