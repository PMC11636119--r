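# sandstab

Community stability and diversity analysis for shrub-driven restoration
of sandy land.

Planted shrubs build "fertile islands" on mobile sand: organic matter
and nitrogen accumulate under the canopy, and over decades a herbaceous
community assembles around them. Restoration monitoring on a
chronosequence (sites restored 0, 13, 25 and 45 years ago, with mobile
sand as the control) needs three quantitative blocks, all implemented
here for ecologists working with quadrat survey tables:

* **Importance values & alpha diversity** — per-stratum species
  importance values
  `Iv = (relative height + relative coverage + relative density) / 3`
  and the Margalef `R = (S−1)/ln N`, Simpson `D = 1 − Σ Pᵢ²`,
  Shannon–Wiener `H = −Σ Pᵢ ln Pᵢ` and Pielou `E = H/ln S` indices.
* **Coverage-based Godron stability** — species are ranked by coverage,
  the cumulative percentage of species is plotted against cumulative
  relative coverage, a least-squares polynomial is fitted and
  intersected with the anti-diagonal `y = 100 − x`; the Euclidean
  distance of the intersection from the 20/80 stability point `(20, 80)`
  scores the stratum, with `√(10² + 10²) = 14.142` as the (inclusive)
  stability threshold.
* **Soil chronosequence summaries** — stratified means/SDs of pH, SOM,
  AN and TP by age, depth layer and canopy position, and percent change
  versus the unrestored control, `100·(T − C)/C`.

A seeded synthetic-data generator (`synth_config()`,
`generate_dataset()`) emulates the statistical structure of such a
survey — richness rising 3→21 with age, geometric rank-abundance with
decaying dominance, under-crown contrasts that close with age, SOM/AN
enrichment factors 3.5008/5.4243 at 45 years — so the full pipeline is
testable without field data.

## Worked example

Assess a 21-species stratum calibrated so its fitted cumulative curve
crosses the anti-diagonal at the stability point `(29.88, 70.12)`:

```r
library(sandstab)
a <- assess_stability(shares_for_stability_point(29.88, 21),
                      paper_compat = TRUE)
a
#> <stability_assessment> [paper_compat]
#> <godron_fit> y = -0.005469x^2 + 1.136x + 41.04  (R^2 = 1)
#>   intersection: (29.88, 70.12)
#>   distance to (20, 80): 13.97  [threshold 14.142]
#>   verdict: stable
```

The distance 13.97 is `√2·|29.88 − 20|` after the 2-decimal rounding
convention of published stability tables (`paper_compat = TRUE`); it is
below the 14.142 threshold, so the stratum is classified stable.

Run the whole pipeline on a synthetic chronosequence:

```r
d <- synth_dataset(synth_config(seed = 1))
res <- restoration_analysis(d)
res$stability[c("restoration_years", "position", "S", "x_star",
                "distance", "stable")]
#>   restoration_years      position  S x_star distance stable
#> 1                 0   under_crown  3  40.73    29.31  FALSE
#> 2                 0 outside_crown  3  42.83    32.28  FALSE
#> 3                13   under_crown 11  33.07    18.48  FALSE
#> 4                13 outside_crown 12  32.46    17.62  FALSE
#> 5                25   under_crown 15  31.51    16.28  FALSE
#> 6                25 outside_crown 16  30.52    14.88  FALSE
#> 7                45   under_crown 21  30.60    14.99  FALSE
#> 8                45 outside_crown 21  31.19    15.83  FALSE
```

Distances shrink from ~30 on bare sand toward the 14.142 threshold
after 45 years: the community converges on — but at this seed does not
yet reach — the stable 20/80 configuration, and the under/outside-crown
gap closes with age. Soil recovery at 45 years versus the control:

```r
subset(res$soil, variable %in% c("SOM", "AN") & restoration_years == 45)
#>    restoration_years variable    mean      sd  n pct_change_vs_control
#> 14                45      SOM  8.5531  2.8921 27                273.52
#> 15                45       AN 67.7003 14.6283 27                435.90
```

i.e. SOM and AN about 274 % and 436 % above the control in this
realisation (the generator's expected enrichments are +250.08 % and
+442.43 %). `write_results(res, "out/")` writes the four tables as CSV.

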