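# connectogrip

Linking structural brain connectivity to distinct aspects of hand grip
performance in hemiparetic cohorts.

Stroke survivors differ in *which* aspect of hand function is impaired:
grip strength, the speed of initiating or releasing a grip, or the
control of fingertip force magnitude and direction. `connectogrip`
implements an analysis pipeline for testing whether these aspects map
onto the structural connectivity of distinct sensorimotor brain
networks:

1. **Grip performance** — from three-axis thumb/index force recordings
   (500 Hz), extract five measures: peak strength; reaction time (first
   sustained crossing of the baseline mean + 3 SD after the grip cue);
   relaxation time (return to within 3 SD after the rest cue);
   magnitude error `|4 N − mean hold force|`; and direction error
   `atan2(√(Ft1² + Ft2²), Fn)` in degrees. Each is normalized as
   paretic / (paretic + nonparetic).
2. **Connectome construction** — symmetrize directed tractography
   streamline counts, `s = (n(i→j) + n(j→i)) / 2`, and correct for
   geometry: `w = s · d^α / (v_i + v_j)^β` with distance `d`,
   region volumes `v`, defaults α = β = 1, over a 20-region
   sensorimotor set (bilateral precentral, Rolandic, postcentral, SMA,
   putamen, caudate, pallidum, thalamus, plus CST and CRP at medulla
   and midbrain).
3. **Two-level factor analysis** — per region, factor the 19 incident
   edges across participants; then factor the pooled region factors to
   obtain latent networks (principal components, Kaiser retention,
   varimax, regression scores with a pseudoinverse so the n < p
   clinical regime works). Networks project back to edges via
   dominant-path composite weights, reported at |w| ≥ 0.4, top 6.
4. **Association** — per (network, measure) cell, standardized OLS of
   the measure on the network score controlling for that network's
   lesion load (membership- and volume-weighted percent lesion
   volume); reports partial r, beta ± SE, VIFs, and the best network
   per measure with and without lesion adjustment.

A seeded synthetic-cohort generator (`cohort_spec()`,
`generate_cohort()`) plants latent networks in streamline counts,
couples the five measures and lesion profiles to them, and synthesizes
force traces whose extracted metrics equal the planted values — so the
entire pipeline is testable against known ground truth without any
clinical data. See the methods vignette
(`vignettes/connectogrip-methods.Rmd`) for the model details and
design decisions.

## Worked example

A full in-memory analysis of a default synthetic cohort (22
participants, the scale this kind of clinical study runs at):

```r
library(connectogrip)
library(dplyr)

spec   <- cohort_spec(seed = 42)            # 22 participants, 3 planted networks
cohort <- generate_cohort(spec, trials = FALSE)

mats  <- lapply(cohort$counts, build_connectome,
                distances = cohort$distances, regions = spec$regions)
edges <- assemble_edge_table(mats, spec$regions)
model <- two_level_model(edges, spec$regions)
model
#> <two_level_model> 21 networks from 135 pooled region factors
#>   20 regions, 22 participants, first-level k: 5-8

netdefs     <- network_definitions(model)
lesion_load <- purrr::map_dfr(model$networks, function(g)
  network_lesion_percent(cohort$lesions,
                         filter(netdefs, network == g), spec$regions))
assoc <- association_table(network_scores(model), cohort$measures,
                           lesion_load)
assoc
#> <association_table> 21 networks x 5 measures
#>   best calls consistent with/without lesion adjustment: FALSE
#> # A tibble: 5 × 3
#>   measure          network_adjusted network_unadjusted
#>   <chr>            <chr>            <chr>
#> 1 ratio_direction  N9               N9
#> 2 ratio_magnitude  N3               N2
#> 3 ratio_reaction   N14              N14
#> 4 ratio_relaxation N21              N21
#> 5 ratio_strength   N12              N10
```

Each measure is assigned the network whose score has the largest
lesion-adjusted |partial r| with it. At n = 22, Kaiser retention keeps
many sampling-noise factors alongside the real ones (21 "networks"
here — see the vignette's caution on the eigenvalue > 1 rule), which
is why planted-versus-recovered comparisons below use factor matching
by Tucker congruence rather than the retained count. The edges that
define a network are its reported composite weights:

```r
filter(netdefs, network == "N9", reported)
#> # A tibble: 6 × 6
#>   network edge                            region_a          region_b       weight reported
#>   <chr>   <chr>                           <chr>             <chr>           <dbl> <lgl>
#> 1 N9      precentral_contra--sma_contra   precentral_contra sma_contra      0.520 TRUE
#> 2 N9      precentral_contra--caudate_ipsi precentral_contra caudate_ipsi   -0.534 TRUE
#> 3 N9      precentral_contra--cst_midbrain precentral_contra cst_midbrain    0.821 TRUE
#> ...
```

The staged file-based pipeline (`run_pipeline()`) does the same from a
directory of trial CSVs, count TSVs and lesion tables, writing every
intermediate plus a JSON run report; `write_cohort()` /
`generate_cohort(spec, dir)` produce that layout for synthetic data.

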