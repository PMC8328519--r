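# gistbias

Analysis pipeline for spatial-reconstruction memory experiments that probe
**item memory** (the encoded location of each landmark) and **gist memory**
(the spatial centre of the whole set) across retention intervals from a day
to months. Designed for behavioural researchers studying memory
consolidation, ensemble/summary-statistic memory, and reconstructive
retrieval, the package answers the question these paradigms are built
around: as item memories fade, does the remembered gist start to pull item
retrievals toward itself?

## What it computes

**Error metrics and chance baselines.** For each participant-session, item
error (mean distance of each retrieved landmark from its encoded location),
gist error (distance of the explicitly reported centre from the true
centroid), and estimated-centre error (distance of the retrieved items'
centroid from the true centroid). All distances are Minkowski,
d(a, b) = (|a₁−b₁|ᵍ + |a₂−b₂|ᵍ)^(1/g), with g = 2 (Euclidean) by default
and g = 1.5 available to model warped stimulus space. Chance baselines are
derived from the layout geometry alone (screen-centre clicking strategies).

**Gist-based bias.** For each retrieved item,

```
bias = (d(encoded, centre) − d(retrieved, centre)) / d(encoded, retrieved)
```

a signed, error-normalised index in [−1, 1]: +1 means the retrieval moved
straight toward the reference centre, −1 straight away. Four reference
centres are supported: the participant's reported centre, the encoded
centroid, an accuracy-weighted centroid (weights (1 − eᵢ/Σe)/(n−1)), and
the local centre excluding a designated spatial outlier.

**Monte Carlo null models.** Because purely random retrieval error produces
negative bias on its own, observed bias is compared against two
participant-matched simulations that preserve each item's observed error
magnitude exactly: *item-only* (Sim-I, uniform retrieval direction) and
*item-plus-gist* (Sim-G, direction probabilities over 200 candidate angles
decreasing with distance to the centre, Pᵢ = (dᵢ − max d)/Σ(dⱼ − max d)).
The quantities observed − Sim-I and Sim-G − observed are the evidence for a
separate gist representation guiding item retrieval.

**Outlier weight.** For designs with one spatial outlier, a weighted-centroid
grid model (81 weights, 0 to 1 in steps of 0.0125) estimates how strongly
the outlier contributed to each reported centre, against the equal-weight
benchmark 1/n.

**Preprocessing.** Misbinding (swap) detection/correction via a
four-condition criterion, and participant exclusion rules (gist out of
scope, 3-SD performance screen, misplaced outlier).

**Synthetic cohorts.** A seeded generator emulates the study structure —
including layout calibration that reconstructs encoded coordinates matching
published chance distances — so the full pipeline runs with no external
data.

## Worked example

Calibrate the six-item layout, simulate the 130-participant three-group
cohort, and run the full pipeline:

```r
library(gistbias)

preset <- load_preset("exp1")
layout <- preset_layout(preset, seed = 1)
chance_baselines(layout)
#> <chance_baselines> item vs screen centre 348.0 px, item vs encoded centre 267.0 px,
#>   gist vs screen centre 270.0 px

cohort <- generate_cohort(layout, preset$params)
cfg <- run_config("exp1", null = null_config(n_simulations = 1000), seed = 1)
res <- run_analysis(cohort, cfg)

res$exclusions
#> <exclusion_report> 128 retained, 2 excluded
#>   three_sd: P069, P109

dplyr::summarise(res$gaps,
  observed = round(mean(observed_bias), 3),
  sim_item_only = round(mean(sim_item_only), 3),
  gap = round(mean(gap_item_only), 3),
  p_gap = signif(stats::t.test(gap_item_only, alternative = "greater")$p.value, 2),
  .by = c(delay_group, session))
#> # A tibble: 6 × 6
#>   delay_group session observed sim_item_only    gap       p_gap
#>   <chr>       <chr>      <dbl>         <dbl>  <dbl>       <dbl>
#> 1 24h         S1        -0.113        -0.054 -0.06  0.91
#> 2 24h         S2        -0.07         -0.061 -0.009 0.61
#> 3 1week       S1        -0.091        -0.053 -0.037 0.81
#> 4 1week       S2         0.013        -0.072  0.085 0.025
#> 5 1month      S1         0.007        -0.053  0.061 0.066
#> 6 1month      S2         0.236        -0.08   0.316 0.000000096
```

Reading the table: observed bias alone is negative everywhere at Session 1 —
that is the error-magnitude artifact, which the item-only simulation (also
negative) reproduces. What carries meaning is the *gap*: near zero wherever
the generator applied no gist pull, and strongly positive at the long delay,
where item retrievals were pulled toward the centre. `res$errors`,
`res$error_changes`, `res$bias`, and (for outlier designs)
`res$outlier_weights` hold the remaining tidy tables; `write_analysis(res,
dir)` exports everything as CSV plus a JSON config sidecar.

## Package layout

- `R/` — geometry primitives, layout/cohort data model and CSV/JSON I/O,
  error and bias metrics, null models, outlier-weight grid model, layout
  calibration, synthetic-cohort generator, pipeline orchestration.
- `vignettes/gist-memory-analysis.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations.
- `inst/extdata/` — the two shipped study presets (JSON).
- `tests/testthat/` — unit, property, and acceptance-level suites.
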