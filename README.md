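# oleagin

Comparative physiology of oleaginous yeasts, as a tested R pipeline:
growth kinetics from OD600 time series, GC-FID fatty-acid quantification
by internal standard, lipid content and composition as percent of cell
dry weight (CDW), lipid-accumulation classification, and categorical
substrate-assimilation summaries. It is written for microbial
physiologists characterising lipid storage across strains — the
motivating system is the *Yarrowia* clade, whose nine species differ
widely in how much lipid they store (roughly 30 to 67 % of CDW on oleic
acid) and in how accumulation evolves over the growth phase.

Every stage has a seeded synthetic counterpart (growth curves,
chromatograms, full strain scenarios), so the whole chain is verifiable
offline against known ground truth.

## The methods in brief

**Growth parameters.** From a series of OD600 readings, `growth_fit()`
estimates the maximum specific growth rate as the largest sliding-window
least-squares slope of ln(OD),

    mu_max = max over windows of slope( t, ln OD ),  window = 5 points

the lag phase λ by the tangent construction (intersection of that
maximum-slope tangent with the baseline ln OD level), the maximum cell
density from the median-smoothed curve, and the generation time as
ln(2)/µmax. It returns a classed model object with `print`, `coef`,
`predict`, `plot`, `residuals` and `simulate` methods.
`select_timepoints()` then finds the three physiological sampling
states: the times of 1/5 × ODmax, 1/2 × ODmax and ODmax.

**FAME quantification.** `detect_peaks()` baseline-corrects a
chromatogram (rolling minimum + mean), finds prominence-filtered peaks
and integrates them by trapezoid; `assign_peaks()` matches them to a
retention-time library; `quantify_fames()` applies the
internal-standard rule with the 75 µg C17:0 spike:

    mass_i = area_i / area_IS × 75 µg / RF_i
    lipid content (% CDW) = Σ mass_i / aliquot CDW × 100

**Classification.** `classify_pattern()` labels the three-point lipid
trajectory (`accumulate_then_mobilize`, `continuous_increase`,
`decline`, `stable`, at 10 % relative tolerance), `call_oleaginous()`
applies the >20 %-of-CDW threshold, and `major_compound()` reports the
dominant fatty acid (with 1 % ties). `summarize_substrates()` partitions
carbon sources into universal / unused / variable across strains, with
halo and toxicity helpers for drop-test data.

## Worked example

Simulate the fastest oleic-acid grower of the clade (µmax 0.34 h⁻¹, OD
max 53.1), fit its growth curve, pick the sampling states, and quantify
the mid-trajectory chromatogram of a scenario peaking at 67.1 % CDW:

```r
library(oleagin)

cfg <- growth_sim_config("YAHI", "oleic", mu_true = 0.34,
                         od_max_true = 53.1, noise_sd = 0.02, seed = 42)
series <- simulate_growth_curve(cfg)
(fit <- growth_fit(series))
#> Growth fit: YAHI on oleic
#>   mu_max  0.347 h^-1   (window 2-4 h, R2 0.9965)
#>   lag     absent
#>   OD max  53.2
#>   gen. time 2 h

select_timepoints(series, fit)
#>   timepoint target_od    time_h    od_at
#> 1     fifth  10.63199  9.453452 10.63199
#> 2      half  26.57998 13.679063 26.57998
#> 3       max  52.09676 23.825243 52.09676

sc <- scenario_config(cfg, pct_cdw = c(25, 67.1, 45))
bundle <- simulate_scenario(sc)
analyze_chromatogram(bundle$samples[[2]]$chromatogram)
#> FAME quantification 'YAHI_oleic_half': 5 compound(s)
#>            mass_ug mg_per_g_cdw fraction
#> C16:0       201.30        40.26     0.06
#> C16:1(n-7)  402.59        80.52     0.12
#> C18:0       100.65        20.13     0.03
#> C18:1(n-9) 2549.76       509.95     0.76
#> C18:2(n-6)  100.65        20.13     0.03
#> total lipid: 67.1% of CDW
```

The fit recovers the configured growth rate within ~2 % despite 2 % OD
noise, reports the lag as absent (oleic-acid cultures start growing
immediately), and the quantification recovers the configured 67.1 %
lipid content from the raw trace. `run_pipeline(clade_scenarios())`
chains these stages for all nine strains on both media and writes
growth-parameter, time-point, trajectory and composition TSVs plus a
manifest of every setting used.

A thin command-line wrapper ships in `inst/cli/oleagin.R` with
subcommands `simulate`, `growth-fit`, `quantify`, `lipid-report` and
`phenotype-summarize`.

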