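# isoniche

Individual dietary specialization from serially sampled tooth-enamel carbon
isotopes.

## The problem

Is a herbivore species with a broad dietary niche built from broad individual
generalists, or from many narrow individual specialists that subdivide the
niche? Serial samples of enamel drilled along a tooth's growth axis record an
individual's d13C — and hence its C3 browse vs C4 grass intake at low
latitudes — over the months-to-years of tooth mineralization. Comparing each
individual's d13C range with its species' total range answers the question
directly, for extant and fossil mammals alike.

`isoniche` is for isotope paleoecologists and ecologists working with such
serial d13C profiles. Its core statistic is the **isotopic individuality
index**

    III = (average individual d13C range of a taxon) / (total d13C range of the taxon)

III near 0: individuals are specialists relative to the species niche; III
near 1: every individual spans the species niche. Around it the package
implements the full analysis chain:

- reading/validating flat serial-sample tables (`read_isoserial`,
  `validate_isoserial`) and the standard inclusion filters: at least *k*
  serial samples on a tooth (`filter_min_samples`), absolute latitude below a
  cutoff (`filter_latitude`), body-size classes (`body_size_category`);
- per-individual summaries, species niche tables, III per diet, 1-permil
  range bins (`individual_summaries`, `species_niche`, `mean_iii_by_diet`,
  `bin_individual_ranges`);
- five-sample moving-window standardization of the samples-per-tooth bias
  (`tooth_windows`, `standardized_ranges`);
- nested variance partitioning — between species, between individuals within
  species, within individuals — by unbalanced method-of-moments ANOVA and by
  REML (`nested_varcomp`);
- Kruskal–Wallis and Dunn's post hoc comparisons across diet or body-size
  groups (`kruskal_wallis`, `dunn_test`, `range_group_table`);
- a hierarchical synthetic-data generator with specialist/generalist presets
  (`sim_params`, `simulate_isoserial`, `scenario_params`);
- one-call orchestration of the scope × filter analysis grid
  (`run_full_analysis`, `write_results`), plus a thin CLI at
  `inst/scripts/isoniche.R`.

## Worked example

A synthetic population of individual specialists — strong between-individual
differences, small within-individual variation — run through the pipeline:

```r
library(isoniche)

sim  <- simulate_isoserial(scenario_params("specialist", seed = 42))
x    <- filter_min_samples(sim$samples, 3)
niche <- species_niche(x, quiet = TRUE)

mean_iii_by_diet(niche)
#>           diet   mean_iii     sd_iii n_species
#> 1      browser 0.12352799 0.06105387         4
#> 2       grazer 0.12127433 0.01605833         4
#> 3 mixed_feeder 0.08095083 0.01336135         4

s <- individual_summaries(x)
prop_range_at_most(s$range, 3)
#> [1] 1

nested_varcomp(x, method = "mom", min_tooth_samples = 5)
#> Nested variance components (mom)
#>   design: 12 species, 96 individuals, 768 serial samples
#>                     species individual within
#> variance (permil^2) 36.3762     5.0321 0.0618
#> proportion           0.8772     0.1213 0.0015
```

Every diet's mean III sits near 0.1 — individuals occupy about a tenth of
their species' isotopic niche — and all 96 individuals have ranges at or
below 3 permil, the classic signature of individual specialization. The
variance partition says the same thing at a different angle: almost nothing
of the total d13C variance (0.15%) lies within individuals. (The species
share here also absorbs the browser/grazer/mixed-feeder mean differences;
recovery studies of the σ² components themselves use a single diet.) Group
comparisons come from `range_group_table(s, by = "diet")`, which prints the
per-diet mean/sd/n of individual ranges with the Kruskal–Wallis H and Dunn's
pairwise z and p-values.

Swap in `scenario_params("generalist", ...)` — no between-individual effect,
a seasonal sinusoid sweeping each profile across the niche — and the same
pipeline returns mean III around 0.9.

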