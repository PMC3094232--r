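# armdyn

Arm-specific dynamics of chromosome rearrangement in malaria mosquitoes.

Comparative physical mapping of polytene chromosomes in *Anopheles
gambiae*, *An. funestus* and *An. stephensi* raises two statistical
questions that this package answers from ordered marker maps alone:

1. **Do polymorphic inversions of different species capture the same
   genes nonrandomly?** For homologous arm pairs with `N` shared
   homologous markers, the expected count co-located in region pair
   `(i, j)` under uniform placement is `E_ij = N f_i f_j` (with `f` the
   fractional region length). The test statistic
   `T = Σ (O_ij − E_ij)² / E_ij` over inversion pairs gets both an
   asymptotic chi-squared p-value and a Monte-Carlo p-value from uniform
   repositioning of every homolog pair. A Bayesian hierarchical binomial
   model then estimates per-pair sharing intensities
   `γ_ij = λ_i^(1) λ_j^(2) + μ_ij` — a product of per-region marginal
   intensities plus a point-mass/hot/cold mixture random effect — giving
   hotspot probabilities `Pr(γ_ij > 1 | data)` and the outside/inside
   connectivity ratio.
2. **Do chromosome arms differ in their tolerance to gene-order
   disruption?** Conserved blocks (maximal colinear, distance-conserved
   marker runs, classified fully vs partially conserved across three
   species) are modelled by a compound Poisson process: block count
   `N(L) ~ Poisson(λL)`, arm-scaled block lengths `b/L ~ Exp(γ)`, with
   conjugate Gamma posteriors. Differencing the fully conserved and
   conserved+disrupted fits yields per-arm disruption rates and the
   summary `z = λ^(diff) γ^(diff) / L` (*blocks per region length per
   total length*), compared across arms by posterior rank probabilities.

A first-class synthetic-data module generates marker maps with planted
sharing intensities and three-lineage rearranged gene orders, so the
whole pipeline is testable without physical-mapping data.

## Worked example

Generate a two-species arm pair at the study conditions (230 shared
markers, realistic inversion layouts) with a six-fold hotspot planted on
the largest inversion pair, then test and model it:

```r
library(armdyn)

hot <- data.frame(region1 = "j", region2 = "g", gamma = 6)
sc  <- study_sharing_scenario(n_homologs = 230, gamma = hot, seed = 42)
d   <- gen_shared_markers(sc)

st <- sharing_test(d$markers1, d$markers2, d$regions1, d$regions2,
                   n_draws = 10000, seed = 1)
st
#> Sharing test: gambiae_like 2R vs stephensi_like 2R
#>   N = 230 shared homologs over 20 inversion pairs
#>   T = 112.007 (df = 20)
#>   asymptotic p = 8.444e-15
#>   simulated  p = < 0.0001 (10000 draws)
```

None of the 10,000 repositioning draws reaches the observed statistic:
marker sharing between these inversion systems is decisively nonrandom.
The intensity model locates the excess and quantifies it:

```r
cnt <- count_shared(d$markers1, d$markers2, d$regions1, d$regions2)
fit <- fit_intensity_model(cnt, burnin = 20000, samples = 20000,
                           chains = 4, seed = 2)
dplyr::arrange(tidy(fit), dplyr::desc(pr_hot))[1:3, ]
#>   region1 region2     O     E estimate conf.low conf.high pr_hot
#> 1 j       g          29  5.95     4.89    3.33       6.65  1
#> 2 b       outside    19 17.7      1.30    0.912      1.75  0.927
#> 3 b       g           7  3.90     1.24    0.722      1.94  0.773

connectivity_ratio(fit)
#>   estimate conf.low conf.high
#> 1    0.886    0.721      1.07
```

The planted pair `(j, g)` is recovered as a hotspot with posterior mean
intensity 4.9 (the planted 6, deflated by the generator's normalisation)
and `Pr(γ > 1) = 1`; all other pairs sit near chance level.
`plot_sharing_heatmap(fit)` renders the intensity map (light = excess,
dark = deficit). For the disruption side:

```r
trio <- gen_rearranged_orders(87, c(12, 12, 12), spacing_mb = 0.7, seed = 7)
cl <- classify_blocks(find_pairwise_blocks(trio$spA, trio$spB),
                      find_pairwise_blocks(trio$spA, trio$spC),
                      find_pairwise_blocks(trio$spB, trio$spC))
block_stats(cl, 60.9)
#>   set   n_blocks total_length_mb mean_length_mb arm_length_mb
#> 1 c           24           24.5           1.02           60.9
#> 2 d            9            6.30          0.700          60.9
#> 3 c+d         33           30.8           0.933          60.9
```

24 blocks survive in all three lineages and 9 more in only a pair; the
~1-Mb mean block length reflects 12 reversals per lineage on an 87-marker
arm. `fit_block_process()` + `disruption_difference()` +
`rank_disruption()` turn such tables into per-arm disruption rates, and
`run_pipeline()` drives the whole chain (counting → test → intensity →
blocks → rates) from one configuration, in code or YAML
(`inst/extdata/synthetic_config.yaml` is a complete example over the
bundled synthetic fixture tables).

## Package layout

* `R/io_maps.R` — marker/region table readers and writers, validation,
  shared-count construction.
* `R/synthetic.R` — scenario builders and generators (marker sharing,
  rearranged orders, block lengths), fixture materialisation.
* `R/sharing_test.R` — expected counts, discrepancy statistic, asymptotic
  and Monte-Carlo p-values.
* `R/intensity_model.R` + `src/intensity_mcmc.cpp` — the hierarchical
  binomial intensity model and its Metropolis-within-Gibbs sampler.
* `R/block_finder.R` — pairwise block detection and three-species
  classification.
* `R/block_rates.R` — conjugate compound-Poisson fits, disruption
  differences, rank probabilities.
* `R/pipeline.R`, `R/plots.R` — orchestration, JSON reports, heat maps
  and density figures.

The methods vignette (`vignettes/armdyn-methods.Rmd`) documents the
models, priors, sampler, tolerances and the generator's assumptions.
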