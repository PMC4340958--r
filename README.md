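# mirffl

Stochastic modelling and cytometry noise analytics for microRNA-mediated
buffering of gene-expression variability.

When a T cell is activated, the surface protein CD69 is induced together
with microRNAs (miR-17/miR-20a of the miR-17-92 cluster) that repress the
*Cd69* mRNA — an **incoherent feed-forward loop** (FFL): a common upstream
signal drives both the target and a repressor of the target. Because the
repressor tracks the same upstream fluctuations as the target, the loop is
predicted to reduce not only the mean of target protein expression but also
its **cell-to-cell variability**, measured as the coefficient of variation
(CV = 100 × SD/mean). `mirffl` is for systems biologists who want to
simulate such circuits exactly, and for cytometrists who want the noise
statistics used to analyse single-cell fluorescence distributions.

The package provides:

* an exact Gillespie (direct-method) simulator for small reaction networks
  with mass-action and Hill-modulated propensities
  (`reaction_network()`, `simulate_ssa()`, `simulate_endpoint_ensemble()`),
  with a compiled core so 10,000-cell ensembles run in seconds;
* builders for two microRNA FFL variants — translational repression, where
  protein synthesis per mRNA is scaled by `1/(1 + (miRNA/K)^2)`, and
  microRNA-directed mRNA degradation through an explicit miRNA:mRNA
  complex (`build_translational_ffl()`, `build_degradation_ffl()`) — plus a
  copy-number-calibrated CD69 instance (`calibrate_cd69_model()`) and
  scenario runners comparing activation with and without the microRNA arm
  (`run_scenario()`, `compare_ffl_effect()`);
* copy-number estimation arithmetic for qPCR and small-RNA cloning data
  (`copies_from_reference_ratio()`, `copies_from_cloning_frequency()`,
  `delta_ct_normalize()`);
* synthetic flow-cytometry event generators with known ground truth
  (`generate_population()`, `generate_paired_channels()`,
  `generate_mixture()`, `generate_dual_reporter()`);
* cytometry noise statistics: `cv()`, the ratio-based technical-noise
  bound for obligate heterodimers (`technical_noise_bound()`),
  peak-channel skew, the law-of-total-variance mixture CV, and
  computational unmixing curves (`unmix_cv_curve()`);
* dual-fluorescence reporter quantification by orthogonal (total least
  squares) regression (`gate_double_positive()`, `orthogonal_fit()`,
  `normalize_to_empty()`, `derepression_ratio()`).

Everything takes and returns tidy tables; fitted objects support
`tidy()`, `glance()` and `autoplot()`.

## Worked example: does the microRNA arm buffer CD69 expression?

Simulate the activated circuit at its published rate constants, with the
microRNA arm intact and with microRNA production held at its resting
level:

```r
library(mirffl)

params <- translational_ffl_params()
with_ffl    <- run_scenario(params, "activated_with_ffl",
                            n_runs = 2000, base_seed = 1)
without_ffl <- run_scenario(params, "activated_without_ffl",
                            n_runs = 2000, base_seed = 2)
with_ffl
#> <scenario_result> activated_with_ffl (translational variant)
#>   protein mean 883.8, CV 10.31%  (2000 runs to t = 5000, seed 1)
without_ffl
#> <scenario_result> activated_without_ffl (translational variant)
#>   protein mean 1315.0, CV 14.90%  (2000 runs to t = 5000, seed 2)

compare_ffl_effect(with_ffl, without_ffl, n_boot = 2000, seed = 1)
#> <ffl_comparison> with-FFL minus without-FFL
#>   delta mean -431.2, delta CV -4.60 points (boot SE 0.298), p = 0.001
```

Co-induction of the microRNA lowers both the mean (884 versus 1315 protein
copies) and the CV (10.3% versus 14.9%) of target expression; the
bootstrap p-value is at the floor attainable with 2000 resamples. The CV
drop is the noise-buffering signature: the microRNA absorbs part of the
fluctuation in upstream activator levels before it reaches the protein.

The copy-number arithmetic behind the CD69-calibrated model:

```r
copies_from_reference_ratio(25000, 215)   # Cd69 mRNA per activated cell
#> [1] 5.375
copies_from_cloning_frequency(1465, 89884, c(400, 800))  # miR-17 per cell
#> # A tibble: 1 × 2
#>     low  high
#>   <dbl> <dbl>
#> 1  6.52  13.0
```

End-to-end report bundles (scenario histograms, summary tables, noise and
reporter suites) are produced by `run_ffl_experiment()`,
`run_noise_suite()` and `run_reporter_suite()`, each driven by a config
list or YAML file and fully reproducible from its base seed.

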