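# cytofuse

Multimodal particle classification for microfluidic impedance cytometry
with simultaneous high-speed imaging.

## The problem

Label-free single-particle analysis in a microfluidic channel can watch a
transit two ways at once: a high-speed camera sees the particle's size,
and a multi-frequency lock-in measurement sees the impedance perturbation
it causes between a pair of electrodes. Either feature alone classifies
imperfectly — the impedance pulse height is volume-coupled but noisy and
drifts between devices and days, while camera sizing is resolution-limited
(one pixel is about 0.2 µm). cytofuse implements the full analysis chain
that fuses both, for particles spanning polystyrene calibration beads
(2–6 µm) to tumour cells (15–17 µm):

- **optical**: rolling 50-frame background, absolute difference image,
  threshold segmentation, centroid, radial intensity profile, diameter from
  the outer half-maximum crossing, sphere volume `V = (4/3) pi r^3`
  (aggregates: sum of component volumes), transit velocity;
- **electrical**: baseline normalization `(Z - Z0)/Z0` with a rolling
  median, prominence-based transit-peak calling, per-frequency peak
  intensity (PI) at 100 kHz – 1.75 MHz;
- **fusion**: nearest-in-time event matching, feature tables (PI at one or
  all eight frequencies, VOL, optional VEL), the `log10(PI) ~ log10(VOL)`
  validation regression per frequency;
- **classification**: a "fine tree" (CART, Gini, at most 100 splits) with
  stratified 5-fold cross-validation, evaluated on independent test runs
  with one-vs-rest accuracy / sensitivity (TPR) / specificity (TNR) /
  fallout (FPR) / false-negative rate (FNR) and full confusion matrices;
- **synthetic acquisition**: a seeded generator producing co-registered
  frame stacks, impedance traces and ground truth with the statistical
  structure the pipeline assumes (quantized optics, volume-proportional
  pulses with calibrated log-normal noise, run-level gain drift, baseline
  drift, aggregates), since raw bench recordings of this kind are not
  publicly available.

See `vignettes/multimodal-pipeline.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

Simulate a run, extract both modalities, fuse, validate the
volume-impedance power law, then run the modality-comparison experiment:

```r
library(cytofuse)

run <- generate_run(params = sim_params(n_events_per_class = 30, seed = 11))
optical    <- extract_optical_events(run)
electrical <- detect_peaks(normalize_trace(run$trace))
fused      <- fuse_events(optical, electrical, truth = run$truth)

regress_all_frequencies(fused)
#> # A tibble: 8 x 5
#>   frequency_hz slope intercept r_squared     n
#>          <dbl> <dbl>     <dbl>     <dbl> <int>
#> 1       100000 0.982     -4.18     0.875   116
#> 2       250000 0.959     -4.12     0.890   116
#> 3       500000 0.987     -4.17     0.883   116
#> 4       750000 0.975     -4.12     0.874   116
#> 5      1000000 0.999     -4.14     0.888   116
#> 6      1250000 0.986     -4.10     0.883   116
#> 7      1500000 0.959     -4.04     0.875   116
#> 8      1750000 0.983     -4.09     0.885   116
```

Each row is the ordinary least-squares fit of log10 peak intensity on
log10 volume at one frequency: the slope recovers the generator's unit
power-law exponent, and R² in the high 0.8s says the two modalities
measure the same underlying volume through very different noise.

```r
ex <- run_modality_experiment(seed = 1)
ex[ex$frequency_set == "all", c("mode", "n_train", "n_test", "cv_acc", "test_acc")]
#> # A tibble: 3 x 5
#>   mode       n_train n_test cv_acc test_acc
#>   <chr>        <int>  <int>  <dbl>    <dbl>
#> 1 electrical     225     75  0.734    0.68
#> 2 optical        225     75  0.934    0.893
#> 3 multimodal     225     75  0.934    0.893
```

On a held-out run generated with its own gain drift, the electrical-only
classifier degrades hardest, the optical classifier holds up, and the
fused classifier matches or beats it — the modality ordering the pipeline
exists to demonstrate. `autoplot(ex)` draws the accuracy bars;
`autoplot(ex$eval_test[[1]])` the confusion heat map.

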