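# polycolo

Quantitative imaging and physiology computations for studying
polycystin-1 (PC-1) / polycystin-2 (PC-2) plasma-membrane clusters in
endothelial cells — and, more generally, for any two-color
single-molecule localization microscopy (SMLM) experiment that asks
whether two surface proteins form colocalized clusters.

The scientific chain the package implements:

* **Localization**: Thompson localization precision
  `sigma^2 = (s^2 + q^2/12)/N + 8*pi*s^4*b^2/(q^2*N^2)`, pixel-integrated
  Gaussian spot fitting (iteratively reweighted least squares),
  early-frame exclusion, and cross-correlation drift correction.
* **Clustering**: rendering, watershed segmentation with
  Gaussian-mixture refinement, precision-corrected cluster areas, and
  maximum-likelihood exponential fits of cluster size.
* **Colocalization**: nearest-neighbor intercentroid distances,
  footprint overlap fractions, a Costes-style randomization null with
  empirical p-values, and Pearson/Manders pixel coefficients.
* **FRET**: sensitized-emission normalized FRET (Xia method),
  `N-FRET = (I_DA - d*I_DD - a*I_AA)/sqrt(I_DD*I_AA)`, with
  bleed-through calibration from single-labeled controls.
* **Physiology**: patch-clamp summary metrics (transient peak against
  a pre-flow baseline, >= 45 s steady-state averages, current density)
  and myography formulas (myogenic tone `100*(1 - Da/Dp)`, Poiseuille
  flow for a target wall shear stress).
* **Synthetic data**: generators for every input — two-channel cluster
  localization tables with ground truth, blinking-emitter camera
  frames, three-channel FRET image sets, and biphasic flow-response
  current traces — so the whole pipeline is testable without external
  data.

A methods vignette (`vignettes/polycystin-cluster-colocalization.Rmd`)
describes the models, estimator choices and their limitations.

## Worked example

Simulate a 5 x 5 um two-channel data set at the default study
conditions (2 clusters/um^2, exponential areas with means 3702.5 and
2157.1 nm^2, 27% colocalized fraction, 27 nm precision), segment both
channels and test colocalization:

```r
library(polycolo)
rep <- run_pipeline(list(
  seed = 7,
  sim = list(roi_width_nm = 5000, roi_height_nm = 5000),
  coloc = list(n_iter = 500)))
print(rep)
#> Pipeline run (seed 7)
#>   simulate: 53 + 46 clusters, 12 colocalized pairs
#>   cluster ch1: 53 clusters, 2.12 /um^2
#>   cluster ch2: 45 clusters, 1.80 /um^2
#>   coloc: NN mean 263.1 nm; overlap 22.6% vs null 1.54% (p = 0.001996)
```

The report reads: segmentation recovered the generated cluster counts
(53/53 and 45/46); 22.6% of channel-1 clusters overlap a channel-2
cluster, against a chance level of 1.5% when channel-2 clusters are
randomly repositioned — the built-in colocalization is detected at
p ≈ 0.002, mirroring the experimental-versus-randomized contrast the
method is designed to quantify.

Single formulas are one call each:

```r
thompson_precision(s = 130, q = 100, n_photons = 500, b = 2)
#> [1] 6.852133
myogenic_tone(d_active = 200, d_passive = 250)
#> [1] 20
flow_for_shear(15, 150)          # dyn/cm^2, um -> ul/min
#> [1] 42.60084
```

And the patch-clamp metrics recover the generator's biphasic flow
response (baseline -5.5 pA/pF, transient -1.3 pA/pF, sustained shift
+4.53 pA/pF) from a noisy trace:

```r
tr <- simulate_current_trace(trace_sim_config(noise_sd_pa_pf = 0.05,
                                              seed = 1))
transient_peak(tr)
#> [1] -1.349922
steady_state_current(tr, 100, 45) - steady_state_current(tr, 10, 45)
#> [1] 4.529317
```

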