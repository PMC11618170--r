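# grasptwist

Simulation-based comparison of the two sequence families used for
time-resolved contrast-enhanced MR angiography (CE-trMRA) of the aorta:

* **TWIST-style Cartesian view sharing** — the central 25% of phase-encode
  lines is re-acquired every frame while the periphery is cycled through
  three interleaved subsets, so each frame borrows two-thirds of its
  periphery from earlier frames;
* **GRASP-style golden-angle radial** — spokes advance by 111.24611° per
  repetition and 13 consecutive spokes form one frame, reconstructed by
  density-compensated Kaiser–Bessel gridding.

Clinical comparisons of these sequences have no ground truth. This package
replaces the patient with a dynamic digital phantom — three aorta-like
vessel cross-sections (ascending, descending, abdominal) enhancing along
staggered gamma-variate boluses
g(t) = ((t−t₀)/tₚ)^α · exp(α(1 − (t−t₀)/tₚ)),
under rigid sinusoidal respiratory motion and Gaussian noise — and samples
its *continuous* k-space line-by-line and spoke-by-spoke, so motion and
enhancement during a frame corrupt the data exactly as on a scanner. On the
reconstructed series it computes the standard image-quality metrics:

* **vessel sharpness** vs = 1/d, with d the 20–80% intensity rise distance
  across the vessel wall;
* **bolus FWHM** and **maximum upslope** of the smoothed, 10×-interpolated,
  min–max-normalised ROI time curve;
* **subtraction SNR**, with noise estimated as sd(frame₃ − frame₂)/√2 from
  two pre-bolus frames;
* background **streak energy**, plus **paired t-tests** and **Fleiss'
  kappa** for reader-score tables.

## Worked example

Simulate one free-breathing subject and acquire it with both schemes on the
identical continuous scene:

```r
library(grasptwist)

cfg <- study_subject_config(101)   # seeded subject: bolus + motion jitter
res <- compare_schemes(cfg)

res$twist
#>   roi fwhm_s maxslope_per_s vs_per_mm d_mm  snr peak_frame
#> 1  AA   10.4          0.211     0.190 5.26 90.8          9
#> 2  DA   12.1          0.191     0.205 4.89 57.0         11
#> 3 AbA   13.9          0.171     0.213 4.69 36.9         12
res$grasp
#>   roi fwhm_s maxslope_per_s vs_per_mm d_mm  snr peak_frame
#> 1  AA   10.5          0.212     0.247 4.04 39.7         10
#> 2  DA   11.8          0.212     0.239 4.18 25.7         11
#> 3 AbA   13.8          0.183     0.279 3.58 34.7         13
res$streak
#>  twist  grasp
#> 0.0006 0.0112
```

Reading the numbers: the radial reconstruction depicts every vessel wall
more sharply (vs 0.24–0.28 /mm versus 0.19–0.21 /mm, i.e. a 20–80% rise of
~4 mm versus ~5 mm) — the Cartesian scheme blurs under the 2.7 mm
respiratory motion and its coarser phase-encode resolution — while its
background streak energy is ~19× higher, the signature artefact of
13-spoke undersampling. Bolus timing metrics are similar between schemes
(both measure FWHM within a few percent of the phantom's ground truth of
10.2/11.6/13.1 s), and the Cartesian series has the higher SNR, as
expected for a plain gridding reconstruction without the clinical
compressed-sensing denoising.

The full seeded cohort with paired statistics:

```r
study <- run_study(n_subjects = 10, seed = 1)
study
#> scheme_study: 10 subjects (seed 1)
#>   radial sharper at all ROIs: 9/10 subjects
#>   Cartesian FWHM <= radial:   7/10 subjects
#>   median |maxslope rel diff|: 5.0%
#>   radial streak energy higher: 10/10 subjects
study$comparison   # per-ROI, per-metric means, SDs and paired t-tests
```

Reader-score agreement uses the same machinery as clinical studies:

```r
scores <- data.frame(subject = rep(1:6, 3), reader = rep(1:3, each = 6),
                     score = sample(1:4, 18, TRUE))
fleiss_kappa(rating_table_from_scores(scores))
```

## Scope notes

The reconstruction is deliberately transparent: view-shared inverse FFT and
density-compensated gridding, not the vendor's compressed-sensing
reconstruction (whose regularisation is unpublished). Consequences — the
radial series' lower SNR here, and the partial reproduction of the
clinical FWHM ordering — are analysed in the methods vignette
(`vignettes/methods.Rmd`), together with the phantom model, estimator
design choices, numerical tolerances and known limitations.
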