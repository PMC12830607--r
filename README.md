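# epimorph

Observer-independent morphometry of corneal epithelial thickness profiles
for limbal stem cell deficiency (LSCD) models.

## The problem

In LSCD models the injured cornea is traditionally graded by eye. The damage
signature, however, is not a uniform change in epithelial thickness but
localized "hot spots" of extreme thinning and thickening along the section.
epimorph quantifies that signature with a small set of distribution-shape
statistics computed on per-eye epithelial thickness profiles — ordered
thickness measurements along the arc length of a histological section —
plus compartment cell densities and longitudinal OCT pachymetry, and
compares injured (right) against healthy control (left) eyes with paired
t-tests.

For a profile standardized to z-scores per animal
(z = (t − μ)/σ, population SD pooled over both of the animal's eyes):

* **Ra** = mean |z − z̄| — arithmetic mean roughness;
* **Rz** = max z − min z — maximum height of the profile (plain max–min,
  not the ISO five-peak variant), the metric most sensitive to hot spots;
* **rolling SD** — sample SD in windows of 5 consecutive measurements (µm);
* **skewness** — bias-uncorrected g1 = m3/m2^(3/2);
* **σ-exceedance** — fraction of measurements with |z| > 1, 2, 3.

A seeded synthetic-data generator (smooth baseline wander + i.i.d. noise +
Gaussian hot spots in study eyes; labeled histology rasters with Poisson
nuclei; OCT swelling curves) makes the whole pipeline testable end to end
without any study data. Thickness profiles can also be extracted directly
from labeled rasters by measuring along basal-contour normals.

## Worked example

```r
library(epimorph)

co   <- generate_cohort(cohort_spec(seed = 42))   # 4 study + 4 control eyes
summ <- summarize_cohort(co$measurements)          # one metric row per eye
tab  <- build_table(summ, measurements = co$measurements)
tab[tab$metric == "Maximum Height of Profile (Rz)", ]
```

```
                               metric study_mean study_sd control_mean control_sd   test  p_value
       Maximum Height of Profile (Rz)     6.0485   0.4116       2.9087     0.3252 paired 7.25e-04
```

The injured eyes' standardized profile range (Rz ≈ 6.0) clearly exceeds the
healthy eyes' (Rz ≈ 2.9): the injected hot spots create extreme standardized
values that the paired test detects across the four animals (p < 0.001),
while a mean-only comparison would miss most of the structure (the
"Epithelium thickness (avg of avgs)" row differs by only ~2 µm).

Longitudinal OCT on the same synthetic conditions:

```r
oc <- generate_oct_series(oct_spec(seed = 42))
find_peak(oc, "central")
#> <oct_peak> central: peak 1470 um at day 8 (baseline 908 um), residual fraction 0.188
paired_test_vs_baseline(oc, 8, "central")
#>   region day n mean_diff_um statistic  p_value stars
#>  central   8 4        561.9      49.6 1.81e-05   ***
```

Swelling peaks at day 8 and by day 28 only ~19 % of the peak excess remains
unresolved — thickness approaches but does not reach baseline.

The whole chain (simulate → extract → morphometry → cellularity → oct →
report) also runs as a pipeline that writes its resolved config, seed, log
and artifacts into one directory:

```r
run_pipeline("all", pipeline_config(outdir = "run1", seed = 42))
```

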