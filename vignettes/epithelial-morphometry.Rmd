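---
title: "Observer-independent morphometry of corneal epithelial thickness profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer-independent morphometry of corneal epithelial thickness profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimorph)
```

## Motivation

Limbal stem cell deficiency (LSCD) destroys the stem cell niches at the
corneal limbus and leaves the cornea unable to renew its epithelium. In
animal models of LSCD, healing is traditionally graded by eye — fluorescein
photographs, semi-quantitative histology scores — which is slow and observer
dependent. epimorph implements a quantitative alternative: the injured and
healthy cornea are compared through a small set of roughness and
heterogeneity statistics computed on *epithelial thickness profiles*,
ordered sequences of thickness measurements taken along a histological
section, plus compartment cell densities and longitudinal OCT pachymetry.
The damaged epithelium is not uniformly thicker or thinner than a healthy
one; its hallmark is localized "hot spots" of extreme thinning and
thickening. Metrics sensitive to the *shape* of the thickness distribution,
not only its mean, are therefore the core of the package.

## The thickness-profile model and its metrics

A profile for one eye is the concatenation, in slide order, of per-slide
measurement series: thickness $t_i$ (µm) at arc-length positions $x_i$.
Metrics are computed per eye as follows.

**Standardization.** Thickness is converted to z-scores,
$z_i = (t_i - \mu)/\sigma$, with $\mu$ and $\sigma$ (population SD,
divisor $n$) computed over a configurable *scope*. The default scope is
`per_animal`: both eye series of one animal are pooled to estimate
$\mu, \sigma$, which are then applied to each eye. This removes
between-animal baseline differences while letting an irregular study eye
widen that animal's scale — which compresses the healthy eye's standardized
range below what per-eye standardization would give, and is exactly what
makes the standardized range a sensitive irregularity contrast. A
`per_eye` scope is available for sensitivity analysis. A zero scale yields
all-zero z-scores rather than NaN.

**Roughness.** On the standardized profile,

* $R_a = \mathrm{mean}\,|z_i - \bar z|$ — arithmetic mean roughness,
  the mean absolute deviation; for reference, i.i.d. standard normal
  z-values give $E|Z| = \sqrt{2/\pi} \approx 0.798$;
* $R_z = \max z_i - \min z_i$ — maximum height of the profile. This is
  deliberately the plain max–min definition, not the ISO five-peak $R_z$;
  it is the metric most sensitive to isolated hot spots. $R_z \ge R_a$
  always.

**Rolling SD.** The sample SD (divisor $n-1$) in every full window of five
consecutive measurements along the linearized contour, summarized by its
mean, in µm. It indexes *local* variability and is nearly blind to smooth,
long-wavelength thickness drift. By default windows run across slide
boundaries (the linearized contour); `break_at_slides = TRUE` keeps them
within slides.

**Skewness.** The bias-uncorrected Fisher–Pearson moment coefficient
$g_1 = m_3 / m_2^{3/2}$ on the raw thicknesses. Thickening hot spots on a
stable baseline push $g_1$ positive. Zero variance yields NA.

**σ-exceedance.** The fraction of measurements with $|z_i| > k$ for
$k = 1, 2, 3$ — a direct "hot spot burden". For Gaussian data these are
31.7 %, 4.55 % and 0.27 %.

The two SD conventions are intentional and configurable: z-scores use the
population SD (the usual z-score convention), the rolling SD uses the
sample SD (the usual windowed-variability convention).

**Smoothing** (centered moving average, odd window, shrunken at the edges)
is applied for *visualization only*. Computing the metrics on smoothed
profiles would attenuate precisely the localized extremes the analysis is
after; a `smooth_window` flag in `summarize_eye()` exists for sensitivity
checks.

## Group comparison

`build_table()` produces one row per metric. All per-eye metrics are
compared with a two-sided paired t-test matching the right (study) and left
(control) eye of each animal. The pooled "avg total" thickness row instead
treats individual measurements as units and uses an unpaired pooled-variance
t-test (Welch optional): with several hundred measurements per group this
row has far more power for a mean shift, but it ignores the within-eye
correlation structure — which is why the per-eye "avg of avgs" row, with
animals as units, is reported alongside it. Raw p-values are reported
without multiplicity correction, one row per metric; a study using this
table for confirmatory claims should correct externally.

Degenerate inputs (zero-variance differences, two constant groups) are
flagged rather than raising errors, so a whole table never dies on one
pathological row.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated. One eye profile is

$$ t(x) = b + w(x) + \varepsilon(x) + \sum_j a_j
   \exp\!\left(-\frac{(x - c_j)^2}{2 s_j^2}\right) $$

* $b$: animal baseline, `baseline_mean_um` 77.7 µm with a between-animal SD
  of 4 µm — healthy porcine epithelium scale;
* $w(x)$: a smooth long-wavelength "wander", a single-period cosine with
  random phase scaled to SD `wander_sd_um` 13 µm. Real sections are
  autocorrelated: thickness drifts slowly along the section while staying
  locally smooth. Pure i.i.d. noise would make the standardized range of a
  ~200-point profile concentrate near 5.5 regardless of the noise SD,
  leaving no room for an injury contrast; the smooth wander keeps the
  healthy standardized range near 3, matching the observed healthy-eye
  scale;
* $\varepsilon(x)$: i.i.d. Gaussian measurement noise, SD 4.4 µm, chosen so
  the control rolling SD lands at the healthy-eye scale (~4.4 µm);
* hot spots (study eyes only): four Gaussian bumps, amplitudes
  +50/−40/+40/−30 µm, width (SD) 150 µm, centers uniform on the middle 80 %
  of the section. Amplitudes were set from the healthy-vs-injured min/max
  thickness scales (injured eyes reaching ≈ 35 µm minima and ≈ 130 µm
  maxima around an ≈ 80 µm baseline); widths make bumps span a handful of
  the 25 µm-spaced measurements, i.e. genuinely local.

Profiles are clipped at a 5 µm floor (positivity; a profile entirely at the
floor is a generation error), split into two slide strips with arc length
restarting per slide, and sample counts are drawn per eye (means 180 study /
203 control, SD 20, floor 30). All defaults were frozen from these scale
arguments before the validation suite was written and are not tuned to test
outcomes.

What the generator does *not* emulate: staining variability, section folds
and tears, nucleus-level epithelial stratification, spatially varying noise,
or any optical properties of real slides. Passing tests therefore
demonstrate that the *analysis chain* is correct and sensitive under the
assumed statistical structure — not that the metrics are robust to every
histological artifact.

The histology-raster generator imprints a prescribed per-column thickness as
an epithelium band over stroma (flat or circular-arc basal contour, clipped
to the arc's lateral span) and scatters nuclei as disks by a homogeneous
Poisson process in one compartment, rejecting positions whose disk would
overlap another nucleus or cross the compartment border (with a warned
fallback when packing is infeasible). The OCT generator rises from the
day −1 baseline as $b + e\,((d+1)/(p+1))^2$ to the peak excess
$e = (\text{multiplier}-1)\,b$ at peak day $p$, then declines linearly so
that by day 28 only `recovery_fraction` (default 0.8) of the excess has
resolved — swelling that approaches but never reaches baseline, peaking
later centrally than limbally.

## Thickness extraction from labeled rasters

`extract_basal_contour()` takes the epithelium/stroma interface as the
lower edge of the (single) large epithelium component, one point per image
column, ordered by arc length; components under `min_component_px` are
discarded, and two or more large components abort with their sizes (a
folded section should be fixed upstream, not silently traced).

`measure_thickness()` honors corneal curvature by measuring along the local
*basal normal*, not image columns: tangents come from symmetric secants of
half-width `normal_window_um` (symmetric secants are parallel to the true
tangent on circular arcs and average out pixelation; near the contour ends
the window shrinks, falling back to a short asymmetric secant). Rays are
marched in 0.25 px steps with midpoint sampling — this makes the recovered
thickness of an axis-aligned band *exact* — and thickness is the length of
the contiguous epithelium run from the interface, so keratinized surface
irregularities at the outer edge stay included while anything beyond a
break is excluded. Rays leaving the image while still inside epithelium
produce *missing* samples, never truncated zeros, because zeros would
corrupt every roughness statistic. At the truncated lateral ends of an arc
section the tissue genuinely ends and rays exit through the cut; accuracy
guarantees apply away from the ends (the validation uses a two-band-width
margin).

These geometric conventions (0-based physical coordinates, pixel (r, c)
spanning ((r−1)s, rs] × ((c−1)s, cs], thickness from the interface) are the
single source of unit handling, all in the I/O module.

## Cellularity

Nuclei are connected components of the nucleus label (minimum area 4 px),
assigned to the compartment of the tissue nearest their centroid; density is
count / compartment area, in cells/mm² (areas include the compartment's own
nucleus pixels, since nucleus disks overwrite the tissue label when
rasterized). Touching nuclei are not split — no watershed — which is exact
for the generator's non-overlapping placement and a known undercount risk on
real H&E material.

## OCT analysis

`percent_of_baseline()` expresses each series relative to its own day −1
value (the baseline maps to exactly 100 %), `paired_test_vs_baseline()`
runs the per-day two-sided paired t-test across animals with star
annotations at 0.05/0.01/0.001, and `find_peak()` takes the argmax of the
across-animal mean curve over post-injury days (ties toward the earlier
day; boundary peaks flagged) and reports the residual fraction
$(t_{28} - b)/(t_{\text{peak}} - b)$. No correction across days is applied,
mirroring per-day reporting practice; the result carries that note as an
attribute. The module is agnostic about which corneal layer the series
quantifies — it analyses the thickness field it is given, and reports
should label the layer explicitly.

## Numerical and design choices

* Population vs sample SD as above; both documented, both testable.
* Rz is computed per eye on the concatenated slides by default; per-slide
  computation with averaging is available through per-slide summaries, as
  the appropriate grouping for a given dataset is an empirical question.
* Rolling SD is on raw µm by default (an SD of ~4–9 µm is interpretable on
  tissue scale); standardized input is accepted wherever a profile is.
* Missing samples are dropped, never imputed.
* Tie-break for multiple ray crossings: farthest contiguous epithelium
  pixel (see above).
* The pipeline runner writes the resolved YAML config, the seed and a log
  next to every artifact; reruns with equal config and seed are
  byte-identical, which the test suite asserts.

## Validation scale

The test suite validates every metric against independent naive
reimplementations on 1,000 random profiles (relative tolerance 1e-9),
checks the analytic Gaussian expectations of Ra and the exceedance
fractions on 10⁵ draws, verifies extraction exactness on flat bands and
±1 px accuracy on arc bands, and estimates the study-vs-control Rz
separation power and the null rejection rate over 200 seeded cohorts each
(paired t, n = 4 animals, α = 0.05). These sizes keep the full suite in the
minutes range on a single core while leaving Monte-Carlo error well inside
the asserted margins. `scripts/acceptance.R` recomputes the same quantities
end-to-end from a fresh seed.

## Limitations

* Real slide exports vary in column naming and structure; the reader's
  column map handles renaming, not structural differences (e.g. wide
  formats).
* The reproduction of a published evaluation table requires the study's raw
  measurement export; without it, validation rests on the synthetic
  conditions described above.
* No watershed splitting of touching nuclei; no stain-based detection on
  RGB H&E; no B-scan segmentation — inputs are already-labeled rasters and
  tabulated thicknesses.
* With four animals per group, paired t-tests on heavy-tailed per-eye
  statistics (Rz is a range) are only approximately calibrated; the suite
  checks the empirical null rate stays near nominal under the generator's
  conditions.
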