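---
title: "Image-based JC-1 screening of mitochondrial membrane potential: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based JC-1 screening of mitochondrial membrane potential: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

JC-1 is a lipophilic cationic dye that accumulates in polarized
mitochondria, where it forms red-emitting J-aggregates; at low membrane
potential it stays a green-emitting monomer. The red/green (Cy3/FITC)
fluorescence ratio therefore indexes mitochondrial health, and its decline
under exposure to an uncoupler such as CCCP or 2,4-dinitrophenol is a
sublethal toxicity endpoint for *Daphnia magna* that responds at lower
concentrations than the classical immobilization test.

`jc1screen` implements the full analysis chain for a multiwell-plate
screen of this endpoint:

1. **Segmentation** (`segment_organism()`): each transmitted-light image
   is Gaussian-smoothed (default sigma 2 px), the well background is
   estimated as the median of an 8 px border band, and pixels whose
   absolute deviation from the background exceeds an Otsu-derived
   threshold are classified as organism. Morphological closing (disc
   radius 3 px), hole filling and a minimum-area filter (500 px at the
   4x geometry, which rejects small extra-organismal dye aggregates)
   clean the mask. Connected components are labelled with
   8-connectivity. The segment count is reported *before* any component
   selection: a count other than 1 flags the layer as incorrect rather
   than being repaired, because a well is only interpretable when it
   contains exactly one organism.
2. **Quantification** (`masked_channel_means()`): the mask is applied to
   the Cy3 and FITC images of the same z-level. Mask pixels whose Cy3
   intensity reaches 65000 on the 16-bit scale are excluded from *both*
   channel means (paired exclusion preserves the ratio's pairing;
   whole-image exclusion is recovered automatically when every pixel
   saturates). FITC saturation does not trigger exclusion by default —
   only the Cy3 channel is thresholded — but a configuration flag is
   provided.
3. **QC and aggregation** (`aggregate_individual()`): the per-organism
   ratio is the arithmetic mean over correct z-levels of a 10-level
   stack (15 um spacing). An individual is excluded when *more than*
   50% of its layers are incorrect; exactly 50% is kept. A layer counts
   as incorrect when its segment count is not 1 or its ratio is
   undefined for any reason (zero usable area, zero FITC mean). When at
   most half the layers fail, the average is taken over the correct
   layers only; averaging over all layers is not possible because failed
   layers have no defined ratio.
4. **Normalization and modelling** (`normalize_to_control()`,
   `fit_ll4()`, `fit_ll2()`, `ec_x()`): ratios are divided by the mean
   ratio of the QC-passing M7 medium controls of the same experiment and
   timepoint, replicate means are formed per (experiment,
   concentration), and the constrained log-logistic models below are
   fitted.

## The concentration-response models

Both families use the `(b, c, d, e)` parameterization

$$f(x) = c + \frac{d - c}{1 + \exp\!\big(b(\ln x - \ln e)\big)}$$

with `e > 0` the inflection concentration and `b` the slope. This is the
convention in which the constraint language of the protocol is natural:

* **Immobilization (LL2)**: lower and upper limits fixed to 0 and 1.
  Counts of immobile animals are modelled as
  `Binomial(n, f(x))` and fitted by maximum likelihood rather than least
  squares on fractions: group sizes are 5–20 animals and whole plateaus
  of 0/n or n/n are common, which ML handles gracefully. A
  least-squares mode is available for sensitivity checks. The
  covariance of `(b, e)` is the inverse observed information at the
  optimum, computed on `(b, ln e)` and mapped back by the delta method.
* **JC-1 ratio (LL4)**: fitted to normalized replicate means by least
  squares with the lower limit `c` *fixed* to the dead-control floor —
  the mean normalized ratio of non-viable reference organisms
  (`dead_control_floor()`). The floor is applied on the normalized
  scale because fitting happens after normalization. `b`, `d` and `e`
  are free; the covariance is the residual variance times the inverse
  Gauss-Newton curvature.

Initialization follows the response direction: the initial inflection is
the concentration whose response lies nearest the midpoint, the slope
sign follows the correlation between response and log concentration, and
up to three perturbed restarts are tried. If Levenberg–Marquardt fails
from every start, a direct simplex search provides estimates flagged
`converged = FALSE` unless the curvature is usable. Zero-dose control
points are retained in the LL4 fit; the response at `x = 0` is the
asymptote the slope sign implies, so they anchor the upper limit.

**Effect concentrations** use the relative definition —
`EC_p` is the concentration at which the response has moved `p`% of the
`d − c` span from the zero-dose asymptote toward the asymptote at high
concentration:

$$\mathrm{EC}_p = e \cdot \left(\frac{p}{100 - p}\right)^{1/|b|},$$

which makes `EC_50 = e` identically. The default 95% confidence interval
is a delta-method interval on the *original* concentration scale. This
choice deliberately reproduces the behavior of published screens in
which poorly determined fits report negative lower bounds; a log-scale
delta interval and a parametric bootstrap (`ci_method = "delta_log"`,
`"bootstrap"`) are provided when strictly positive intervals are wanted.
At the default design (3 replicate means at 7 concentrations, noise sd
0.05) the empirical coverage of the EC50 interval is in the low-to-mid
90s percent, verified by simulation in the test suite.

Control groups are compared (`compare_controls()`) with a Shapiro–Wilk
normality check on each group followed by Welch's t-test when both pass
at alpha = 0.05 and a Wilcoxon rank-sum test otherwise; constant groups
are routed to the rank-sum branch. No multiple-testing correction is
applied anywhere: endpoints are compared by confidence-interval overlap,
which the fit report exposes as a flag.

## The synthetic plate generator

Raw instrument images for this assay are generally not publicly
deposited, so validation rests on a generator whose ground truth is
analytic (`simulation_truth()`, `phantom_params()`,
`generate_well_stack()`, `generate_plate()`).

The phantom organism is a two-ellipse body-and-head composite with thin
antenna strokes — not anatomically faithful; segmentation only needs a
contiguous object of realistic scale (about 3000 px footprint at the
default 160x160 px geometry). The transmitted-light channel is a bright
background with a darker silhouette; FITC carries a uniform diffuse
signal on the silhouette; Cy3 carries punctate signal (Gaussian spots,
resampled per z-level, attenuated toward the body center to echo the
loss of translucency in deeper tissue) whose silhouette mean is rescaled
exactly so that the red/green ratio of every z-level equals
`control_ratio` times the generating LL4 curve at the well's dose. In
the noise-free, artifact-free limit the pipeline therefore reproduces
each well's intended ratio to floating-point accuracy, and fitted EC
values equal the generating ones.

Noise is Gaussian read noise plus shot noise (a Gaussian approximation
of Poisson noise with sd equal to the square root of the intensity, the
standard fluorescence camera model). Artifacts are injected per well
with configurable probabilities: saturated Cy3 patches (intensity
65535), bright aggregates outside the silhouette (below the minimum
component area, so the size filter removes them), empty wells, and
double occupancy (two parallel, disjoint organisms, which yields segment
count 2 at every level and a QC exclusion).

Default design parameters mirror the reference study: 7–8
concentrations per compound (e.g. CCCP at 0.5–2500 ug/L), five
individuals per concentration, three independent experiments, 10
z-levels, Cy3 saturation at 65000, and a dead-control floor of 0.2 on
the normalized scale. The per-individual ratio noise default (sd 0.05)
matches the replicate-mean scatter used throughout the validation
simulations.

What the generator does *not* emulate — optical sectioning and PSF
blur, anatomical detail, instrument-specific intensity scales,
organism movement between channels — bounds what passing tests show:
they demonstrate that the pipeline's rules are implemented exactly and
that parameter recovery holds under a plausible noise model, not that
the segmentation would match any particular instrument's vendor module
on real images.

## Numerical choices and degenerate inputs

* A constant (zero-contrast) transmitted-light image yields an empty
  mask and segment count 0, not an exception; the same applies when the
  Otsu split lies within the border band's noise floor (5 times its
  median absolute deviation), which is what makes genuinely empty wells
  come out as segment count 0 rather than noise blobs.
* All-saturated masks give undefined means and force the layer
  incorrect. Zero FITC means give an undefined ratio and do likewise.
* Immobilization data that are all-zero or all-one are rejected as
  non-identifiable; a layout without QC-passing medium controls stops
  normalization with the experiment named; a missing dead-control group
  is an error instructing the caller to set `jc1_floor` explicitly.
* Likelihood probabilities are clamped to `[1e-12, 1 - 1e-12]`, so
  boundary counts at extreme doses do not produce infinite deviance.
* Connected components use 8-connectivity (implemented in C++), chosen
  as the blob-labelling convention and documented so that segment
  counts are reproducible.
* The measurement CSVs round-trip all numerics at full double
  precision; the plate-image naming convention is
  `<well>_z<k>_<channel>.tif` with 1-based z and channels TL/CY3/FITC.
* 8-bit TIFF inputs are linearly rescaled to the 16-bit range (with a
  warning) before thresholding, because the 65000 saturation rule is
  defined on the 16-bit scale.
* Treatment rows with concentration 0 are accepted with a warning and
  never pooled into the control group, so a layout edit cannot silently
  reclassify a well.

## Problem sizes used in the validation suite

The test suite regenerates everything from code at fixed seeds: the
end-to-end recovery uses a full plate of 3 experiments x 8
concentrations x 5 individuals plus control, solvent-control and
dead-control groups (165 stacks of 10 z-levels at 160x160 px) and
requires the fitted EC50 to land within 15% of the generating value;
parameter-recovery checks use 200 replicate fits per scenario; interval
coverage uses 500 simulated datasets. Image-based unit tests use
4-level stacks of the same geometry.

## Known limitations

* The vendor segmentation algorithm that inspired the
  brightness-difference rule is unpublished; equivalence on real
  images cannot be verified, only functional adequacy on phantoms.
* The LL2 maximum-likelihood estimator's *median* EC50 can sit well
  below the truth when the true value falls inside a wide gap of a
  steep concentration series (boundary counts at the flanking doses
  reward steeper slopes, and the single informative dose drags the
  estimate toward itself). This is a property of the design, not the
  optimizer — the same code recovers truths located near a design
  concentration to well under 1%. Dense, well-placed concentration
  series matter more than the fitting machinery.
* Delta-method intervals on the original scale are symmetric and can
  extend below zero for weakly identified fits; that is intentional
  (see above), and the log-scale or bootstrap intervals are the remedy
  when positivity is required.
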