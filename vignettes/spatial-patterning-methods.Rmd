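---
title: "Quantifying spatial patterning in bilayered embryo-like aggregates"
author: "belapol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial patterning in bilayered embryo-like aggregates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belapol)
```

## The problem

Stem-cell aggregates that recapitulate the peri-implantation mouse embryo —
an epiblast-like (Epi) core wrapped in a visceral-endoderm-like (VE) layer,
separated by a laminin-rich basement membrane — break symmetry when a subset
of VE cells differentiates into anterior visceral endoderm (AVE) on one side
of the structure, and when a mesoderm-marker domain (T/Bra) appears in the
Epi. The analytical question is not *whether* a reporter is expressed but
*whether its expression domain is spatially asymmetric*, and if so, how two
domains are oriented relative to each other. belapol implements that
analysis for 2D optical sections, from segmented-nucleus input through a
permutation-calibrated classification, together with a clonal-composition
analysis of marker-positive cell nests in 2D culture and a synthetic-data
generator that makes every stage testable with known ground truth.

## The polarization statistic

For one compartment (Epi or VE) of one Z-slice, let $r_i$ be the nucleus
centroids, $c$ their unweighted centroid, and $w_i \ge 0$ the per-nucleus
median intensity of a channel after rescaling. The domain's polarization
vector and its size-normalized magnitude are

$$
P \;=\; \frac{\sum_i w_i (r_i - c)}{\sum_i w_i},
\qquad
p \;=\; \frac{\lVert P \rVert}{R_{\mathrm{gyr}}^{\,e}},
\qquad
R_{\mathrm{gyr}} = \sqrt{\tfrac{1}{n}\sum_i \lVert r_i - c\rVert^2 }.
$$

Two choices here were genuinely open and are worth stating:

* **The centroid is unweighted.** With an intensity-weighted center the
  statistic of a uniformly expressing compartment would not vanish; with the
  unweighted centroid, uniform weights give $P = (0,0)$ *exactly*, which is
  the natural null anchor and is asserted in the tests.
* **The normalization exponent** `norm_exponent` defaults to 1, making $p$
  dimensionless and invariant to rescaling all positions; exponent 2
  (units 1/µm) is also implemented because the normalization power is a
  documented point of ambiguity in this family of measures. The choice is
  immaterial for classification: observed and shuffled statistics share the
  same $R_{\mathrm{gyr}}$, so the percentile verdict is provably identical
  under either exponent (also asserted).

Each channel is evaluated only over the nuclei of its own compartment
(AVE reporter over VE, mesoderm marker over Epi), with compartments assigned
by centroid containment against the basement-membrane ("Laminin-ring") and
outer contours.

## Preprocessing

From a label mask plus intensity channels, `extract_nucleus_table()`
measures centroid, area, circularity $4\pi A/P^2$ and per-channel median
intensity per nucleus. The perimeter is the marching-squares contour length
of the label at level 0.5 after averaging the binary indicator over a 3×3
neighborhood: contouring the raw binary mask follows the pixel staircase
and overestimates a disc's perimeter by roughly 8%, pushing its circularity
to ~0.84, whereas the smoothed level set interpolates the boundary
sub-pixel and returns circularity 0.98–1.03 for rendered discs. Circularity
may slightly exceed 1 for small labels; values are accepted up to 1.1 as
rasterization tolerance.

Size and circularity filters (`filter_nuclei()`) remove under- and
over-segmentations and debris. No universal thresholds exist; the defaults
(area 40–400 µm², circularity ≥ 0.5) suit mouse ESC nuclei of ~8 µm
diameter, are configurable, and are echoed into every report so no result
is detached from the filter that produced it.

Intensities are rescaled per slice and per channel by the maximum
per-nucleus median (`rescale_intensities()`), mapping the brightest nucleus
to exactly 1. The per-slice scope reflects that each slice is an
independent acquisition; pooling slices of one aggregate is available via
`scope = "aggregate"` but mixes acquisitions and is not the default. A
channel with an all-zero maximum is zeroed with a warning rather than
producing NaNs.

## The shuffle null and the polarized call

The null hypothesis is "no spatial organization of expression": shuffling
the measured intensities across the fixed nucleus positions
(`permutation_null()`) preserves the geometry and the intensity multiset
while destroying any domain. With `n_perm` draws (default 100), a structure
is called polarized when its observed $p$ strictly exceeds the null
magnitude in at least 95% of draws (`classify_polarized()`, threshold
configurable). Ties count against the call, which guarantees that a
degenerate all-equal-intensity slice — whose observed statistic and entire
null are exactly zero — is never flagged.

Because the observed statistic is exchangeable with the null draws under
the null hypothesis, the exact false-positive level of the ≥95% rule with
$B$ draws is $(0.05B + 1)/(B + 1)$: 0.059 at $B = 100$, approaching 0.05 as
$B$ grows. The package's calibration checks therefore run the rule at
$B = 500$ (level 0.052) over 500 synthetic null slices and verify the
flagged fraction lands in the exact binomial 99% interval around 0.05;
the reporting default stays at 100 draws. The null mean magnitude is also
reported for every test, since comparing the observation to the *average*
shuffled vector is a plausible alternative reading of this family of
methods; the percentile criterion is what classifies.

Aggregates are imaged as two independent Z-slices 15 µm apart.
How two per-slice verdicts combine into one per-aggregate call is not
canonical, so `combine_slices()` makes the rule explicit: `any` (default,
most sensitive), `all` (most stringent), or `mean_vector`, which averages
the slices' normalized observed vectors and re-tests against the per-draw
average of their null vectors.

## Relative orientation of two domains

`angle_between()` reports the unsigned angle in $[0, 180]$ between two
domains' polarization vectors; a signed angle would require a fixed
anatomical frame that aggregates lack. Angles from slices where either
vector is undefined are flagged, not silently zeroed, and angles from
non-polarized structures are retained but labelled so the polarized and
non-polarized groups can be summarized separately. `orientation_summary()`
adds a Monte-Carlo uniformity check: under independent random orientations
the inter-domain angle is uniform on $[0, 180]$, so the observed
Kolmogorov–Smirnov distance from that law is compared with simulated
same-size samples; no named circular-statistics test is invoked because the
scientific claim being checked is only presence/absence of a preferred
relative orientation. Per-aggregate summaries of per-slice angles use an
axial circular median (`circular_median_axial()`) so near-0°/near-180°
mixtures do not average to 90°.

## Nests and clonality

In homogeneous 2D VE-like cultures, AVE-reporter-positive cells appear in
spatial clusters ("nests"). Two generating mechanisms are distinguishable
with mixed clonal labels: clonal expansion of single founders (nests
monoclonal) versus local signaling neighborhoods (nest labels drawn from
the culture's label mix). The pipeline operationalizes the readout:

* `flag_positive()` thresholds the rescaled intensity (default 0.3,
  boundary inclusive);
* `detect_nests()` takes fixed-radius connected components (default link
  distance 25 µm ≈ two cell diameters, minimum size 3) — the simplest rule
  consistent with "spatially clustered", chosen because nests are otherwise
  scored by eye;
* `clonality_score()` reports monoclonal / mixed / unscored counts; nests
  containing any unlabeled cell are excluded from the fraction rather than
  guessed.

None of the three knobs has a canonical value, so `clonality_sweep()` emits
the monoclonal fraction over a positivity-threshold grid as part of every
report. For $L$ equiprobable labels and nests of size $m$, the signaling
regime's expected monoclonal fraction is $L^{1-m}$ (1/81 for $L = 3$,
$m = 5$), which the tests verify by simulation against the end-to-end
estimator.

## The synthetic generator

`generate_slice()` emulates one optical section: Epi nuclei uniform in the
disk inside the ring radius, VE nuclei uniform in the annulus, a minimum
center spacing of one nucleus diameter enforced by rejection sampling
(failing loudly after 10⁴ consecutive rejections rather than overlapping).
A channel's mean intensity is
$\mathrm{baseline} + \mathrm{amplitude}\cdot g(\theta_i)$ in its own
compartment, where $g$ is the von Mises density rescaled to peak 1 at the
domain angle; $\kappa = 0$ gives $g \equiv 1$, an *exact* angular null.
Gaussian noise is added and clipped at zero. Nested domains (a tight core
inside a broader domain) are two channels sharing the angle with
$\kappa_{\mathrm{core}} > \kappa_{\mathrm{broad}}$. Rendered fixtures
(`render_slice()`) draw nuclei as filled discs in a label mask; intensity
discs are flat (constant per-nucleus value) rather than shaded blobs so
that per-nucleus medians round-trip exactly through the extractor — the
round trip, not photorealism, is what the fixture must guarantee.

Defaults are order-of-magnitude choices for this system, stated once and
not fitted to any dataset: ring radius 45 µm, outer radius 100 µm
(a ~200 µm aggregate), nucleus diameter 8 µm (area ≈ 50 µm², inside the
default filter window), 40 Epi and 150 VE nuclei, baseline 0.1,
amplitude 0.5, noise SD 0.1 (signal-to-noise 5). The 150-nucleus VE ring is
a statistical test condition rather than a literal single-cell layer; it
gives the classifier's calibration checks realistic sample sizes. One
caveat follows from the intensity model: the normalized magnitude is not
monotone in $\kappa$ over its whole range — past $\kappa \approx 4$ the
few bright nuclei are increasingly outweighed by the summed baseline, so
$p$ peaks and declines. Monotonicity checks therefore run on
$\kappa \in \{0, 0.5, 1, 2, 4\}$, where expectation is strictly increasing.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: optical blur and illumination gradients, segmentation
errors (the synthetic tables are perfect segmentations), 3D effects
collapsed into a slice, cell-shape anisotropy, and any mechanistic coupling
between the two channels beyond their shared geometry. Conclusions about
classifier calibration and power transfer to real data only to the extent
that shuffle-null exchangeability holds there too.

`generate_clonal_culture()` places nest founders with a minimum separation
(default 60 µm) and members within a nest radius (default 15 µm) so that
truth nests are resolvable by the default detector (inter-nest gaps exceed
the link distance; members chain to their founder within it), then labels
cells by regime. This is a geometry for *testing the estimator*, not a
model of colony growth.

## Numerical and reproducibility choices

* Every randomized stage takes an explicit seed; batch drivers derive
  per-(aggregate, slice, channel) sub-seeds from one master seed via a
  deterministic string hash (`derive_seed()`), so any single test can be
  replayed in isolation and full re-runs are byte-identical (asserted on
  report checksums).
* Degenerate inputs are flagged, never coerced: all-zero weights make the
  polarization undefined (not 0), a zero vector has no angle, fewer than
  two nuclei have no $R_{\mathrm{gyr}}$.
* `acos` arguments are clamped to $[-1, 1]$ against rounding; the exact
  arithmetic identities (zero vector under uniform weights, rescaled
  maximum exactly 1) are asserted at machine precision in the tests.
* Simulation sizes in the test suite — 500 null slices, 200 replicates per
  $\kappa$ or angle offset, 2000 scored nests — were chosen to put the
  Monte-Carlo error well inside each check's tolerance band.

## Known limitations

Strictly 2D; no multipole descriptors beyond the first moment; no
multiple-testing correction across aggregates (none is applied in the
study design this mirrors); the permutation null assumes exchangeability of
intensities across positions within a compartment, which intensity
gradients of technical origin would violate; and nest detection by a fixed
radius has no notion of density-dependent linking.
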