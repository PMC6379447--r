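---
title: "Supervised colour-threshold quantification of TTC-stained infarcts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised colour-threshold quantification of TTC-stained infarcts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcquant)
```

## The measurement problem

In rodent models of ischemic stroke (middle cerebral artery occlusion,
MCAO), infarct size is the primary outcome. TTC
(2,3,5-triphenyltetrazolium chloride) is reduced by intact
mitochondrial enzymes, staining viable brain tissue deep red; dead
tissue stays pale. A coronal section photographed on a dark plate thus
carries its own segmentation cue: three colour classes with a strong
brightness ordering (pale infarct > deep-red tissue > near-black
plate) and a strong red-channel ordering (tissue > plate). The classic
workflow traces the classes by hand in a general-purpose image tool;
the approach implemented here replaces tracing with two supervised
thresholds and reports

$$\mathrm{Ratio} = 100 \cdot \frac{n_\mathrm{infarct}}{n_\mathrm{infarct} + n_\mathrm{normal}}\,,$$

the infarct as a percentage of the whole coronal section area. The
denominator is tissue only: plate pixels inside the region of interest
are classified as neither and never counted. This follows from the
two-mask design — "whole section" is exactly what the two masks
jointly cover.

## The classification model

For a pixel with 8-bit channels $(r, g, b)$:

* **Brightness** is the arithmetic mean $(r+g+b)/3$. The method never
  defines brightness beyond requiring the infarct > tissue > plate
  ordering; the mean is the choice that preserves it. Under the
  plausible alternative $\max(r,g,b)$, pure red would be as "bright"
  as white and the first threshold could not separate pale infarct
  from deep-red tissue at all.
* **Hue** is standard HSV hue from max/min channel arithmetic, mapped
  to signed degrees $(-180, 180]$ with pure red at $0$, so the
  symmetric acceptance band is directly expressible. Achromatic pixels
  ($r = g = b$) have undefined hue (`NA`). No saturation floor is
  applied for near-achromatic pixels: hue is computed whenever
  $\max \ne \min$. A floor would be a defensible refinement but is not
  part of the method being reimplemented.
* **Stage 1 (infarct)**: member iff brightness $> t_\mathrm{infarct}$.
  Strict inequality — the rule is "greater than", so ties at the
  threshold are excluded (both stages).
* **Stage 2 (normal tissue)**: member iff $r > t_\mathrm{red}$ *and*
  hue $\in [-60F, +60F]$ *and* the pixel is not already infarct. The
  stage order is part of the workflow (infarct is confirmed and fixed
  first), so a pale pixel that also passes the red test is infarct,
  never normal. The hue gate is applied only at this stage; the
  original description attaches it solely to normal-area extraction.
* No morphological cleanup is applied by default — the method is pure
  per-pixel thresholding. `filter_small_components()` exists for
  exploration but is off by default and excluded from acceptance
  properties.

## Parameters

| parameter | domain | default | meaning |
|---|---|---|---|
| `t_infarct` | 0–255 | supervised | brightness cut isolating pale infarct |
| `t_red` | 0–255 | supervised | red-channel cut isolating stained tissue |
| `f_hue` (F) | 0–0.2 | 0.2 | half-band = 60·F degrees around pure red |

`f_hue = 0.2` (band $[-12°, +12°]$) is the default because the filter
exists to reject impurities, not to trim red tissue: the widest band is
the least invasive setting, and in the original workflow the hue
scrollbar is only adjusted "occasionally". At $F = 0$ the band
degenerates to $\{0°\}$.

The thresholds themselves are deliberately *not* automated — specimens
and lighting vary, which is the stated reason the method is
semi-automated. `threshold_sweep()` reproduces the supervision loop in
batch form; `suggest_thresholds()` is an explicit extension beyond the
canonical method (flagged as such in its documentation) that seeds the
loop with Otsu splits: the full brightness histogram separates plate
from tissue, the tissue-restricted histogram separates normal from
infarct, and the red-channel histogram gives `t_red`. Otsu's
between-class variance is flat across the empty gap between two
populated histogram levels; we take the plateau midpoint, which centres
the cut in the gap (the lowest-maximizer convention would sit the cut
on the lower class level itself).

## The synthetic world

No photograph set is deposited with the method this package
reimplements, so correctness is established on synthetic sections with
pixel-level ground truth. The generator states the world the method
assumes, and its defaults were fixed before any test was run:

* 160×120 px image; elliptical section (semi-axes 60×45 px, ~8,500
  tissue pixels) on a dark plate.
* Palette: background (8,8,8); normal (170,30,30) — hue exactly 0,
  deep red; infarct (230,225,215) — pale, brightness 223. These
  satisfy the orderings the method requires, with ≥60-unit gaps, and
  are asserted at construction.
* Infarct geometry: concentric ellipse scaled by $\sqrt{f}$ and offset
  toward one side (roughly where an MCA-territory infarct sits), a
  half-plane cut, or an explicit ellipse. The default fraction is 30%,
  the value used throughout the contract examples.
* Noise: i.i.d. per-channel Gaussian, rounded and clipped to [0,255] —
  the simplest model that exercises threshold robustness. Nothing in
  the source method specifies an imaging-noise model.
* Impurities: ellipses drawn on the plate only (never over tissue),
  with colours required to lie outside the widest red band — gray,
  green, blue debris, i.e. exactly what the hue filter exists to
  reject. The gray default (120,120,120) deliberately passes a typical
  `t_red`, so only the hue gate removes it.
* Studies: per-animal target fractions drawn uniformly in 10–50%
  (the range of the contract's study example, and a realistic spread
  for transient MCAO), per-animal seeds derived from one study seed.
  All generation is seeded; there is no unseeded path.

What a green test does *not* establish: the generator has flat class
colours, no illumination gradients, no shadows or specular highlights,
no JPEG artefacts, no anatomical texture, and sharp class boundaries
with no mixed edge pixels. Results on synthetic fixtures bound the
algorithmic behaviour (exactness, monotonicity, impurity rejection),
not performance on difficult photographs — which is precisely why the
method keeps a human in the loop.

With `noise_sd = 10` the dominant error mode is instructive: brightness
noise is attenuated by the 3-channel mean (σ/√3 against ≥70-unit
margins, negligible), but hue near pure red has noise σ of roughly
$60\sqrt{2}\sigma / C \approx 6°$ (chroma $C \approx 140$), so a few
percent of normal-tissue pixels fall outside the ±12° band and leave
the denominator, biasing the ratio upward by well under 1 percentage
point at the default geometry. The ±1.0 pp recovery criterion holds
with this bias included, which is the honest reading of "robust".

## Method-comparison statistics

All five tests are implemented from their formulas (n−1 sample SD
throughout, two-tailed p-values throughout) and verified against
independent reference implementations to 1e-9 (statistics) / 1e-6
(p-values):

* paired t: $t = \bar d / (s_d/\sqrt n)$, df $= n-1$; an 11-animal
  design reports df = 10. Zero-variance differences are degenerate;
  `compare_methods()` records exact agreement as a note ("methods
  identical") rather than an error, since it is the strongest possible
  no-difference outcome.
* Pearson r with $t = r\sqrt{(n-2)/(1-r^2)}$, df $= n-2$; $|r|=1$
  maps to $p = 0$.
* OLS of method B on method A via the normal equations;
  $r^2 = r_{xy}^2$ for the simple fit, defined 0 for constant y.
* One-sample KS against a normal with the sample's own mean and SD.
  Fitting the null parameters from the sample makes the classical
  asymptotic p-value conservative (the Lilliefors situation); it is
  kept, documented as approximate, because the screening role only
  needs it as a flag. The asymptotic series is evaluated with the
  classical 1e-6 term truncation so values are bit-comparable with
  standard implementations. A practical consequence of the fitted
  null, verified empirically: a uniform sample at n = 200 does *not*
  reliably exceed the fully-specified 5% critical value
  $1.36/\sqrt n$ — it clears only the parameter-fitted (Lilliefors)
  critical value $\approx 0.886/\sqrt n$. The test suite uses the
  appropriate critical value for each case.
* Variance similarity: reports of this design sometimes label the
  check "Fisher's exact test"; an exact contingency-table test cannot
  assess variances, so this package provides Fisher's F-test of
  variance equality under its correct name, with $F \ge 1$ by
  construction (larger variance in the numerator) and
  $p = 2\,P(F_{df_1,df_2} \ge F)$ capped at 1.

## Numerical and interface choices

* Coordinates are 0-based $(x, y)$ = (column, row) with half-open
  rectangles, so ROI area arithmetic is exact and nested crops compose.
* Channel bytes are taken at face value — no ICC/gamma handling, no
  JPEG-artefact processing; thresholds are user-tuned anyway, and the
  original tool shows no colour management.
* PNG and JPEG are read via libpng/libjpeg wrappers; baseline
  uncompressed TIFF (both byte orders, 8/16-bit, gray/RGB, strips) is
  parsed by a small built-in reader because no TIFF package is
  available in the supported toolchain. Compressed or tiled TIFF is
  rejected with a clear message.
* PNG output is bit-reproducible for identical input, so re-running a
  command overwrites outputs identically.
* Degenerate inputs fail loudly and specifically: empty ROI, ROI out
  of bounds (naming the offending coordinate), no tissue at the chosen
  thresholds ("empty section"), constant-intensity ROI for Otsu,
  zero-variance samples for each statistic.

## Known limitations

* Single section per call; multi-section plates are handled as
  repeated calls with distinct ROIs.
* No edema correction, no hemisphere normalization, no volume
  integration across a slice series — deliberate scope, matching the
  per-section method.
* The white/red-background check is a heuristic warning (border pixels
  predominantly bright or red-hued), not a validator.
* `suggest_thresholds()` assumes at least two distinguishable classes
  in the ROI and is a starting point only; supervision remains the
  contract.
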