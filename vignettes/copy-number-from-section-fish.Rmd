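---
title: "Copy number from tissue-section FISH: models, simulator, and image pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number from tissue-section FISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectionFISH)
```

## The estimation problem

FISH on thin tissue sections observes, per nucleus, a spot count for a probe
bound to a locus of interest. Three features of sectioned material corrupt
the naive count-and-average estimate: most nuclei are only partially inside
the section, control probes cannot be assumed diploid in aneuploid tumours,
and overlapping nuclei defeat single-nucleus segmentation. This package
estimates absolute copy number with a geometric volume correction and two
Poisson models, one for manually counted nuclei and one for fully automated
counting.

## Geometry: how much of a nucleus does a section sample?

Nuclei are modelled as spheres of radius $r$; the section is a slab of
thickness $h$. With $d$ the distance from the nucleus midline to the near
face of the slab, the sampled volume is the exact slab–sphere intersection

$$V_\mathrm{seg}(d) = \pi h\left(r^2 - d^2 - hd - \tfrac{h^2}{3}\right),$$

valid while the slab $[d, d+h]$ lies inside the sphere; outside that range
the package clips the integral to the sphere (an empty intersection gives
zero). `segmentVolume()` is verified against numeric quadrature of
$\pi(r^2-z^2)$ to a relative tolerance of $10^{-9}$.

Two *averages* of this quantity appear in the package, and the distinction
matters:

* `averageSampledVolume()` returns the closed form
  $V_\mathrm{avg} = \pi h\left(\tfrac{2r^2}{3} + \tfrac{rh}{3} -
  \tfrac{h^2}{6}\right)$. This is the package's normative correction for
  real tissue sections. It has two attractive properties: at $h = 2r$ it
  equals the sphere volume exactly (a section as thick as the nucleus
  captures everything), and for the standard scenario of a 3 µm section
  through a 9 µm diameter nucleus it gives the familiar figure that only
  41 % of the nuclear volume is sampled.
* `expectedSampledVolume(g, L)` returns the exact expectation of
  $V_\mathrm{seg}(d)$ under an explicit offset model
  $d \sim \mathrm{Uniform}(0, L)$, which is
  $\pi h\left(r^2 - \tfrac{L^2}{3} - \tfrac{hL}{2} - \tfrac{h^2}{3}\right)$
  while the slab stays inside the sphere (numeric quadrature of the clipped
  segment otherwise).

These two averages are *not* reparametrisations of each other: no uniform
offset range reproduces the closed form. In particular, under the
simulator's own placement model ($r = 9$, $h = 3$,
$d \sim \mathrm{Uniform}(0, r - 2h)$) the expected sampled fraction is
0.2176, while the closed form gives 0.1898 — a 15 % discrepancy. An
estimator must divide by the average that matches how the data were
actually generated: if sections are *known* to follow a given offset
distribution (as in the simulator, where the adjustment factor would
otherwise inflate every estimate by 15 % and push the worst-case benchmark
error well above one copy), the offset-consistent expectation is the right
normalisation; for real sections, where the placement distribution is not
observable, the closed form is the package's standard correction and is
what `volumeAdjust()`, `estimateManual()` and `estimateAuto()` use by
default (`volumeModel = "closed_form"`). Both estimators expose
`volumeModel = "uniform_offset"` for the model-consistent alternative, and
the benchmark (`runGrid()` via `sectionEstimates()`) uses it, matching its
generative model. This design choice is deliberate and central; the
geometry tests pin both averages separately.

## Manual counting: Gamma–Poisson posterior

Observed per-nucleus counts are volume-adjusted
($n^\mathrm{voladj}_c = n^\mathrm{obs}_c \cdot
V_\mathrm{sphere}/V_\mathrm{avg}$, real-valued, never rounded) and modelled
as Poisson with rate $\lambda$:

$$P(n^\mathrm{voladj} \mid \lambda) = \prod_{c=1}^{C}
\frac{e^{-\lambda}\lambda^{n^\mathrm{voladj}_c}}{n^\mathrm{voladj}_c!},$$

with the factorial extended through the Gamma function for non-integer
adjusted counts; the conjugate update only needs the sufficient statistic
$\sum_c n^\mathrm{voladj}_c$. Under a Gamma$(a, b)$ prior the posterior is
Gamma$(a + \sum_c n^\mathrm{voladj}_c,\; b + C)$, so the package samples
the posterior chain directly (independent draws; any correct MCMC sampler
targets the same distribution, and the closed-form posterior mean
`posteriorMeanClosedForm()` serves as the analytic cross-check in the
tests). The reported copy number is the mean of the post-burn-in draws,
with the central 95 % interval of the chain as its uncertainty.

Settings, with units and defaults:

* `priorShape`, `priorRate` (`a`, `b`): 0.001 each. Near-flat, so the
  posterior mean essentially equals the mean adjusted count; the prior only
  regularises empty or tiny tables. These hyperparameters are a package
  choice, declared rather than inherited.
* `chainLength`: 10 000 post-burn-in draws; Monte-Carlo error of the
  posterior mean shrinks as $1/\sqrt{T}$ and is negligible against the
  posterior spread at this length.
* `burnIn`: 1 000 discarded draws. With direct conjugate sampling burn-in
  is not statistically necessary; it is retained so that a
  Metropolis-style sampler can be swapped in without changing reported
  conventions.
* Rounding: copy numbers are reported both continuous and rounded
  half-away-from-zero, clamped at zero (`roundHalfUp()`).

A subtlety of `SpotCountTable`: each row carries a `cells` multiplicity.
When two overlapping nuclei are counted as one blob with their spots
summed, that row represents two cells, and the posterior update divides by
the total number of *cells*, not rows. Without this, unresolved overlaps
would mechanically inflate the per-cell rate by the merge fraction.

## Automated counting: homogeneous Poisson point process

Separating nuclear staining from background is easy even when separating
nuclei from each other is not. The automated path therefore models spots as
events of a homogeneous Poisson point process over segmented nuclear area
$a$ (µm²): $N(a) \sim \mathrm{Poisson}(\lambda^\mathrm{PP} a)$. The MLE
pooled over fields is $\hat\lambda^\mathrm{PP} = \sum N / \sum a$
(`fitPPP()`, cross-checked in tests against a numeric maximiser of the
log-likelihood), and the copy number is

$$E[n] = \hat\lambda^\mathrm{PP} \cdot \pi r^2 \cdot
\frac{V_\mathrm{sphere}}{V_\mathrm{avg}},$$

with the nuclear radius $r$ supplied by the user (measured from images).
The homogeneity assumption is deliberately strong; the simulator's
subclonal mixtures probe its failure mode and show the estimate tracks the
ploidy-weighted mean copy number.

The standard control-probe baseline
(`controlAdjust()`: expected-over-observed control ratio times the observed
count) is included for comparison. It is close to unbiased only when the
control truly has the assumed copy number — and even then the ratio
estimator carries a small positive finite-sample bias of order
$n \cdot \mathrm{Var}(\bar c)/E[\bar c]^2$ — and fails by
$n\,(2/n^\mathrm{ctrl} - 1)$ otherwise.

## The tissue-section simulator

`simulateSection()` composes the generative steps that define the benchmark
conditions: $C = 50$ nuclei of radius 9 µm per 3 µm section; offsets
$d_c \sim \mathrm{Uniform}(0, r - 2h)$ (the sampler refuses $r \le 2h$, for
which the stated range is empty); per-nucleus sampled fractions
$V_\mathrm{seg}(d_c)/V_\mathrm{sphere}$; observed counts
$\mathrm{Poisson}(n \cdot V_\mathrm{frac})$ for the locus and the control
independently; overlap merging; then a $\pm 1$ counting error applied to a
fraction $|e|$ of objects (rounded half up, decrement floored at zero).

Merging follows sequential pairing: each nucleus merges with its successor
with probability $P$, a merged pair takes no further part in pairing, spot
counts are summed, and the merged projected area is the union of two equal
circles whose centre distance is drawn as a fraction
$\mathrm{Uniform}(0, 0.3]$ of the diameter — the only geometrically
coherent reading of the merged-area construction, with the centre-distance
support interpreted as a diameter fraction and kept configurable
(`bFractionMax`).

The benchmark grid (`runGrid()`) crosses count-error fractions
$e \in \{-0.2, -0.1, -0.05, 0, 0.05, 0.1, 0.2\}$ (the error grid is read as
±5 %, ±10 %, ±20 % plus zero), overlap probabilities
$\{0, 0.1, 0.3, 0.5, 0.8\}$, control copies 1–4 and true copies 1–10, with
10 replicate sections per condition, all driven by one seeded RNG stream so
the whole grid is exactly reproducible. Estimates are summarised as mean
absolute error (continuous scale) and rounded-count accuracy;
`summarizeBenchmark()` aggregates either per full grid point or per
heatmap-style cell (error or overlap level × control copies, pooling true
copies and replicates), the granularity at which benchmark errors are
conventionally reported as integers. The full factorial at these defaults
is 14 000 sections; the acceptance analyses run the noise slice (2 800
sections) and the overlap slice (2 000 sections), which complete in
seconds.

What the simulator does *not* emulate: spatial correlation between
neighbouring nuclei, probe hybridisation efficiency varying across the
section, intensity-dependent miscounting (errors are a flat ±1), and any
imaging physics — it generates counts, not images. Benchmarks passed on
this simulator therefore validate the estimators' handling of subsampling,
control aneuploidy, overlap and symmetric miscounts, nothing more.

## The image pipeline and its synthetic fields

`processField()` reimplements a pragmatic spot-segmentation chain:
best-focus selection by Vollath's F4 measure with a window of 4 planes
below to 5 above the best (clamped at stack edges), maximum-intensity
projection, contrast normalisation allowing up to 40 % of pixels to
saturate, nuclear masking, retention of the top 10 % of in-mask intensity,
two-stage Gaussian blur + automatic threshold, and a size filter.

Numerical and design choices:

* **Nuclear segmentation** is a substitute segmenter (Otsu threshold, hole
  filling, opening, small-object removal); parity with any particular
  external segmenter is a non-goal, and its contract is defined by IoU
  ≥ 0.9 against synthetic truth.
* **Saturation semantics**: the clip level is the $(1-s)$ intensity
  quantile of the whole plane, mapped to 1 after a full-range rescale; if
  that quantile does not exceed the minimum (extremely sparse planes) a
  plain rescale is used. The quantile-clip reading was chosen over a
  display-range stretch because only it makes "40 % of the image" well
  defined on arbitrary planes.
* **Top-10 % filter** uses the in-mask pixel population as its reference;
  computing it over the whole plane would let the (large, dark)
  extranuclear area set the cutoff and defeat the filter's purpose.
* **Thresholding**: Intermodes iteratively smooths the 256-bin histogram
  with a 3-bin running mean until exactly two local maxima remain
  (histogram ends count as maxima; ties break toward the left mode via
  floor of the midpoint) and splits them at the midpoint; if bimodality is
  never reached within 10 000 passes the function warns and falls back to
  Otsu. Rényi-entropy thresholding maximises the sum of background and
  foreground Rényi entropies of order $\alpha$ (default 2; $\alpha \to 1$
  recovers the Shannon maximum-entropy threshold). The single-order
  criterion is used rather than a multi-order combination rule; the order
  is exposed. Both are verified bin-by-bin against independent brute-force
  implementations. Inside the two-stage spot segmentation the lowest
  histogram bin is excluded from the criterion (`ignoreZero`), because
  masked-and-filtered planes are dominated by exact-zero background that
  would otherwise drag either criterion to a near-zero threshold and
  dilate every spot into its neighbours.
* **Channel-to-method mapping** is explicit per channel
  (`thresholdMethods`): Intermodes for channels with a precipitation
  signal (whose intermediate-intensity mode it separates), Rényi entropy
  for those without. Nothing is auto-detected.
* **Size filter**: connected components with area inside
  $[\pi(0.1)^2, \pi(0.75)^2]$ µm² by default, i.e. spot diameters
  0.2–1.5 µm; configurable.

`synthField()` generates the matching synthetic data: DAPI disks
(optionally overlapping), in-nucleus Gaussian spots whose per-nucleus count
is Poisson(copies × sampled fraction) for an explicit section geometry,
diffuse extranuclear autofluorescence, bright extranuclear artifact blobs,
faint precipitation inside nuclei, Gaussian noise, and defocus-blurred
z-planes. The diffuse autofluorescence is what gives the 40 % saturation
step its meaning — it occupies the top intensity mass so that clipping
equalises weak spots with bright extranuclear signal, which masking then
removes. Planted spots are kept ≥ 12 px apart within a nucleus so that
clean-field recovery is exact by design; real spot pairs closer than the
blur scale would merge, which is one reason the point-process estimate,
not the raw count, is the quantity of interest. The planted truth (mask,
counts, copies) rides along for end-to-end checks: on clean fields the
chain recovers planted counts exactly, and imaging + point-process
estimation recovers planted copies within ±1 for copies 1–4.

## Degenerate inputs and edge conventions

Zero observed control counts make the control baseline undefined (error,
reported as NA inside the benchmark); zero pooled nuclear area makes the
point-process intensity undefined (error); empty masks yield empty
observations; constant planes are returned unchanged by normalisation and
all-background by thresholding; sections thicker than the nucleus diameter
clamp the sampled fraction to 1 with a warning; and all-zero count tables
shrink to the prior (≈ 0 copies under the near-flat default).

## Known limitations

Spherical nuclei with a single shared radius; homogeneous spot intensity
across nuclear area; no 3-D spot detection (spots are counted on a
projection); the simulator's counts-only abstraction above; and the
finite-sample behaviour of the ratio-type control baseline, which is
reported for comparison, not recommended. Estimating copy number from a
handful of fields inherits their sampling bias regardless of the model.
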