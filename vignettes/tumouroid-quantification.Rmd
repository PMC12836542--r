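---
title: "Methods: image-based tumouroid growth and dose-response quantification"
author: "tumouroidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based tumouroid growth and dose-response quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumouroidr)
```

## The problem

Patient-derived tumouroids (PDTs) are 3D cultures grown from tumour biopsies
in gel droplets and used for ex vivo drug testing. Destructive endpoint
assays (e.g. ATP-based viability) give one number per well; continuous
brightfield/confocal imaging instead yields a growth trajectory per well
without consuming the sample. This package implements the computational half
of such a screen: turning per-well Z-stack time-lapse images into
morphometric growth readouts and dose-response parameters.

The pipeline has four stages, each exposed as plain functions:

1. **Best-focus projection** (`best_focus_project`): a Z-stack is collapsed
   to one 2D image by copying, per square tile, the plane with the highest
   sharpness.
2. **Segmentation** (`select_threshold`, `binarize`, `label_and_filter`,
   `measure_component`): an image-specific global threshold separates dark
   tumouroids from the bright background; connected particles are measured
   in physical units.
3. **Readouts** (`well_readouts`, `replicate_stats`,
   `readout_correlations`): seven per-well, per-day quantities — total
   covered area, relative total area, count, and per-object mean size,
   diameter, perimeter and circularity.
4. **Dose-response** (`normalize_to_control`, `fit_ll5`, `ed50`, `gi50`,
   `rank_sensitivity`): treated wells are normalized to the vehicle-control
   mean and fitted with a five-parameter log-logistic model.

A synthetic plate generator (`sim_config`, `simulate_plate`) provides ground
truth for every stage.

## Best-focus projection

Tumouroids settle at different depths in the gel droplet, so no single plane
is in focus everywhere. The frame is partitioned into tiles (default 32 px)
and each tile is copied from the plane maximizing the **variance of the
discrete Laplacian** — a standard, parameter-free sharpness score that is
zero on flat tiles and strictly decreases under Gaussian blur. Ties break to
the lowest plane index, making the output deterministic. Tiles are copied
hard, without blending: every output pixel equals a pixel of exactly one
input plane, and the chosen plane per tile is kept as a provenance map. Seam
artifacts between tiles are accepted at low magnification; smaller tiles
resolve objects at different depths that sit close together, at the cost of
less signal per tile in noisy images.

## Segmentation

The threshold is anchored on the *background* population of the intensity
histogram (256 bins over the image range): the mode estimates the background
level, and a normal-consistent median absolute deviation of the pixels
within a quarter of the intensity range of the mode estimates its spread.
The cutoff is `mode - k * spread` (default `k = 3`) for dark objects. Every
ingredient — binning over the range, the mode, the windowed MAD — transforms
affinely with the intensities, so the classification mask is invariant under
gain/offset changes. The spread is floored at one histogram bin width so
that noiseless images still get a cutoff strictly on the object side of the
background.

A background-anchored rule was chosen over Otsu-style class separation
because early-day images have a tiny object fraction, where variance-based
thresholds fail; the documented cost is a tendency to *overestimate*
tumouroid-covered area (faint halo pixels near the background level are
included), which is visible and testable on synthetic data.

Binarization fills holes inside candidate regions (translucent tumouroid
centres must not perforate particles), and connected components are
extracted with 8-connectivity. Components smaller than the area of a
40 µm-diameter disk (~1257 µm², matching a 40 µm lower size cut on seeded
material) are treated as debris; the floor is configurable. Merged,
overlapping tumouroids are deliberately *not* split: merging is reported as
it is measured, which depresses count and circularity as objects grow — a
known property of this readout family.

Per-object measurements: area is the pixel count times the pixel area;
perimeter uses corner-weighted contour steps (0.980 per axis step, 1.406 per
diagonal, −0.091 per direction change), accurate to ~2% on disks down to
5 px radius, where plain step counting errs by ~5%; circularity
`4πA/P²` is clamped at 1 so rasterization noise never pushes a disk above
the nominal 0–1 range; a single-pixel component is assigned its square
contour (4 pixel edges) and circularity 1.

## Readouts and normalization

`relative_total_area` divides a well's total covered area by the same
well's value on its **anchor day** — the first day with a usable image.
The anchor maps to exactly 1 and the readout is invariant under any global
rescaling of the well's areas, which removes well-to-well variation in
seeding density; it is the primary growth readout. The anchor day is
recorded in all outputs. A zero-area anchor makes the readout undefined for
that well; such wells are excluded with a logged reason rather than failing
the run (mirroring real-world exclusions, e.g. gel breakage, which are
handled per day, not per experiment).

"Average area" (whole-well total area averaged over replicates) and
"average size" (per-object mean area) are deliberately distinct readouts,
named `total_area_um2` and `mean_size_um2`. Replicate summaries report
mean, SEM (sample SD over replicate wells / √n; undefined for n = 1) and n
per readout and day. Readout correlations are Pearson, over (well, day)
observations, excluding count, with pairwise-complete handling of missing
values.

## Dose-response model

Treated replicate wells are divided by the *mean* of the vehicle technical
replicates of the same sample and day — one point per replicate, never
pre-averaged, so fits see the replicate scatter. Vehicle wells (dose 0) are
used only as the denominator and never as fitted points, avoiding `log(0)`.

The model is the five-parameter log-logistic

$$y(x) = c + \frac{d - c}{\left(1 + e^{\,b(\ln x - \ln e)}\right)^{f}}$$

with slope $b$, lower asymptote $c$, upper asymptote $d$ (not constrained
to 1 — control-normalized responses may exceed it), location $e$ (nM) and
asymmetry $f > 0$. Fitting is least squares in log-dose via
Levenberg–Marquardt with a deterministic multi-start: $b$ from a linear
regression of response on log dose, $c, d$ from the extreme per-dose means,
$e$ from the dose nearest the midpoint, and a fixed 3×3 grid of $(b, f)$
multipliers. No random starts are used; fits are bit-reproducible.

Derived doses, both closed-form:

- **ED50** = $e\,(2^{1/f} - 1)^{1/b}$, the dose at the midpoint of the
  *fitted* span $(c, d)$ — 50% of maximal fitted inhibition. (The
  alternative reading, 50% of the *empirically observed* span, can be
  computed from the returned asymptotes; the fitted-span convention is the
  default because it is what standard dose-response tooling reports.)
- **GI50**: the dose where the absolute response crosses 0.5 (50% growth
  inhibition relative to control), by inverting the model; it is flagged
  undefined — not an error — when the fitted curve never reaches 0.5.

Sensitivity rankings are reported under all three criteria (maximal
inhibition $1 - c$, ED50, GI50) side by side, because they can legitimately
disagree: a sample can reach deeper maximal inhibition while another has a
lower midpoint dose.

### Identifiability of the asymmetric 5PL

With fewer than five distinct concentrations the asymmetry $f$ cannot be
identified and the fit falls back to the symmetric 4PL ($f = 1$, flagged);
the same fallback triggers when the Jacobian is numerically ill-conditioned
(condition number > 1e10).

Even at five concentrations, $e$ and $f$ trade off along a near-flat ridge:
on a 10-fold ladder with four replicates and 5% response noise, the
linearized (Cramér–Rao) standard error of $e$ exceeds $e$ itself, so *no*
estimator can pin the raw location parameter reliably at that design. The
practically identifiable location quantity is the **ED50**, whose
linearized relative standard error at the same design is ~11%; empirically
the fitter recovers it with single-digit median error. Users should compare
samples on ED50/GI50, not on $e$.

## The synthetic plate generator

`simulate_plate` emulates the screening scenario end to end and is the
package's validation instrument. Defaults are the reference conditions: six
doses (vehicle plus a 5-step, 10-fold ladder 0.1–1000 nM), four technical
replicates, imaging days 1–14 with treatment starting day 2 and lasting
7 days, Hill inhibition with IC50 10 nM.

- **Geometry.** Each well seeds `n_objects` disks with day-0 radii drawn
  from 25–45 µm (the seeded size fraction), placed uniformly with a
  configurable minimum centre separation, each at a random Z-plane. Radii
  grow exponentially at `growth_rate` 0.08/day — relative area ≈3.6× by
  day 9, a realistic magnitude for growing PDT cultures — scaled by
  `1 - inhibition(c)` during the treatment window only (growth resumes
  after drug removal, mirroring wash-out).
- **Rendering.** Objects are dark anti-aliased disks (background 0.85,
  object 0.35) on 256×256 px frames at 3 µm/px (a 2× objective scale);
  5 planes at 20 µm spacing; defocus is an isotropic Gaussian PSF growing
  at 0.03 px per µm of defocus; additive Gaussian noise (sd 0.02). The
  anti-aliased edge makes threshold placement consequential, and the
  per-plane blur makes best-focus selection meaningful. All randomness
  derives from `rng_seed`; identical configurations render bit-identical
  plates.
- **Ground truth.** The per-well true area is the pixel count of the union
  of anti-aliased disks (any coverage), clipped to the frame — the area a
  perfect segmenter could recover from the rendering — plus per-object
  centres, depths and radii per day.

What the simulator does **not** emulate: irregular (non-disk) tumouroid
shapes, intensity gradients and vignetting, gel breakage, bubbles, debris
fields, drug-induced swelling or morphology change, and object motion
between days. Passing the synthetic benchmarks therefore demonstrates that
the *computational* chain is correct and self-consistent — not that the
thresholding rule or the growth model matches any particular instrument or
tumour type; on real data the threshold multiplier `k`, the tile size and
the debris floor are the knobs expected to need adaptation.

## Numerical choices and benchmark sizes

- Histogram: 256 bins over the observed range; mode ties break to the
  lowest bin; spread floor = one bin width.
- Tile ties break to the lowest plane index; tiles at the frame edge may be
  smaller than nominal.
- Connectivity is fixed at 8-neighbour; labels are assigned in raster order
  of each component's first pixel.
- The degenerate inputs each have a defined contract: constant images are a
  threshold error; empty masks yield empty object tables; zero-object days
  yield zero area, zero count and missing means; a zero anchor area marks
  the well unusable for relative area; flat response sets are a fit error.
- Validation problem sizes (the package's own benchmark choices, run in the
  test suite): segmentation recovery uses a noiseless 192 px plate, 3
  planes, 4 objects/well at ≥180 µm separation, 2 replicates, days 1/5/9,
  16 px projection tiles — geometries where defocus halos from co-tiled
  objects stay below ~2% of well area, so the 5% recovery bound is
  meaningful; the projection oracle uses 5 planes and 32 px tiles;
  dose-response recovery uses 100 seeded screens of the 5-dose ladder with
  4 replicates and 5% noise; determinism is checked end-to-end by checksum.

## Known limitations

- Merged objects are counted once; count and circularity drift as cultures
  grow dense. This is inherent to threshold-based particle analysis
  without watershed splitting (deliberately out of scope).
- The covered-area bias is upward by design (background-anchored cutoff);
  relative total area largely cancels it within a well, which is one more
  reason it is the primary readout.
- The raw 5PL location parameter `e` is reported but weakly identified at
  5-dose designs; use ED50/GI50 (see above).
- Single-tumouroid tracking across days is not attempted; readouts are
  well-level.
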