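---
title: "Quantifying microcirculation from video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microcirculation from video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microflow)
```

## The problem

Intravital reflectance video of the microcirculation — capillaries,
arterioles and venules below ~100 µm — shows dark vessels on a brighter
tissue background, because haemoglobin absorbs green light much more
strongly than the surrounding tissue does. Two physiological indices are of
interest frame-to-frame: the red-blood-cell (RBC) flow velocity in each
vessel and the vessel diameter. Both are early, sensitive markers of
circulatory failure (e.g. in sepsis models), and both can be read out
without contact or contrast agents if the video is analysed carefully.

The catch is that the raw video is dominated by nuisance structure: the
animal breathes and twitches (whole-frame translation), the tissue has
static texture, specular reflections leave saturated spots, and the RBC
signal itself is a faint, sparse modulation on top of the dark vessel.
`microflow` implements a processing chain that strips these nuisances one
by one and then measures velocity and diameter in physical units, plus the
longitudinal group statistics used to compare treatment groups over time.

## The processing chain

### 1. Body-motion correction (`register_sequence`)

Every frame is registered to the first frame by maximizing the normalized
cross-correlation of a template region over integer shifts within a search
radius. Integer shifts keep intensities unresampled — no interpolation
noise enters the pipeline — and the residual (< 1 px) is absorbed by the
sparse term of the decomposition below. Matching runs on the green channel,
where contrast is strongest. Ties are broken deterministically (smallest
shift magnitude, then smallest dy, then dx). A flat template is an error; a
correlation peak on the search boundary sets a per-frame `clipped` flag
rather than silently returning a wrong shift.

Template matching needs static structure to lock onto. In real tissue this
is provided by texture; a perfectly uniform background with only moving
content is a degenerate scene for *any* registration method, and the
synthetic generator therefore renders a static texture field by default.

### 2. Vessel extraction (`enhance_vessels`, `segment_vessels`)

The default segmentation is a classical multiscale Hessian vesselness
filter for *dark* tubular structures: per scale \(s\), the image is
convolved with scale-normalized Gaussian second-derivative kernels, the
Hessian eigenvalues \(|\lambda_1| \le |\lambda_2|\) are formed, and

\[ V_s = \exp\!\left(-\tfrac{R_b^2}{2\beta^2}\right)
        \left(1 - \exp\!\left(-\tfrac{S^2}{2c^2}\right)\right),
\qquad R_b = \lambda_1/\lambda_2,\; S = \sqrt{\lambda_1^2+\lambda_2^2}, \]

restricted to \(\lambda_2 > 0\) (dark ridge polarity), with
\(\beta = 0.5\) and \(c\) half the maximal \(S\) at that scale. The
per-pixel maximum over scales is then gated to pixels at least 0.4 local
standard deviations darker than their large-scale local mean. The gate
matters: coarse scales spill a halo around thin vessels, and the halo sits
at background brightness while genuine vessel pixels are substantially
dark. Truncated second-derivative kernels are re-centred to zero sum, so
responses stay unbiased near small-image limits.

The thresholded mask is cleaned (small components removed, small holes
filled). Scales should bracket half the expected vessel radii —
`c(2, 4, 8, 16)` px covers vessels of roughly 5–60 px width at the default
calibration (0.64 µm/px).

A patch-based probabilistic predictor (any function mapping an image patch
to a probability patch, e.g. a trained CNN applied at 256×256 with
overlap-averaged stitching and a 0.5 binarization) can be plugged in via
`segment_vessels(predictor = ...)`; `extract_patches` / `stitch_patches`
implement the exact overlap-average protocol and are identity-exact when
stitching unmodified patches.

### 3. Thinning and centerlines (`skeletonize`, `centerline_paths`)

Zhang–Suen thinning reduces the mask to an 8-connected, 1-px skeleton that
preserves component homotopy and is idempotent. Branch detection uses the
ring crossing number rather than the raw neighbour count: staircase pixels
on a thinned diagonal can have 3–4 neighbours without being branches, and
the crossing number is the criterion that distinguishes the two. Short
spur twigs (boundary-dent artifacts, up to 8 px) are pruned, true branch
points are removed together with their 8-neighbourhood, and each remaining
chain is traced into an ordered subpixel path.

Traced pixel chains are smoothed (moving average, window 5, ends padded by
linear extrapolation). This is not cosmetic: a raw staircase walk
overstates geometric arc length by up to \(\sqrt 2\), and arc length
calibrates the kymograph's distance axis — an unsmoothed path would
inflate every velocity by the staircase factor (we measured ~20% on
horizontal vessels before smoothing).

### 4. RBC isolation by robust PCA (`rpca_decompose`, `sparse_video`)

The registered green video, unrolled one column per frame, is the sum of a
low-rank matrix (static tissue and vessels) and a sparse matrix (moving
RBCs and residual motion). Principal component pursuit,

\[ \min_{L,S} \|L\|_* + \lambda \|S\|_1 \quad \text{s.t.}\quad D = L + S, \]

is solved by the inexact augmented-Lagrangian method: soft-thresholding for
\(S\), singular-value thresholding for \(L\), geometric growth of the
penalty (×1.5), tolerance \(10^{-7}\) on the relative Frobenius residual,
at most 500 iterations. \(\lambda = 1/\sqrt{\max(m,n)}\) by default — the
standard choice with exact-recovery guarantees for incoherent problems —
and the solver is deterministic. On planted rank-2 + 5%-sparse 200×150
problems it recovers \(L\) to relative error below \(10^{-3}\) with ≥ 99%
of the sparse support (test suite, 20 seeds). Decompositions are windowed
at 150 frames by default, the length that reliably yields a clean spectral
signature downstream. A thin economy SVD (Gram-matrix eigendecomposition
for strongly rectangular matrices) keeps full-frame windows fast.

The sparse magnitude |S| — both polarities are RBC signal — is rescaled by
its 99.5th percentile and clipped to [0, 1]; this "sparse video" is what
the velocimetry stage samples.

### 5. Velocity from the kymograph spectrum (`estimate_velocity`)

Sampling the sparse video bilinearly at 1-px arc-length steps along a
centerline, one row per frame, gives the kymograph: moving cells trace
oblique streaks whose slope (px of path per frame) *is* their speed. The
estimator works in the Fourier domain, where parallel streaks concentrate
energy along a line through the origin orthogonal to the streak direction.
With \(\theta'\) the angle between that dominant line and the temporal-
frequency axis,

\[ v = \cot\theta' \;\text{px/frame}
     = \cot\theta' \cdot \frac{\text{pixel size}}{\text{frame interval}}
       \;\mu\text{m/s}. \]

Numerics: the kymograph is centre-cropped to a square (never resampled —
resampling would silently rescale the velocity), mean-subtracted and
Hann-windowed; DC and radii < 2 are excluded; the dominant angle is found
on a 0.25° grid restricted to a radial band and refined by parabolic
interpolation. Two quality diagnostics accompany every estimate: the
energy ratio of the dominant line within the band (< 0.02 flags a weak
signature), and an ambiguity flag set when the *orthogonal* line carries at
least half the dominant line's energy. The second catches the stalled-flow
case: stationary cells plus amplitude shimmer produce a spectral *cross*
(one arm from the static pattern, one from the temporal flicker), and the
angle is then genuinely ambiguous between zero and infinite speed — the
honest output is a flagged non-estimate, not a number. Speed is reported
unsigned with a separate direction sign; by default, velocity is only
estimated for vessels in the 20–100 µm class, where streaks are
well-formed.

### 6. Diameter by FWHM (`vessel_diameter`)

At regular arc intervals along the centerline, the green channel is
sampled along the normal. The diameter is the full width at half maximum
of the dip: with \(m\) the interior minimum and \(p_L, p_R\) the highest
shoulder values on each side, the crossing level is
\(m + \big((p_L+p_R)/2 - m\big)/2\), and the width is the distance between
the subpixel linear-interpolated crossings adjacent to the minimum.
Extremum *locations* are found on a lightly smoothed copy (window 3); the
level and crossings use raw values, so the measurement is exactly
invariant to positive affine intensity maps. Per-normal widths are
aggregated by the median; failing normals (profile exits frame, no dip,
level not crossed) are skipped and counted. Rectangular dips recover their
width exactly; Gaussian dips recover \(2\sqrt{2\ln 2}\,\sigma\) within
0.25 px for \(\sigma\) from 2 to 16 px (test suite).

The frame measured is the per-pixel temporal 10th percentile of the
registered window (a "background" frame). The mean or median would carry a
bright bias along the centerline under heavy cell traffic; a low quantile
is immune to transient brightening while leaving the dip shape — and hence
the affine-invariant FWHM — unchanged.

Classification follows the convention that a capillary is strictly thinner
than 20 µm: `< 20` capillary, `20–100` arteriole/vein (the 20 µm boundary
belongs to the upper class), `> 100` out of range.

### 7. Group statistics (`group_summary`, `ttest_vs_baseline`)

Longitudinal tables (group × subject × timepoint × quantity) are
summarized as mean ± SD (n−1). For cross-index comparison plots, series
are range-normalized and mean-centred, \(x \mapsto (x-\bar x)/(\max x -
\min x)\) — mean 0, range 1, invariant to positive affine maps; z-scoring
is available as an alternative mode, since "normalize and centralize"
admits both readings. Each follow-up timepoint is compared to baseline by
a two-sided **paired** Student's t-test on per-subject differences — paired
because the same animals are measured at baseline and follow-up — with
p-values from the t distribution (n−1 df) and a 0/1 flag at α = 0.1. A
Welch unpaired variant sits behind `paired = FALSE`. Zero-variance
differences are resolved explicitly (all-zero → p = 1; constant non-zero →
p = 0) instead of erroring mid-analysis. No multiple-testing correction is
applied, matching the per-timepoint presentation convention of this kind
of study. Under a simulated null (n = 5, 2 000 replicates) the flag rate
is 0.10 ± 0.02 (test suite).

## The synthetic generator: what it emulates, and what it does not

`render_scene` renders the scene class the pipeline targets with exact
ground truth: dark vessels of specified width/contrast on a textured
background (green channel carries full contrast, red/blue half), sparse
bright Gaussian particles advected along each centerline at constant
velocity, per-frame integer translation jitter, saturated specular disks,
and additive Gaussian noise, all quantized to the 16-bit grid so disk round
trips are bit-exact and fully reproducible from the seed.

Default study conditions: 0.64 µm pixels, 150 frames, 1/30 s frame
interval, tissue level 0.75, texture amplitude 0.1 (sd units), noise sd
0.01, jitter ±2 px, particle entry rate 10 s⁻¹ per vessel with amplitude
0.2 and 15% per-frame amplitude flicker. Particle spots use σ = width/4
capped at 3 px — the physical RBC scale (~7 µm) does not grow with vessel
width. The vessel edge tapers over ~1 px with its half-darkening point
exactly at the nominal radius, so the FWHM ground truth equals the nominal
width by construction. Amplitude flicker is what keeps even stalled cells
visible to the low-rank/sparse split, and is also why the stalled case is
reported as ambiguous rather than as a spurious speed (section 5).

Not emulated: pulsatile flow, vessel branching and plasma gaps, optical
blur and vignetting, non-rigid tissue deformation, depth effects. Passing
tests on these scenes therefore demonstrates correctness of the
*algorithms* under the stated scene model — registration recovery,
decomposition recovery, spectral slope estimation, FWHM geometry — not
performance on any particular real preparation.

`render_kymograph` synthesizes the space–time image directly (streaks of
exact slope) for oracle tests of the orientation estimator, and
`simulate_cohort` generates longitudinal group tables with known trends
for the statistics layer.

## Problem sizes and determinism

Every stage is deterministic given its inputs; all randomness flows
through explicit seeds, and the generator restores the caller's RNG state.
The bundled validation uses scene sizes chosen to exercise the full chain
at meaningful calibration: 72×170 px, 150-frame scenes for the velocity
sweep (planted 50–400 µm/s, ten seeds per velocity, median compared within
±10%), 120×170 px single frames for segmentation metrics, 200×150
matrices for decomposition recovery, and 2 000 replicates for the t-test
level. The acceptance script (`scripts/acceptance.R`) re-runs the same
computations from scratch at five seeds per velocity and reports the
resulting numbers as JSON.

## Known limitations

- Velocities are resolvable up to the streak-slope regime the spectrum can
  separate from the u axis (~21 px/frame ≈ 400 µm/s at the default
  calibration); faster flow needs a shorter frame interval.
- The Fourier estimator reports one dominant velocity per window; it does
  not resolve pulsatility or mixed velocities within a window.
- Stalled flow yields a flagged ambiguous estimate by design.
- Centerlines are branch-free segments; vessel-graph topology (density,
  tortuosity) is out of scope.
- The classical vesselness default is a stand-in interface for a trained
  patch predictor; no network or training loop ships with the package.
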