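---
title: "curvassay: models, estimators and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{curvassay: models, estimators and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvassay)
```

# Scope

`curvassay` implements the quantitative analyses used to characterize
curvature-sensing cytoskeletal proteins such as non-erythroid (αII/βII)
spectrin: (i) signed-curvature profiling of cell outlines combined with
per-channel boundary fluorescence, and classification of actin- versus
spectrin-enriched boundary regions; (ii) deformation-index cytometry
(DI = H/W) from cross-flow junction videos, an apparent-stiffness readout;
(iii) gel and lipid-strip densitometry including the dilution-corrected
sedimentation binding ratio; and (iv) closed-form design calculators for
spherical supported lipid bilayer (SSLB) assays. Because no raw imaging data
are publicly deposited for this class of experiment, every stage is
validated against seeded synthetic phantoms with analytic ground truth;
the generators are first-class, tested package code.

# Boundary curvature and localization

## Contour model and sign convention

A cell outline is a closed plane curve, stored as `n` points uniformly
spaced in arc length (default `n = 1000`), in micrometres, with positive
shoelace area. Coordinates follow the image convention (x = columns,
y = rows, pixel centers at 0-based integers times the pixel size). With
positive orientation the discrete curvature

$$\kappa = \frac{x'y'' - y'x''}{(x'^2 + y'^2)^{3/2}}$$

is positive wherever the osculating circle's center lies on the interior
(cytoplasmic) side: a convex cell is uniformly positive and invaginations
are negative. The verbal convention "positive = bending inward toward the
cytoplasm" does not by itself fix the sign of a convex outline; we document
this choice rather than guess, and note that all downstream classification
uses $|\kappa|$ only, so results do not depend on it.

## Curvature estimation

Derivatives are estimated with periodic Savitzky–Golay local quadratic
fits over a window of 1.5 µm (default; configurable). We also provide
moving-average presmoothing with periodic central differences
(`method = "central"`). Savitzky–Golay is the default because its passband
is much flatter: on analytic circles and ellipse tips it is accurate to
0.1–0.4 %, versus several percent for the moving-average variant at equal
window, and it preserves genuine micron-scale curvature peaks that the
moving average attenuates. The window trades noise suppression against
resolution of the sharpest features; 1.5 µm resolves protrusion tips with
radii of about 1 µm while keeping the pixelation noise floor of
$|\kappa|$ in flat regions near 0.05 µm⁻¹ at realistic noise.

The reported smoothed magnitude track is the *absolute value of the
smoothed signed curvature*, $|\overline{\kappa}|$ (2 µm periodic moving
average, then magnitude). Smoothing before taking the magnitude lets
zero-mean estimator noise cancel; the reverse order (smoothing $|\kappa|$)
folds noise and gives flat membrane a spurious curvature floor of the
order of the noise amplitude, which would corrupt any threshold estimate
near 0.1 µm⁻¹.

Internal consistency checks: total turning $\oint \kappa \, ds = 2\pi$
within 1 % on simple closed outlines; scale covariance
$\kappa \to \kappa/c$ under coordinate scaling by $c$; exact rigid-motion
invariance; agreement with an independent three-point osculating-circle
estimate within 2 % on analytic shapes.

## Segmentation and boundary intensity

Cells are segmented by Otsu thresholding (default: the spectrin/GFP
channel, which marks the whole cell body), keeping the largest connected
component and filling holes. The pipeline thresholds the *raw* image by
default and denoises at the mask level instead (the traced mask is lightly
blurred so the 0.5 iso-level interpolates the boundary at sub-pixel
accuracy): blurring the intensity image before thresholding spreads the
bright cortical band outward and produces a contour offset that varies
with local boundary brightness — a subtle, signal-dependent bias we
measured at up to 0.25 µm.

Boundary fluorescence is the mean intensity over a disc (default diameter
1.0 µm) centered 0.4 µm inside the boundary along the inward normal. The
inward offset targets the cortical band, which lies just inside the
membrane, and makes the profile robust to roughly ±1 px of contour
placement uncertainty; with a 0.5 µm disc centered exactly on the contour
the profile is dominated by placement error at realistic noise. Profiles
are normalized per cell and channel to [0, 1] (min–max by default;
percentile clipping available).

On phantoms, the recovered normalized profiles correlate with the
programmed ground-truth responses at Pearson r > 0.95 (SNR 5) when the
programmed features are wider than the sampling band; features at or below
the band width (sub-micron filopodia-like spikes) are attenuated, as they
would be optically.

## Enrichment classification and curvature by class

A boundary sample is *X-enriched* when channel X's normalized intensity is
at least `intensity_floor` (0.3) and exceeds the other channel by
`dominance_margin` (0.1); contiguous runs shorter than `min_run_samples`
(10 samples ≈ 1 µm at defaults) are dropped; runs are circular. This makes
the usual by-eye shading of enriched regions explicit and testable.
Swapping the channels provably swaps the labels.

Per class we pool the smoothed $|\kappa|$ values and report median,
quartiles and the fraction below a cutoff (default 0.2 µm⁻¹, the reported
flat-membrane preference threshold for spectrin). A two-sided Wilcoxon
rank-sum test plus a rank-biserial effect size compares the class
distributions; this test is descriptive support chosen by this package,
not a claim inherited from any particular study.

# Deformability cytometry

DI = H/W, where H and W are the pixel extents (max − min + 1) of the
segmented cell along the declared outflow and inflow axes, reported at the
frame that maximizes DI during a transit. Extent counting with sub-pixel
cell placement is an unbiased estimator of the diameter, and the half-pixel
end effects largely cancel in the ratio. Frames are gated on contrast
(peak background difference at least 8 noise MADs) before Otsu
thresholding — without the gate, Otsu happily "detects" structure in
noise-only separator frames and merges adjacent transits, which both loses
cells and biases mean DI upward (we measured +0.05–0.1 before gating).
Runs of consecutive detections form transits (dilute suspension, one cell
at a time); single-frame transits are accepted but flagged.

# Densitometry and binding ratio

ROIs (rectangles or discs) are integrated after background subtraction:
either the median of a border ring around the ROI (default) or a
rolling-ball grayscale opening. Negative net intensities are clamped to
zero and flagged. The sedimentation bound fraction is

$$\text{ratio} = \frac{B}{B + d\,U},$$

with B and U the integrated bound/unbound lane intensities as loaded and
d the dilution factor applied to the unbound fraction before loading —
the only dimensionally consistent bound fraction using a dilution factor
on U. The ratio is exactly invariant to common intensity scaling and
monotone in each argument. Strip spots are blank-subtracted and scaled to
the maximum spot. Whether published "relative binding ratios" were further
normalized across bead sizes is not stated in our sources; we output the
raw bound fraction and an optional column normalized to a chosen lane.

# SSLB assay design

Membrane curvature of a bead is κ = 1/r = 2/d (66.7 µm⁻¹ at 30 nm;
2 µm⁻¹ at 2000 nm). For uniform spheres of equal density, total surface
area per unit mass scales as 1/d, so equal-area masses follow
mass = ref_mass × d/d_ref: from 2 mg of 1000 nm beads, 200 µg (100 nm),
100 µg (50 nm), 60 µg (30 nm). Note that the κ = 2/d convention gives
2 µm⁻¹ for a 1000 nm bead; a figure of ~0.5 µm⁻¹ sometimes quoted for
micron-scale beads is inconsistent with the convention that yields
66.7 µm⁻¹ at 30 nm, and this package uses 2/d throughout.
`lipid_mix_masses()` converts molar mixing ratios (e.g. DOPC : DOPE :
cholesterol : PtdIns(4,5)P₂ at 4 : 4 : 1 : 1) into per-component masses.

# The synthetic world

Generators are pure functions of a spec plus a seed (byte-identical
reruns) and return complete ground truth.

## Phantom cells

The outline is a star-shaped radial curve
$r(\theta) = R_0\,(1 + \sum_k a_k \cos(k\theta + \phi_k)) + \text{bumps}$,
always simple, with exact curvature from the polar formula. The spectrin
boundary response is logistic in curvature magnitude,
$S = 1/(1 + e^{\beta(|\kappa| - \kappa_0)})$, with actin its complement
$A = 1 - S$; the hard indicator is the $\beta \to \infty$ limit. The
default steepness is $\beta = 6/\kappa_0$: a fixed *relative* transition
width, so $\kappa_0$ remains a genuine threshold whether it is 0.1 or
0.5 µm⁻¹ (a fixed absolute width would smear a 0.1 µm⁻¹ threshold into
no threshold at all). Channels are painted as a cortical band just inside
the outline (cytoplasmic fill 0.5 for the spectrin channel so segmentation
sees the whole cell; faint 0.08 fill for actin) plus Gaussian noise at
amplitude 1/SNR.

Default geometry (chosen once, before the validation suite was frozen, and
verified stable on an independent seed set): R₀ = 13 µm (cells ~26 µm
across), gentle elongation modes k = 2, 4, a dominant 6-fold lobe mode
whose first-order curvature amplitude is drawn per cell from
U(0.5, 0.75) µm⁻¹, and 4–6 protrusions of length 2.5–5 µm and angular
width 0.10–0.22 rad (tip radii down to ~1 µm). The rationale: recovering
an exclusion threshold from the 90th percentile of the spectrin-class
$|\kappa|$ distribution requires the boundary to *cover* curvature
densely from ~0 up past the probed threshold. Lamellipodial lobes supply
the 0.1–0.5 µm⁻¹ range (cell-to-cell amplitude variation spreads the
coverage), protrusion tips supply |κ| ≳ 0.7 anchors for the actin class,
and flat inter-lobe arcs supply |κ| ≈ 0. Protrusion widths are bounded
below so that enriched tip arcs exceed the classifier's 1 µm minimum run
length — sub-resolution features are invisible to the band-sampled
profiles and would only produce unclassifiable slivers, as in real images.
What a green phantom test does *not* establish: performance under optical
blur (no PSF model), uneven illumination, cytoplasmic texture,
multi-cell scenes, or segmentation of dim/low-contrast cells.

## Deformation videos

Each cell transits as a short run of area-preserving ellipse frames whose
DI ramps up to a per-cell true peak (Normal(mean DI(Q), sd), truncated at
DI ≥ 1) and back down, separated by blank frames. The default curve
DI(Q) = 1 + 0.04 Q over Q = 5–25 µL min⁻¹ spans ~1.2 to 2.0, the range
typical of soft-cell deformability experiments; the default 200 cells per
flow rate sits inside the 85–515 cells per experiment reported for such
assays, with 10 % size jitter and pixel noise 0.05. Sub-pixel center
jitter makes extent measurements unbiased; the option
`subpixel_jitter = FALSE` places centers on pixel corners so integer
semi-axes yield mathematically exact extents, which the noise-free
recovery tests exploit.

## Gels and strips

Gaussian bands/spots with programmed integrated volumes on a flat
background. Gel noise is referenced to the *faintest* nonzero band, so a
requested SNR holds for every quantified band; the ROI templates span
±2σ, which captures the same fraction of every band and therefore cancels
exactly in the binding ratio.

# Numerical choices and degenerate inputs

* Windows given in µm are rounded to odd sample counts (minimum one
  sample).
* A constant intensity profile normalizes to 0.5 everywhere with a
  warning; empty enrichment classes yield NA summaries rather than errors;
  classes with fewer than 3 samples make the rank-sum comparison NA with a
  warning.
* Self-intersecting input polygons warn and proceed (segmentation can
  produce touching protrusions); fewer than 3 distinct points is an error.
* Background exceeding signal clamps integrated intensities at 0 with a
  flag; B = U = 0 makes the binding ratio an error, d < 1 is a config
  error.
* Pipelines signal `curvassay_config_error` / `curvassay_data_error`
  conditions, which the CLI maps to exit codes 2 / 1.

# Known limitations

* 2D outline curvature only; no 3D membrane (mean/Gaussian) curvature.
* One cell per analysis ROI; no deconvolution or flat-fielding beyond
  constant background subtraction.
* No TIFF image I/O in this R stack: quantitative interchange uses CSV
  matrices; PGM and PNG are supported for visualization.
* The deformability module does not model hydrodynamic stress or extract
  elastic moduli; DI is a relative stiffness readout.
* Densitometry assumes an approximately flat local background and
  unsaturated detection.
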