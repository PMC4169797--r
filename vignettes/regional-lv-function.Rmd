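---
title: "Regional LV function: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional LV function: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvregional)
```

# What the package computes

After an acute anterior myocardial infarction, regional left-ventricular
function changes differently in the ischemic territory, in the segments
adjacent to it, and in remote myocardium. The package implements the full
measurement chain used to quantify this in an ischemia–reperfusion
experiment:

1. **Wall thickening** — centerline wall thickness from endo-/epicardial
   contours on a short-axis cine stack; `WT = ES − ED` thickness per chord,
   `FWT = WT / ED` thickness; cavity volumes, EF, cardiac output and LV mass
   by slice summation.
2. **Velocity-encoded strain** — material points segmented at end diastole
   are tracked through 2D in-plane velocity images of the 2-, 3- and
   4-chamber planes; Lagrangian radial and longitudinal strain
   `(L(t) − L(0)) / L(0)` is evaluated per wall element and summarized at end
   systole.
3. **AHA-17 mapping** — all regional quantities are reduced to the standard
   6 basal + 6 mid + 4 apical segments + apical cap.
4. **Territory classification** — the perfusion defect (area at risk, AAR)
   is all myocardium below 50% of the maximum counts; a segment is
   *ischemic* if more than half of it lies in the defect, *adjacent* if any
   of it does (up to half), *remote* if none does. Myocardial salvage index
   is `MSI = 1 − infarct size / AAR`.
5. **Statistics** — paired t (regional function) and Wilcoxon signed-rank
   (global hemodynamics) tests at α = 0.05, and ROC threshold scans (1000
   steps from the minimum to the maximum of each metric) to find cutoffs
   separating the three territories.

No imaging data are deposited with the experiment the package emulates, so
all stages are validated against an **analytic phantom** with closed-form
ground truth, plus a segment-level statistical generator that reproduces the
published class means.

# The deforming-LV phantom

## Geometry

The LV is a truncated prolate half-ellipsoid treated as a stack of circular
annuli. With apex-to-base fraction $u \in [0,1]$ ($u=0$ apex tip, $u=1$
base) and long-axis length $L$, the end-diastolic endocardial radius is

$$ r_\mathrm{endo}(u) = R_\mathrm{endo}\sqrt{2u - u^2}, $$

the equatorial profile of an ellipsoid with semi-axes
$(R_\mathrm{endo}, R_\mathrm{endo}, L)$. The epicardium keeps a constant
wall cross-section per slice,

$$ r_\mathrm{epi}^2(u,t) - r_\mathrm{endo}^2(u,t) =
   R_\mathrm{epi}^2 - R_\mathrm{endo}^2 \equiv C, $$

at *all* positions and times: the wall is incompressible in the imaging
plane. This makes thickness, volumes and radial strain available in closed
form everywhere, including the apex (where the wall thins toward
$\sqrt{C}$ total thickness but never vanishes).

Defaults — $R_\mathrm{endo} = 20$ mm, $R_\mathrm{epi} = 28$ mm, $L = 80$ mm —
give an ED cavity volume of $\tfrac{2}{3}\pi R_\mathrm{endo}^2 L = 67$ ml,
an 8 mm equatorial wall and a 97 ml myocardial volume: porcine scale, chosen
once to sit near the published group means (EDV 82 ml, mass 86 ml) while
keeping round numbers for the closed forms.

## Motion

Systole scales the endocardial radius by a smooth sinusoidal factor
$s(t) = 1 - m\,(1-f)\,\beta(t)$ with
$\beta(t) = \tfrac12(1 - \cos 2\pi t/T)$, where $f$ is the ES endocardial
fraction (default 0.8) and $m$ the local **dysfunction multiplier** (1 =
full contraction, < 1 hypokinetic, 0 akinetic; applied inside the perfusion
defect). A material ring at ED radius $\rho$ moves to

$$ r(\rho, t) = \sqrt{\rho^2 + \left(s^2(t) - 1\right) r_\mathrm{endo}^2(u)},$$

which conserves the annulus area between the endocardium and every material
circle. The long axis shortens affinely toward the (fixed) apex:
$z(t) = z_0\,(1 - \lambda(t))$, $\lambda(t) = \Lambda\,\beta(t)$ with
$\Lambda = 0.1$ by default. Worked example: a 20 mm endocardium contracting
to 15 mm inside a 30 mm epicardium gives an ES epicardial radius of
$\sqrt{15^2 + (30^2 - 20^2)} = \sqrt{725} \approx 26.93$ mm — the wall
thickens from 10 mm to 11.93 mm while the cavity shrinks.

Two modeling consequences are deliberate:

* the dysfunction multiplier acts on the **radial** contraction only;
  longitudinal shortening stays global, so the Eulerian velocity field can
  be inverted from pixel position to material slice in closed form;
* wall cross-sectional area is conserved even in dysfunctional regions
  (reduced endocardial excursion with an incompressible wall), which is also
  how a stunned wall fails to thicken.

## Velocity fields

Because the motion is differentiable, the in-plane velocity on a long-axis
plane (signed distance $x$ from the long axis, height $z$) is exact:

$$ v_x = \frac{s\,\dot s\, r_\mathrm{endo}^2(u_0)}{x}, \qquad
   v_z = -\frac{z\,\dot\lambda}{1-\lambda}, \qquad
   u_0 = \frac{z}{L\,(1-\lambda)} . $$

The $1/x$ factor is regularized linearly within half a pixel of the long
axis; the analytic extension of the field into the cavity is *not* a blood
pool model — it only keeps interpolation consistent near the endocardial
border. Rasters default to 1.6 mm pixels, 20 frames over a 1 s cycle, and
are written with a venc of 20 cm/s recorded in the sidecar (peak tissue
speeds at the default geometry are ≈ 2–14 cm/s, safely inside it). Optional
additive Gaussian velocity noise (cm/s) is off by default.

## What the phantom does not emulate

MR physics (phase wrap, eddy currents, partial volume), speckle and texture,
papillary muscles (contours arrive papillary-free), the right ventricle,
through-plane motion in the velocity rasters, and inter-subject anatomical
variability. Passing the phantom suites therefore demonstrates the
correctness of the *measurement chain*, not robustness to acquisition
artifacts in real data.

# Measurement chain: numerical choices

**Centerline thickness.** Rays are cast from the midpoint of the endo- and
epicardial vertex centroids at 80 equally spaced azimuths per slice (the
experiment names no chord count; 80 makes concentric-circle thickness exact
to < 0.1%). Contours are validated for simplicity and containment; rays
passing exactly through a polygon vertex are accepted with a 1e-9 edge
tolerance. ED is frame 1; ES is the frame of minimum summed cavity area.

**Basal-slice rule.** The most basal analyzable slice is the most basal one
showing myocardium over the full circumference at ES; more basal slices are
excluded. With longitudinal shortening on, this truncates a basal slab, so
measured cavity volumes systematically undershoot the analytic ellipsoid
volume — the same long-axis-motion limitation the source experiment reports.
The 2% volume validation is therefore run with shortening off.

**Tracking.** Fourth-order Runge–Kutta over each frame interval (2 substeps
by default) with bilinear spatial and linear temporal interpolation, periodic
in the cycle. The cycle-closure residual of each trajectory is redistributed
linearly over the frames — the published tracking uses an unspecified
optimization scheme; linear drift redistribution is the standard
velocity-field variant and the pre-correction drift is kept for QC. On the
analytic field the drift is ≈ 1e-7 mm and tracked ES positions are within
0.1 mm of the analytic motion at 20 frames/cycle.

**Strain elements.** Radial elements pair each endocardial point with the
epicardial point at the same level along the long axis ("slice" pairing), so
the element measures the in-plane thickness change that defines the
closed-form radial strain; pairing along the tilted geometric wall normal is
available as an option but mixes longitudinal geometry into the radial
reading near the apex (up to ≈ 0.02 strain on the default phantom).
Longitudinal elements join consecutive boundary points; near the apex the
boundary chain itself tilts toward the in-plane radial direction, so
measured longitudinal strain picks up some radial contraction there even
when $\Lambda = 0$ — a geometric property of boundary-chain strain, kept
because real contour chains behave the same way. Elements with reference
length below 0.5 mm are excluded. Summary strain is taken at ES (the
wall-thickening phase), not peak-over-time, for determinism.

**AHA mapping.** Azimuth origin at the anterior wall, increasing toward the
septum. Longitudinal thirds give the basal/mid/apical rings; $u < 1/6$ is
the apical cap. Long-axis planes sit at fixed azimuths chosen to hit the
standard segment pairs: 2-chamber 0°/180° (anterior/inferior), 3-chamber
60°/240° (anteroseptal/inferolateral), 4-chamber 120°/300°
(inferoseptal/anterolateral). Polar rasters default to 36 azimuth × 20
apex-base bins with equal pixel weights (no sector-area weighting),
mirroring polar-plot-based quantification.

**Classification.** "1–50% ischemic" is read as the half-open interval
(0, 0.5]: a segment with more ischemic than non-ischemic myocardium is
ischemic, any other segment containing ischemia is adjacent, a segment with
none is remote. Boundary behavior (0, 0.5, 0.5 + ε) is unit-tested.

**ROC.** 1000 equally spaced thresholds from the metric minimum to maximum;
a value strictly below (wall thickening, radial strain) or strictly above
(longitudinal strain) the cutoff is called ischemic, with directions
reversed for the remote comparison. The optimum maximizes the Youden index;
ties break toward higher specificity, then toward the middle of the tied
run. The scan is verified against an exhaustive midpoint oracle and an
independent ROC package. Adjacent segments are called by the band strictly
between the two binary optima; its sensitivity is expected to be poor — the
middle of three overlapping classes — matching the published finding.
Segments are pooled across subjects with no within-subject clustering
correction (none is described for the source analysis).

# The segment-level generator

Per-segment measurements are drawn independently per subject × segment ×
phase from class-conditional normal distributions. Defaults encode the
published class means for wall thickening (2.7 → 0.65 mm ischemic,
2.4 → 1.5 mm adjacent, 2.4 → 2.8 mm remote). Per-segment standard
deviations are not published; 0.5 mm (thickening) and 0.05 (strain) are used
— SEM-scale variability consistent with the reported group statistics — and
are configurable. Strain means are likewise not printed: the defaults
(radial 0.17 pre everywhere, 0.03/0.10/0.20 post; longitudinal −0.09 pre,
−0.02/−0.055/−0.09 post) are chosen once to respect the published ordering
and the threshold-band structure (ischemic < adjacent < remote for radial
strain, the reverse in magnitude for longitudinal). Class labels follow a
fixed anterior-first priority list (LAD territory) unless explicit labels
are supplied. The default class split 5/5/7 reflects a distal-LAD occlusion.

The default phantom defect spans 120° around the anterior wall over the
apical 60% of the long axis (20% of the polar domain) with counts at 30% of
maximum; the nested infarct (same 120°, apical 50%, transmurality 0.9)
yields an infarct of 15% of LV and `MSI = 1 − 15/20 = 0.25`, the published
mean salvage (25 ± 15%). The AAR itself is not published; the defect size is
a realistic distal-LAD area at risk.

# Problem sizes and determinism

The validation suites run the phantom at 20 frames/cycle, 1.6 mm velocity
pixels, 120 contour vertices and 80 chords; sweep-style checks (thickening
vs strain across dysfunction levels, end-to-end pipeline tests) use reduced
settings (10–12 frames, 2.5 mm pixels, 36–48 chords) — sizes at which every
closed-form check still resolves, chosen so the whole suite runs in well
under a minute per file. All stochastic steps take explicit integer seeds;
`run_pipeline()` derives stage seeds from one master seed and identical
configurations produce byte-identical outputs.

# Known limitations

* Cavity volumes inherit the basal-truncation bias whenever longitudinal
  shortening is on (by design, matching the measurement convention).
* Measured longitudinal strain near the apex mixes in radial contraction
  (boundary-chain geometry); the apical cap value should be read with that
  in mind.
* The published per-animal variability cannot be reproduced: no per-segment
  spread is printed, so cohort-level sensitivities/specificities from the
  generator depend on the assumed SDs and are structural (ordering, band
  shape) rather than numerical reproductions.
* Circumferential strain is out of scope: the velocity data live on
  long-axis planes, giving radial and longitudinal components only.
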