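---
title: "Quantifying tumor-vessel circumferential involvement and staging resectability"
author: "VesselContact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-vessel circumferential involvement and staging resectability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VesselContact)
```

## The measurement problem

Whether a pancreatic ductal adenocarcinoma (PDAC) can be resected depends on
how far it wraps around five peripancreatic vessels: the celiac trunk
(CeTr), hepatic artery (HA), superior mesenteric artery (SMA), superior
mesenteric vein (SMV) and portal vein (PV). Radiologists express this as a
circumferential contact angle and grade it in five groups (0, 0–90, 90–180,
180–270, 270–360 degrees); resectability guidelines such as those of the
Dutch Pancreatic Cancer Group (DPCG) then map per-vessel contact to a stage:
resectable, borderline resectable, or locally advanced.

`VesselContact` automates that measurement from a 3D multi-label
segmentation volume (NIfTI), produced by any segmentation source. It does
not segment; it consumes label masks.

## The measure

For one vessel, every plane orthogonal to each of the three grid axes that
contains both the vessel and the tumor is examined. Within a plane, each
connected cross-section of the vessel (8-connectivity; components under
4 pixels are ignored as measurement noise) contributes

$$\mathrm{degrees} \;=\; \frac{TV}{V}\,\times\,360,$$

where $V$ is the physical length (mm) of the cross-section's outer boundary
and $TV$ the portion of that boundary adjacent to tumor pixels. The
reported value per vessel is the maximum over all components of all planes,
together with the plane attaining it. A vessel never co-occurring with the
tumor scores 0.

Two formula modes exist. The default is the geometric fraction above. A
`"literal"` mode evaluates $TV/(TV+(TV-V))\times360$, the expression as it
appears in print in the method's source description; that expression is
undefined at $TV = V/2$ (zero denominator) and negative below, while its
output range is stated as 0–360 and its worked example (89° for a
sub-quarter arterial contact) is only consistent with the fraction reading.
The literal mode is therefore retained for transparency only and raises a
documented error at its degenerate point.

### Perimeter and contact estimation

* **Outer contour.** The component mask is hole-filled and its 0.5
  iso-level contour extracted (marching squares on the zero-padded mask),
  giving a closed sub-pixel polygon whose vertices sit on pixel-edge
  midpoints. Hole filling implements the convention that the circumference
  of a vessel segment is its *outer* boundary.
* **Staircase correction.** The raw mid-crack polygon overestimates smooth
  boundaries (digital disks by 6–14% at radii 5–50 px). Vertices are
  smoothed with a circular moving average (window 5), after which disk
  perimeters are within about 1% of $2\pi r$ across that radius range. The
  window is a documented constant; windows of 3 undercorrect (~1–4% high)
  and 7 overcorrect small components (~2% low).
* **Contact classification.** Each raw contour segment separates exactly
  one vessel pixel from one outside pixel. Under the default `"face"` rule
  a segment is in contact when that outside pixel carries the tumor label.
  An alternative `"diagonal"` rule also accepts segments whose outside
  pixel is background while the vessel boundary pixel has tumor in its
  8-neighbourhood; this tolerates single-pixel stair-stepping in real
  masks, but extends measured arcs by about one boundary pixel per end
  (at a 10 px vessel radius that is ~11° of inflation at worst, enough to
  push a 225° wrap above a 235° reading), so face adjacency is the
  default. Both $TV$ and $V$ are summed from the same smoothed polygon, so
  the ratio benefits from cancellation of any residual orientation-
  dependent bias; $TV \le V$ holds structurally.
* **Image borders.** Boundary running along the image edge counts toward
  $V$ but can never be contact; the report carries a warning when this
  occurs.

### Binning and staging

Exact zero maps to the dedicated "0" group; positive values fall in
right-closed intervals, so 90 maps to "0–90" and 90.001 to "90–180". The
same right-closed convention is used by the staging rule tables, making 90°
arterial contact borderline resectable rather than locally advanced. The
bundled DPCG encoding is: arterial contact 0 compatible with resectable,
(0, 90] borderline, >90 locally advanced; venous contact ≤90 resectable,
(90, 270] borderline, >270 locally advanced. The case stage is the worst
stage over vessels, with the driving vessels reported as the decision
trace. The exact cut-offs ship as an editable YAML
(`extdata/dpcg_default.yaml`) because published criteria revisions can be
accommodated without touching code; validation rejects tables with gaps or
overlap. Occlusion and stenosis modifiers present in the full DPCG/NCCN
criteria carry no signal in a label mask and are deliberately not
evaluated; every staging result carries a fixed caveat saying so.

## The phantom harness

All validation runs on synthetic phantoms with analytically known wrap
angles; no clinical data is required.

```{r phantom}
ph <- makeWrapPhantom(90, shape = c(48L, 48L, 48L), wrapExtent = 8L)
quantifyVessel(ph$volume, "SMA")
truthStage(ph$truth)
```

The default geometry — 96³ voxels at 0.5 mm isotropic, vessel radius 5 mm,
tumor shell 3 mm, wrap extent 10 slices (5 mm) — emulates the SMA caliber
at CT-like resolution and runs in under a second per phantom. The tumor
sector is grown outward from the analytic vessel surface, so abutment holds
at every wrapped angular position; a zero wrap instead places a detached
tumor ball 2 mm clear of the vessel so that co-occurring planes exist but no
contact does. Tubes are inset 2 mm from the volume faces so phantom vessels
never touch the image border.

**Why the wrap is short relative to the tube.** The quantifier maximizes
over *all* grid-axis planes. A longitudinal plane grazing the wrapped arc
sees contact of roughly the wrap length $L_w$ against a perimeter of
roughly twice the tube length $L_v$, i.e. about $360\,L_w/(2 L_v)$ degrees
— independent of the true wrap angle. For the plane-sweep maximum to equal
the cross-sectional angle down to a smallest angle of interest
$\theta_{\min}$, the geometry must satisfy
$L_w < L_v\,\theta_{\min}/180$. With the 5 mm default wrap against the
~44 mm tube this floor sits near 22°, below the smallest validated angle
(30°). A 10 mm wrap would raise the floor to ~38° and make small wrap
angles unrecoverable in this volume — a genuine property of the
max-over-planes measure, not an implementation artifact, and the reason
thin, longitudinally extended contact can read high on real data too.

**Jitter.** With `jitter = TRUE`, every voxel on the in-plane 8-boundary of
the tumor shell (either side, never inside a vessel) toggles membership
with probability 0.1 under a caller-supplied seed. This emulates
segmentation noise amplitude-wise (~1 voxel surface roughness) while
leaving the analytic wrap angle within the binning tolerance. It does not
emulate the structured failure modes of real segmentation — dropout of a
vein near the tumor, label leakage between touching structures, or
systematic over-segmentation — so passing phantom tests bounds
discretization and noise-robustness error, not clinical accuracy.

**Curved vessels.** `makeCurvedVesselPhantom()` bends the tube into a helix
whose amplitude ramps smoothly to zero around the wrap window, keeping the
wrapped sub-segment straight and its ground truth analytic. Recovery there
is validated to a relaxed ±15°, reflecting the known weakness of a
circumference-based (rather than centerline-based) measure under vascular
deformation.

## Numerical choices

* Axes and slice indices are 1-based everywhere, matching the host
  language; the in-plane spacing of a plane is the pair of volume spacings
  of the two remaining axes in ascending order.
* The grid is used exactly as stored — no reorientation. Because all three
  axes are swept and the degree is a within-plane ratio, 90° grid
  rotations change the result only through floating-point summation order
  (validated ≤ 2°, observed 0).
* Label values are matched exactly; files with non-integer voxels are
  rejected rather than rounded.
* Components below 4 pixels are ignored by default: a 2-pixel speck has a
  contour but no meaningful circumference.
* Ties between planes resolve to the first plane encountered
  (axis 1 → 2 → 3, ascending index); only the reported argmax plane, not
  the maximum value, depends on this.
* Quantile convention for the per-group summaries is linear interpolation
  between order statistics (`stats::quantile` type 7); the convention used
  by the source publication's table is unstated, so this is a documented
  package choice.
* One-way ANOVA is the classical between/within decomposition
  (`stats::lm`/`anova`); zero within-group variance with unequal means is
  reported as $F = \infty$, $p = 0$ rather than an error. The conventional
  0.05 significance threshold is reported alongside, never hard-coded into
  a decision.

## Problem sizes used in validation

The shipped test-and-validation runs use: the nine-angle sweep
{30, 60, …, 360}° at 96³/0.5 mm and 192³/0.25 mm; digital disks of radius
5–50 px; the full 5⁵ = 3125-combination staging truth table against an
independent brute-force evaluator; three axis permutations; and 50 seeded
jittered phantoms spanning all five categories, scored for category and
stage agreement. These sizes keep a full run within a few minutes on one
CPU while exercising every code path; larger sweeps change none of the
reported error bounds in exploratory runs.

## Known limitations

* The measure follows the vessel's cross-section circumference, not a
  centerline; oblique or deformed vessels can read high (the curved-phantom
  tolerance quantifies this for gentle curvature only).
* Stenosis/occlusion — which guidelines treat as maximal involvement
  regardless of measured contact — is out of scope for a label-mask input.
* Thin but longitudinally extended contact inflates the plane-sweep
  maximum (see the wrap-length constraint above); interpreting small
  angles on elongated contact regions warrants inspecting the argmax plane
  the report provides.
* Phantom validation bounds geometric and noise error; it cannot stand in
  for evaluation against expert readings on clinical CTs.
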