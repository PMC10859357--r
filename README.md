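# VesselContact

Automated quantification of tumor–vessel circumferential involvement and
rule-based resectability staging for pancreatic cancer, from 3D
multi-label segmentation volumes.

## The problem

Resectability of pancreatic ductal adenocarcinoma (PDAC) hinges on how far
the tumor wraps around five peripancreatic vessels — celiac trunk (CeTr),
hepatic artery (HA), superior mesenteric artery (SMA), superior mesenteric
vein (SMV) and portal vein (PV). Radiologists read this off CT as a
contact angle, grade it in five groups (0, 0–90, 90–180, 180–270,
270–360°), and apply guideline criteria (here, the Dutch Pancreatic Cancer
Group scheme) to call the case resectable, borderline resectable, or
locally advanced. The reading is subjective and shows substantial
inter-observer variability.

`VesselContact` computes the same quantity automatically from a
segmentation label mask (NIfTI, from any segmentation source — this
package does not segment). For each vessel it sweeps **every plane along
all three grid axes** that contains both the vessel and the tumor; in each
plane it measures, per connected vessel cross-section, the outer-boundary
circumference *V* (mm, sub-pixel contour with staircase correction) and
the tumor-contact length *TV* (mm), converts the pair to degrees

&nbsp;&nbsp;&nbsp;&nbsp;degrees = (TV / V) × 360,

and reports the **maximum over all planes** with the plane that attains
it. Per-vessel degrees are binned into the five radiological groups and
mapped to a case stage by a configurable rule table (worst vessel wins,
with a decision trace). A synthetic phantom generator with analytically
known wrap angles makes the whole pipeline testable without clinical
data, and evaluation utilities (categorical agreement, per-group
median/IQR summaries, one-way ANOVA) reproduce the standard comparison
computations against rater categories.

## Worked example

A phantom volume (96³ voxels, 0.5 mm) holding all five vessels, with a 45°
wrap on the hepatic artery and a 200° wrap on the superior mesenteric
vein:

```r
library(VesselContact)

ph  <- makeMultiVesselPhantom(c(CeTr = 0, HA = 45, SMA = 0, SMV = 200, PV = 0))
rep <- quantifyVolume(ph$volume)
involvementTable(rep)[, 1:7]
#>   vessel max_degrees category axis index circumference_V_mm contact_TV_mm
#> 1   CeTr        0.00        0    2    33              96.08         0.000
#> 2     HA       45.84     0-90    3    44              31.43         4.001
#> 3    SMA        0.00        0    2    63              92.08         0.000
#> 4    SMV      201.35  180-270    3    44              31.43        17.576
#> 5     PV        0.00        0    2    39              92.08         0.000

classifyStage(rep)
#> Resectability stage: borderline_resectable
#>   driven by: HA, SMV
```

The HA wrap of 45° is recovered at 45.8° on an axial plane (axis 3,
slice 44) where the vessel cross-section's circumference is 31.4 mm and
4.0 mm of it touches tumor; the SMV's 200° wrap reads 201.4°. Under the
DPCG table, arterial contact in (0, 90] and venous contact in (90, 270]
are both borderline-grade, so the case stage is borderline resectable,
driven by HA and SMV. Clinical volumes are loaded with
`readLabelVolume("scan.nii.gz", "labels.yaml")`, and a thin CLI
(`inst/cli/vesselcontact`) exposes `quantify`, `stage`, `make-phantom` and
`evaluate` subcommands.

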