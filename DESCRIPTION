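Package: VesselContact
Title: Tumor-Vessel Circumferential Involvement and Resectability Staging
        from 3D Label Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Quantifies the circumferential involvement (contact angle in
        degrees, 0-360) of peripancreatic vessels by a pancreatic tumor from
        3D multi-label segmentation volumes, by sweeping all grid-axis planes
        that contain both structures, measuring each vessel cross-section's
        perimeter and tumor-contact length with a sub-pixel contour method,
        and taking the maximum degree over all planes. Maps the per-vessel
        degrees to a resectability stage (resectable, borderline resectable,
        locally advanced) through a configurable rule table following the
        Dutch Pancreatic Cancer Group criteria. Includes a synthetic phantom
        generator with analytically known wrap angles for end-to-end
        validation, and evaluation utilities (categorical agreement,
        per-group degree summaries, one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, grDevices, utils, RNifti, yaml, jsonlite, EBImage
Suggests: testthat (>= 3.0.0), optparse
biocViews: Software, BiomedicalInformatics, ImageSegmentation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
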