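# Default resectability rule table following the Dutch Pancreatic Cancer
# Group (DPCG) criteria, expressed on the circumferential involvement degree
# scale (0-360). Intervals are right-closed; a lower bound of 0 also admits
# exactly 0, and [0, 0] is the exact-zero singleton. Occlusion/stenosis
# modifiers are not representable in a label mask and are not encoded here.
vessel_classes:
  CeTr: arterial
  HA: arterial
  SMA: arterial
  SMV: venous
  PV: venous
arterial_stages:
  resectable: [0, 0]
  borderline_resectable: [0, 90]
  locally_advanced: [90, 360]
venous_stages:
  resectable: [0, 90]
  borderline_resectable: [90, 270]
  locally_advanced: [270, 360]
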