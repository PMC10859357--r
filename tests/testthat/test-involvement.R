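test_that("degree formula: fraction mode is proportional, literal mode is
           the printed expression with its degenerate point", {
  expect_equal(involvementDegree(c(0, 2.5, 5, 7.5, 10), 10),
               c(0, 90, 180, 270, 360))
  expect_equal(involvementDegree(0, 7), 0)
  expect_equal(involvementDegree(7, 7), 360)
  # literal agrees with fraction at the anchors TV = 0 and TV = V
  expect_equal(involvementDegree(0, 10, mode = "literal"), 0)
  expect_equal(involvementDegree(10, 10, mode = "literal"), 360)
  expect_error(involvementDegree(5, 10, mode = "literal"), "degenerate")
  expect_error(involvementDegree(1, 0), "circumference")
  expect_error(involvementDegree(11, 10), "TV")
})

test_that("binning follows the right-closed five-group convention", {
  expect_equal(binDegree(89), "0-90")
  expect_equal(binDegree(0), "0")
  expect_equal(binDegree(c(1e-9, 90, 90.001, 180, 270, 270.001, 360)),
               c("0-90", "0-90", "90-180", "90-180", "180-270", "270-360",
                 "270-360"))
  expect_error(binDegree(-1), "0, 360")
  expect_error(binDegree(361), "0, 360")
})

test_that("quantifyVessel recovers a 90-degree wrap on a phantom", {
  ph <- makeWrapPhantom(90, shape = c(64L, 64L, 48L), wrapExtent = 8L)
  vi <- quantifyVessel(ph$volume, "SMA")
  expect_lt(abs(maxDegrees(vi) - 90), 10)
  expect_true(involvementCategory(vi) %in% c("0-90", "90-180"))
  expect_equal(involvementCategory(vi), binDegree(maxDegrees(vi)))
  tab <- involvementTable(vi)
  expect_lte(tab$contact_TV_mm, tab$circumference_V_mm)
  expect_false(tab$absent)
})

test_that("no contact and full encasement hit the scale ends", {
  ph0 <- makeWrapPhantom(0, shape = c(64L, 64L, 48L), wrapExtent = 8L)
  vi0 <- quantifyVessel(ph0$volume, "SMA")
  expect_equal(maxDegrees(vi0), 0)
  expect_equal(involvementCategory(vi0), "0")

  ph360 <- makeWrapPhantom(360, shape = c(64L, 64L, 48L), wrapExtent = 8L)
  vi360 <- quantifyVessel(ph360$volume, "SMA")
  expect_equal(maxDegrees(vi360), 360, tolerance = 1e-6)
  expect_equal(involvementCategory(vi360), "270-360")
})

test_that("measured wrap angle is monotone in the true angle", {
  sz <- c(64L, 64L, 48L)
  meas <- vapply(c(60, 120, 240), function(th)
    maxDegrees(quantifyVessel(makeWrapPhantom(th, shape = sz,
                                              wrapExtent = 8L)$volume,
                              "SMA")), numeric(1))
  expect_true(all(diff(meas) >= -2))  # 2 degrees discretization slack
})

test_that("quantifyVolume reports all five vessels and flags absences", {
  ph <- makeMultiVesselPhantom(c(CeTr = 0, HA = 0, SMA = 90, SMV = 270,
                                 PV = 0))
  rep <- quantifyVolume(ph$volume)
  tab <- involvementTable(rep)
  expect_setequal(tab$vessel, vesselNames())
  expect_lt(abs(tab$max_degrees[tab$vessel == "SMA"] - 90), 10)
  expect_lt(abs(tab$max_degrees[tab$vessel == "SMV"] - 270), 10)
  expect_equal(tab$max_degrees[tab$vessel %in% c("CeTr", "HA", "PV")],
               rep(0, 3))
  expect_false(any(tab$absent))

  # control volume: no tumor voxels anywhere
  vox <- voxels(ph$volume)
  vox[vox == 1L] <- 0L
  ctrl <- LabelVolume(vox, spacing(ph$volume), labelMap(ph$volume))
  tab0 <- involvementTable(quantifyVolume(ctrl))
  expect_equal(tab0$max_degrees, rep(0, 5))
  expect_equal(tab0$category, rep("0", 5))
})

test_that("a vessel with no voxels is flagged absent, others measured", {
  ph <- makeWrapPhantom(120, shape = c(64L, 64L, 48L), wrapExtent = 8L)
  vox <- voxels(ph$volume)  # contains tumor + SMA only
  vol <- LabelVolume(vox, spacing(ph$volume), labelMap(ph$volume))
  tab <- involvementTable(quantifyVolume(vol))
  expect_true(all(tab$absent[tab$vessel != "SMA"]))
  expect_false(tab$absent[tab$vessel == "SMA"])
  expect_lt(abs(tab$max_degrees[tab$vessel == "SMA"] - 120), 15)
  pv <- tab[tab$vessel == "PV", ]
  expect_equal(pv$max_degrees, 0)
  expect_true(is.na(pv$axis))
})

test_that("vessel at the image border is measured with a warning and
           border boundary never counts as contact", {
  vox <- array(0L, c(20, 20, 8))
  vox[1:6, 8:13, 3:6] <- 4L       # vessel block touching the x = 1 face
  vox[7:9, 8:13, 3:6] <- 1L       # tumor on the interior side
  vol <- LabelVolume(vox, rep(1, 3), defaultLabelMap())
  vi <- quantifyVessel(vol, "SMA")
  expect_match(paste(involvementTable(vi)$warnings, collapse = " "),
               "border")
  expect_gt(maxDegrees(vi), 0)
  expect_lt(maxDegrees(vi), 360)
  tab <- involvementTable(vi)
  expect_lte(tab$contact_TV_mm, tab$circumference_V_mm)
})

test_that("involvement report writes JSON and CSV views", {
  ph <- makeMultiVesselPhantom(c(CeTr = 0, HA = 0, SMA = 90, SMV = 0,
                                 PV = 0), shape = c(64L, 64L, 48L),
                               wrapExtent = 8L, radius = 2.5,
                               shellThickness = 1.5)
  rep <- quantifyVolume(ph$volume)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  writeInvolvementReport(rep, jsonPath = fj, csvPath = fc)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_setequal(back$vessel, vesselNames())
  csv <- read.csv(fc)
  expect_equal(csv$max_degrees,
               round(involvementTable(rep)$max_degrees, 1))
})
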