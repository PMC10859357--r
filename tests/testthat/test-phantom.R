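smallGeom <- list(shape = c(64L, 64L, 48L), wrapExtent = 8L)

test_that("identical spec and seed give voxel-identical phantoms", {
  a <- makeWrapPhantom(135, shape = smallGeom$shape,
                       wrapExtent = smallGeom$wrapExtent,
                       jitter = TRUE, seed = 42)
  b <- makeWrapPhantom(135, shape = smallGeom$shape,
                       wrapExtent = smallGeom$wrapExtent,
                       jitter = TRUE, seed = 42)
  expect_identical(voxels(a$volume), voxels(b$volume))
  c <- makeWrapPhantom(135, shape = smallGeom$shape,
                       wrapExtent = smallGeom$wrapExtent,
                       jitter = TRUE, seed = 43)
  expect_false(identical(voxels(a$volume), voxels(c$volume)))
})

test_that("tumor and vessel voxel sets stay disjoint, with and without
           jitter", {
  for (jit in c(FALSE, TRUE)) {
    ph <- makeWrapPhantom(270, shape = smallGeom$shape,
                          wrapExtent = smallGeom$wrapExtent,
                          jitter = jit, seed = 5)
    vox <- voxels(ph$volume)
    expect_equal(sum(vox == 1L & vox == 4L), 0L)  # trivially disjoint grid
    expect_true(all(unique(as.integer(vox)) %in% c(0L, 1L, 4L)))
  }
})

test_that("a zero wrap places tumor clear of the vessel (no in-plane
           8-adjacency)", {
  ph <- makeWrapPhantom(0, shape = smallGeom$shape,
                        wrapExtent = smallGeom$wrapExtent)
  vox <- voxels(ph$volume)
  expect_gt(sum(vox == 1L), 0)  # tumor present somewhere
  d <- dim(vox)
  adjacent <- FALSE
  for (s in seq_len(d[3])) {
    sl <- vox[, , s]
    tm <- sl == 1L
    if (!any(tm)) next
    grow <- tm
    nr <- nrow(sl); nc <- ncol(sl)
    for (di in -1:1) for (dj in -1:1) {
      si <- max(1, 1 + di):min(nr, nr + di)
      sj <- max(1, 1 + dj):min(nc, nc + dj)
      grow[si - di, sj - dj] <- grow[si - di, sj - dj] | tm[si, sj]
    }
    if (any(grow & sl == 4L)) adjacent <- TRUE
  }
  expect_false(adjacent)
})

test_that("a full wrap forms a complete ring in interior wrap slices", {
  ph <- makeWrapPhantom(360, shape = smallGeom$shape,
                        wrapExtent = smallGeom$wrapExtent)
  vox <- voxels(ph$volume)
  s <- dim(vox)[3] %/% 2L
  sl <- vox[, , s]
  tum <- which(sl == 1L, arr.ind = TRUE)
  ves <- which(sl == 4L, arr.ind = TRUE)
  ctr <- colMeans(ves)
  ang <- (atan2(tum[, 2] - ctr[2], tum[, 1] - ctr[1]) * 180 / pi) %% 360
  occupied <- table(cut(ang, breaks = seq(0, 360, by = 10),
                        include.lowest = TRUE))
  expect_true(all(occupied > 0))  # every 10-degree sector holds tumor
})

test_that("a quarter wrap occupies a quarter of the angular positions", {
  ph <- makeWrapPhantom(90, wrapStart = 15)  # default geometry
  vox <- voxels(ph$volume)
  s <- dim(vox)[3] %/% 2L
  sl <- vox[, , s]
  tum <- which(sl == 1L, arr.ind = TRUE)
  ves <- which(sl == 4L, arr.ind = TRUE)
  ctr <- colMeans(ves)
  ang <- (atan2(tum[, 2] - ctr[2], tum[, 1] - ctr[1]) * 180 / pi) %% 360
  rel <- (ang - 15) %% 360
  expect_lt(max(rel), 90 + 8)  # all tumor angles inside the wrap (+raster)
  bins <- cut((ang) %% 360, breaks = seq(0, 360, by = 10),
              include.lowest = TRUE)
  expect_equal(sum(table(bins) > 0), 9, tolerance = 1)  # ~9/36 sectors
})

test_that("phantom truth is derived through the public bin/classify
           operations", {
  mk <- function(wraps) makeMultiVesselPhantom(
    wraps, shape = smallGeom$shape, wrapExtent = smallGeom$wrapExtent,
    radius = 2.5, shellThickness = 1.5)
  ph <- mk(c(CeTr = 0, HA = 0, SMA = 120, SMV = 0, PV = 0))
  tr <- ph$truth
  expect_equal(truthCategories(tr), binDegree(truthAngles(tr)),
               ignore_attr = TRUE)
  expect_equal(truthStage(tr), caseStage(classifyStage(truthAngles(tr))))
  expect_equal(truthStage(tr), "locally_advanced")

  ph2 <- mk(c(CeTr = 0, HA = 0, SMA = 45, SMV = 200, PV = 0))
  expect_equal(truthStage(ph2$truth), "borderline_resectable")
  ph3 <- mk(c(CeTr = 0, HA = 0, SMA = 0, SMV = 0, PV = 0))
  expect_equal(truthStage(ph3$truth), "resectable")
})

test_that("multi-vessel phantoms refuse intersecting tubes", {
  expect_error(makeMultiVesselPhantom(
    c(CeTr = 0, HA = 0, SMA = 0, SMV = 0, PV = 0),
    shape = c(40L, 40L, 40L), radius = 6, shellThickness = 3),
    "intersect|exit")
})

test_that("curved phantoms keep an analytic straight wrap segment", {
  ph <- makeCurvedVesselPhantom(90, shape = smallGeom$shape,
                                wrapExtent = smallGeom$wrapExtent,
                                amplitude = 3, period = 32)
  vi <- quantifyVessel(ph$volume, "SMA")
  expect_lt(abs(maxDegrees(vi) - 90), 15)  # relaxed under curvature

  ph0 <- makeCurvedVesselPhantom(0, shape = smallGeom$shape,
                                 wrapExtent = smallGeom$wrapExtent,
                                 amplitude = 3, period = 32)
  expect_equal(maxDegrees(quantifyVessel(ph0$volume, "SMA")), 0)

  a <- makeCurvedVesselPhantom(90, shape = smallGeom$shape,
                               wrapExtent = smallGeom$wrapExtent,
                               amplitude = 3, period = 32,
                               jitter = TRUE, seed = 9)
  b <- makeCurvedVesselPhantom(90, shape = smallGeom$shape,
                               wrapExtent = smallGeom$wrapExtent,
                               amplitude = 3, period = 32,
                               jitter = TRUE, seed = 9)
  expect_identical(voxels(a$volume), voxels(b$volume))

  expect_error(makeCurvedVesselPhantom(90, amplitude = 30, period = 4),
               "self-intersect|exit")
})

test_that("phantoms round-trip through the on-disk representation", {
  ph <- makeWrapPhantom(90, shape = c(32L, 32L, 32L), radius = 3,
                        shellThickness = 2, wrapExtent = 10L)
  dir <- tempfile()
  paths <- writePhantom(ph, dir)
  expect_true(all(file.exists(paths)))
  vol <- readLabelVolume(paths[["volume"]], paths[["labels"]])
  expect_identical(voxels(vol), voxels(ph$volume))
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(tr$angles$SMA, 90)
  expect_equal(tr$stage, truthStage(ph$truth))
})
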