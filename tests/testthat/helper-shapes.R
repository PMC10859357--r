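## Programmatic 2D/3D fixtures.

## Digital disk of radius r px centred in an (2r + margin)^2 grid.
diskMask <- function(r, margin = 9L, centerOffset = c(0, 0)) {
  n <- 2L * r + margin
  cx <- (n + 1) / 2 + centerOffset[1]
  cy <- (n + 1) / 2 + centerOffset[2]
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

## Wrap a LabelPlane around an integer matrix.
asPlane <- function(pix, spacing = c(1, 1), axis = 3L, index = 1L) {
  storage.mode(pix) <- "integer"
  new("LabelPlane", pixels = pix, spacing = as.numeric(spacing),
      axis = as.integer(axis), index = as.integer(index))
}

## Plane holding a vessel disk (label vl) plus an annular tumor arc (label
## tl) of thetaDeg degrees starting at startDeg, abutting the disk surface.
wrappedDiskPlane <- function(r = 10, thetaDeg = 90, startDeg = 15,
                             shell = 5, n = 4L * r, vl = 4L, tl = 1L) {
  cx <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  rr <- sqrt((xs - cx)^2 + (ys - cx)^2)
  pix <- matrix(0L, n, n)
  pix[rr <= r] <- vl
  if (thetaDeg > 0) {
    ang <- (atan2(ys - cx, xs - cx) * 180 / pi - startDeg) %% 360
    pix[rr > r & rr <= r + shell & (ang <= thetaDeg | thetaDeg >= 360)] <- tl
  }
  pix
}

## Small random 3D label volume for brute-force comparisons.
randomLabelVolume <- function(seed, shape = c(12L, 10L, 8L)) {
  set.seed(seed)
  vox <- array(sample(c(0L, 0L, 0L, 1L, 4L), prod(shape), replace = TRUE),
               shape)
  LabelVolume(vox, c(0.5, 0.7, 1.0), defaultLabelMap())
}

## Saddle-free test shapes on grids <= 32x32 for oracle equivalence.
oracleShapes <- function() {
  shapes <- list()
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  shapes$square10 <- sq
  rect <- matrix(0L, 20, 12); rect[4:17, 3:9] <- 1L
  shapes$rect <- rect
  ell <- matrix(0L, 18, 18); ell[3:15, 3:7] <- 1L; ell[3:7, 3:15] <- 1L
  shapes$ell <- ell
  cross <- matrix(0L, 19, 19); cross[8:12, 3:17] <- 1L; cross[3:17, 8:12] <- 1L
  shapes$cross <- cross
  for (r in c(3, 5, 7, 9))
    shapes[[paste0("disk", r)]] <- diskMask(r, margin = 7L) * 1L
  shapes$pixel1 <- {m <- matrix(0L, 5, 5); m[3, 3] <- 1L; m}
  shapes
}
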