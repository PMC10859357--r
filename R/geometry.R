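## Internal 2D geometry primitives: 8-connected component labelling,
## hole-free outer contours at the 0.5 iso-level, and contour smoothing.
## All functions work in pixel units; physical spacing is applied by the
## callers when lengths are summed.

## 8-connected labelling built on EBImage::bwlabel (4-connected flood fill)
## plus a union-find merge of labels that touch diagonally.
.labelComponents8 <- function(mask) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # / diagonal
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- findRoot(pairs[k, 1]); b <- findRoot(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(nlab), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Outer contour of a connected binary component: holes are filled first
## (the circumference of a vessel cross-section is its outer boundary), then
## the 0.5 iso-contour is traced on the zero-padded mask. Returns the closed
## polygon's vertices (pixel units, duplicate endpoint removed) and the
## hole-filled mask.
.outerContour <- function(mask) {
  storage.mode(mask) <- "integer"
  filled <- EBImage::fillHull(mask)
  nr <- nrow(filled); nc <- ncol(filled)
  pm <- matrix(0L, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- filled
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                z = pm, levels = 0.5)
  if (!length(cl)) stop("no contour found: empty component")
  cc <- cl[[which.max(vapply(cl, function(k) length(k$x), integer(1)))]]
  x <- cc$x; y <- cc$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  list(poly = cbind(x, y), filled = filled > 0L)
}

## Circular moving average of a closed polygon's vertices. Removes the
## half-pixel staircase of the mid-crack contour; window 5 keeps digital-disk
## perimeters within ~1% of 2*pi*r for radii 5-50 px. Polygons with fewer
## vertices than the window are returned unchanged.
.CONTOUR_SMOOTH_WINDOW <- 5L

.smoothClosedPolygon <- function(poly, window = .CONTOUR_SMOOTH_WINDOW) {
  n <- nrow(poly)
  if (n < window) return(poly)
  k <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), -k:k, function(i, j) ((i + j - 1L) %% n) + 1L)
  cbind(rowMeans(matrix(poly[idx, 1], n)),
        rowMeans(matrix(poly[idx, 2], n)))
}

## Per-segment physical lengths of a closed polygon (segment i connects
## vertex i to vertex i+1, wrapping).
.segmentLengths <- function(poly, spacing) {
  nxt <- c(seq_len(nrow(poly))[-1], 1L)
  sqrt(((poly[nxt, 1] - poly[, 1]) * spacing[1])^2 +
       ((poly[nxt, 2] - poly[, 2]) * spacing[2])^2)
}

## 3x3 (8-neighbourhood) binary dilation via shifts.
.dilate8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    si <- max(1L, 1L + di):min(nr, nr + di)
    sj <- max(1L, 1L + dj):min(nc, nc + dj)
    out[si - di, sj - dj] <- out[si - di, sj - dj] | mask[si, sj]
  }
  out
}

## Core cross-section measurement for one component.
##
## planePix   integer label matrix (NULL to measure the perimeter only)
## compMask   logical matrix, the component (same dims as planePix)
## Returns V (mm), TV (mm), and whether any boundary segment faces outside
## the matrix (image border: counts toward V, can never be contact).
##
## A raw mid-crack segment separates exactly one inside from one outside
## pixel; lengths are taken from the smoothed polygon so that TV/V uses the
## same (bias-corrected) scale for both numerator and denominator.
.componentMeasure <- function(planePix, compMask, tumorLabel = NULL,
                              spacing = c(1, 1),
                              adjacency = c("face", "diagonal")) {
  adjacency <- match.arg(adjacency)
  oc <- .outerContour(compMask)
  P <- oc$poly
  S <- .smoothClosedPolygon(P)
  lens <- .segmentLengths(S, spacing)
  V <- sum(lens)
  if (is.null(tumorLabel))
    return(list(V = V, TV = NA_real_, border = NA))

  nr <- nrow(compMask); nc <- ncol(compMask)
  nxt <- c(seq_len(nrow(P))[-1], 1L)
  dx <- P[nxt, 1] - P[, 1]
  dy <- P[nxt, 2] - P[, 2]
  mx <- (P[, 1] + P[nxt, 1]) / 2
  my <- (P[, 2] + P[nxt, 2]) / 2
  nl <- sqrt(dx^2 + dy^2)
  nxn <- -dy / nl
  nyn <- dx / nl
  c1 <- cbind(round(mx + 0.5 * nxn), round(my + 0.5 * nyn))
  c2 <- cbind(round(mx - 0.5 * nxn), round(my - 0.5 * nyn))
  inBounds <- function(cc) cc[, 1] >= 1 & cc[, 1] <= nr &
                           cc[, 2] >= 1 & cc[, 2] <= nc
  lookup <- function(cc, M, default) {
    v <- rep(default, nrow(cc))
    ok <- inBounds(cc)
    v[ok] <- M[cbind(cc[ok, 1], cc[ok, 2])]
    v
  }
  in1 <- lookup(c1, oc$filled, FALSE)
  inside <- c1; inside[!in1, ] <- c2[!in1, ]
  outside <- c2; outside[!in1, ] <- c1[!in1, ]
  border <- !inBounds(outside)
  outVal <- lookup(outside, planePix, -1L)
  contact <- outVal == tumorLabel
  if (adjacency == "diagonal") {
    tumorDil <- .dilate8(planePix == tumorLabel)
    contact <- contact | (outVal == 0L & lookup(inside, tumorDil, FALSE))
  }
  contact[border] <- FALSE
  list(V = V, TV = sum(lens[contact]), border = any(border))
}
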