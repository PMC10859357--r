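## Independent oracles used to verify the implementation. These re-derive
## the same documented quantities by brute force and share no code with the
## package internals.

## Brute-force marching-squares contour: enumerate every 2x2 cell of the
## zero-padded mask, emit the 0.5-crossing segment(s) per cell from the
## standard case analysis, then assemble the segments into a single closed
## polygon by endpoint matching. Fails loudly on saddle cells (the test
## fixtures are constructed saddle-free) and on masks with holes (callers
## fill holes first, matching the outer-boundary definition).
oracleContourPolygon <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(0L, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  segs <- list()
  for (i in 1:(nr + 1L)) for (j in 1:(nc + 1L)) {
    A <- pm[i, j];      C <- pm[i, j + 1L]
    B <- pm[i + 1L, j]; D <- pm[i + 1L, j + 1L]
    n1 <- A + B + C + D
    if (n1 == 0L || n1 == 4L) next
    ## pm[i, j] sits at coordinate (i - 1, j - 1)
    left   <- c(i - 0.5, j - 1)  # A-B edge midpoint
    right  <- c(i - 0.5, j)      # C-D
    top    <- c(i - 1, j - 0.5)  # A-C
    bottom <- c(i, j - 0.5)      # B-D
    if (n1 %in% c(1L, 3L)) {
      corner <- if (n1 == 1L) which(c(A, B, C, D) == 1L)
                else which(c(A, B, C, D) == 0L)
      pts <- switch(corner,
        list(left, top), list(left, bottom),
        list(right, top), list(right, bottom))
      segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
    } else {
      if (A == D) stop("saddle cell in oracle fixture")
      if (A == B) segs[[length(segs) + 1L]] <- rbind(top, bottom)
      else segs[[length(segs) + 1L]] <- rbind(left, right)
    }
  }
  if (!length(segs)) stop("empty mask")
  ## assemble: endpoints are multiples of 0.5; key on doubled coords
  key <- function(p) paste(round(2 * p[1]), round(2 * p[2]))
  ends <- lapply(segs, function(s) c(key(s[1, ]), key(s[2, ])))
  lookup <- new.env()
  for (k in seq_along(ends)) for (e in ends[[k]]) {
    lookup[[e]] <- c(lookup[[e]], k)
  }
  used <- rep(FALSE, length(segs))
  cur <- 1L; used[1] <- TRUE
  poly <- segs[[1]]
  curKey <- ends[[1]][2]
  repeat {
    cand <- setdiff(lookup[[curKey]], which(used))
    if (!length(cand)) break
    nxt <- cand[1]
    used[nxt] <- TRUE
    s <- segs[[nxt]]
    if (key(s[1, ]) == curKey) { poly <- rbind(poly, s[2, ]); curKey <- key(s[2, ]) }
    else { poly <- rbind(poly, s[1, ]); curKey <- key(s[1, ]) }
  }
  if (!all(used)) stop("mask boundary is not a single closed loop (hole?)")
  ## drop closing duplicate
  poly[-nrow(poly), , drop = FALSE]
}

## The same published smoothing definition (circular moving average,
## window 5), written as a plain loop.
oracleSmooth <- function(P, w = 5L) {
  n <- nrow(P)
  if (n < w) return(P)
  k <- (w - 1L) %/% 2L
  out <- P
  for (i in seq_len(n)) {
    idx <- ((i - k - 1L):(i + k - 1L)) %% n + 1L
    out[i, ] <- colMeans(P[idx, , drop = FALSE])
  }
  out
}

oraclePerimeter <- function(mask, spacing = c(1, 1)) {
  P <- oracleSmooth(oracleContourPolygon(mask))
  Q <- rbind(P, P[1, ])
  sum(sqrt((diff(Q[, 1]) * spacing[1])^2 + (diff(Q[, 2]) * spacing[2])^2))
}

## Exhaustive triple-loop definition of planesContaining.
oraclePlanes <- function(vox, la, lb) {
  d <- dim(vox)
  out <- NULL
  for (ax in 1:3) for (i in seq_len(d[ax])) {
    sl <- switch(ax, vox[i, , ], vox[, i, ], vox[, , i])
    if (any(sl == la) && any(sl == lb))
      out <- rbind(out, data.frame(axis = ax, index = i))
  }
  if (is.null(out)) data.frame(axis = integer(), index = integer()) else out
}

## Independent evaluation of the default DPCG rule table.
oracleStage <- function(deg) {
  art <- function(d) if (d == 0) 1L else if (d <= 90) 2L else 3L
  ven <- function(d) if (d <= 90) 1L else if (d <= 270) 2L else 3L
  sev <- max(art(deg[["CeTr"]]), art(deg[["HA"]]), art(deg[["SMA"]]),
             ven(deg[["SMV"]]), ven(deg[["PV"]]))
  resectabilityStages()[sev]
}

## Definitional sums-of-squares one-way ANOVA.
oracleAnova <- function(groups) {
  x <- unlist(groups)
  m <- mean(x)
  nj <- vapply(groups, length, integer(1))
  mj <- vapply(groups, mean, numeric(1))
  ssb <- sum(nj * (mj - m)^2)
  ssw <- sum(vapply(seq_along(groups),
                    function(j) sum((groups[[j]] - mj[j])^2), numeric(1)))
  k <- length(groups); N <- length(x)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

## Order-statistics quantiles with linear interpolation (h = (n-1)p + 1),
## written independently of stats::quantile.
oracleQuantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
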