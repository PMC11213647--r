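#' Unwrap the rectal surface dose into a 2D map
#'
#' For each axial rectal contour: locate the posterior-most vertex (minimum
#' anterior coordinate, ties broken toward patient-right), traverse the
#' closed contour clockwise as seen from inferior, resample it at
#' \code{nSamples} equal-arc-length points starting at the anchor, and
#' sample the dose at each point by bilinear in-plane interpolation. Rows
#' are ordered inferior to superior.
#'
#' @param dose dose \linkS4class{ImageGrid}.
#' @param rectumContours list of \linkS4class{Contour} on consecutive
#'   slices.
#' @param nSamples circumferential samples per slice (default 100).
#' @return A \linkS4class{DoseSurfaceMap} with the raw map filled.
#' @export
unwrapSurface <- function(dose, rectumContours, nSamples = 100) {
  if (!length(rectumContours)) stop("no contours supplied")
  slices <- vapply(rectumContours, function(cn) cn@slice, integer(1))
  ord <- order(slices)
  rectumContours <- rectumContours[ord]
  raw <- matrix(0, length(rectumContours), nSamples)
  rowC <- axisCoords(dose, 2)
  colC <- axisCoords(dose, 3)
  for (i in seq_along(rectumContours)) {
    cn <- rectumContours[[i]]
    if (nrow(cn@points) < 3) stop("degenerate contour (< 3 points)")
    pts <- orientClockwiseFromInferior(cn@points)
    pts <- rotateToPosteriorAnchor(pts)
    samp <- resampleArcLength(pts, nSamples)
    # bilinear in-plane dose interpolation at the surface points
    fy <- (samp[, 1] - dose@origin[2]) / dose@spacing[2]
    fx <- (samp[, 2] - dose@origin[3]) / dose@spacing[3]
    slice <- dose@voxels[cn@slice, , ]
    raw[i, ] <- bilinearSample(slice, fy, fx)
  }
  DoseSurfaceMap(raw = raw)
}

# Fixed circumferential convention: traversal is clockwise viewed from
# inferior, which with (row = posterior->anterior, col = right->left) axes
# means negative shoelace area in (col, row); the first step from the
# posterior anchor then heads toward patient-right.
orientClockwiseFromInferior <- function(pts) {
  if (polygonSignedArea(pts) > 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  else pts
}

rotateToPosteriorAnchor <- function(pts) {
  post <- which(pts[, 1] == min(pts[, 1]))
  anchor <- post[which.min(pts[post, 2])]     # tie -> patient-right (min col)
  if (anchor > 1) pts <- rbind(pts[anchor:nrow(pts), , drop = FALSE],
                               pts[seq_len(anchor - 1), , drop = FALSE])
  pts
}

# n points at equal arc length along the closed polygon, starting at vertex 1
resampleArcLength <- function(pts, n) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  at <- (seq_len(n) - 1) / n * total
  cbind(stats::approx(arc, closed[, 1], xout = at)$y,
        stats::approx(arc, closed[, 2], xout = at)$y)
}

bilinearSample <- function(m, fy, fx) {
  ny <- nrow(m); nx <- ncol(m)
  fy <- pmin(pmax(fy, 0), ny - 1)
  fx <- pmin(pmax(fx, 0), nx - 1)
  y0 <- pmin(floor(fy), ny - 2); x0 <- pmin(floor(fx), nx - 2)
  wy <- fy - y0; wx <- fx - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - wy) * (1 - wx) + m[i01] * (1 - wy) * wx +
    m[i10] * wy * (1 - wx) + m[i11] * wy * wx
}

#' Interpolate a raw dose-surface map to 42 x 42
#'
#' Bilinear interpolation to exactly 42 rows (cranio-caudal) by 42 columns
#' (circumferential); the circumferential axis is treated as periodic.
#'
#' @param dsm \linkS4class{DoseSurfaceMap} with a raw map of at least 2 x 2.
#' @return The map with the interpolated slot filled.
#' @export
interpolateDSM <- function(dsm) {
  raw <- dsm@raw
  if (nrow(raw) < 2 || ncol(raw) < 2) stop("raw map must be at least 2 x 2")
  nr <- nrow(raw); nc <- ncol(raw)
  out <- matrix(0, 42, 42)
  rPos <- (seq_len(42) - 1) / 41 * (nr - 1)       # row sample positions
  cPos <- (seq_len(42) - 1) / 42 * nc             # periodic phase positions
  r0 <- pmin(floor(rPos), nr - 2); wr <- rPos - r0
  c0 <- floor(cPos); wc <- cPos - c0
  c1 <- (c0 + 1) %% nc                            # wrap-around column
  for (i in seq_len(42)) {
    rowLo <- raw[r0[i] + 1, ]; rowHi <- raw[r0[i] + 2, ]
    vLo <- rowLo[c0 + 1] * (1 - wc) + rowLo[c1 + 1] * wc
    vHi <- rowHi[c0 + 1] * (1 - wc) + rowHi[c1 + 1] * wc
    out[i, ] <- vLo * (1 - wr[i]) + vHi * wr[i]
  }
  DoseSurfaceMap(raw = raw, interpolated = out, isEQD2 = dsm@isEQD2)
}

#' EQD2-convert a dose-surface map
#'
#' Applies the fractionation correction cell-wise to the interpolated map
#' (per-cell dose divided into the plan's fractions).
#'
#' @param dsm interpolated \linkS4class{DoseSurfaceMap}.
#' @param fractions number of fractions.
#' @param alphaBeta alpha/beta ratio, Gy (default 3).
#' @return EQD2-flagged \linkS4class{DoseSurfaceMap}.
#' @export
eqd2DSM <- function(dsm, fractions = 20, alphaBeta = 3) {
  if (!length(dsm@interpolated)) stop("interpolate the DSM first")
  DoseSurfaceMap(raw = dsm@raw,
                 interpolated = eqd2(dsm@interpolated, fractions, alphaBeta),
                 isEQD2 = TRUE)
}

#' Binarize an EQD2 dose-surface map
#'
#' Cells at or above the threshold are true; the relative area is the true
#' count over the full 42 x 42 = 1764 cells. The published bleeding-risk
#' flag uses threshold 51 Gy with cut-off relative area > 0.374.
#'
#' @param dsm EQD2-converted interpolated \linkS4class{DoseSurfaceMap}.
#' @param thresholdGy binarization threshold (51 or 61 Gy).
#' @return list(map = 42 x 42 logical, relArea = fraction).
#' @export
binarizeDSM <- function(dsm, thresholdGy) {
  if (!dsm@isEQD2) stop("DSM must be EQD2-converted before binarization")
  if (!length(dsm@interpolated)) stop("interpolate the DSM first")
  m <- dsm@interpolated >= thresholdGy
  list(map = m, relArea = sum(m) / length(m))
}

#' EllipseFit: moment-equivalent ellipse of the largest cluster
#'
#' @slot center (row, col) centroid in cell units.
#' @slot semiAxes ellipse semi-axes (cell units).
#' @slot orientation angle of the major axis, radians.
#' @slot lateralExtent length of the ellipse's projection onto the
#'   circumferential axis, columns.
#' @slot relativeLateralExtent lateralExtent / 42 (may exceed 1 for
#'   near-full-width clusters).
#' @slot clusterSize cells in the largest cluster.
#' @export
setClass("EllipseFit",
  representation(center = "numeric", semiAxes = "numeric",
                 orientation = "numeric", lateralExtent = "numeric",
                 relativeLateralExtent = "numeric", clusterSize = "integer"))

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf(
    "EllipseFit: cluster %d cells, lateral extent %.2f cols (relative %.3f)\n",
    object@clusterSize, object@lateralExtent, object@relativeLateralExtent))
})

#' Fit an ellipse to the largest cluster of a binary DSM
#'
#' Clusters use 8-connectivity with circumferential wrap-around; the largest
#' cluster (ties: smallest centroid row, then column) is summarized by its
#' second-central-moment equivalent ellipse (cells treated as unit squares,
#' adding 1/12 per-cell variance). The lateral extent is the full projection
#' of the ellipse onto the circumferential axis, 4 * sqrt(cov_cc); the
#' published bleeding-risk flag compares extent/42 against 0.591 for the
#' 61 Gy map. An empty map returns the defined degenerate all-zero fit.
#'
#' @param binaryMap 42 x 42 logical matrix.
#' @return An \linkS4class{EllipseFit}.
#' @export
largestClusterEllipse <- function(binaryMap) {
  stopifnot(is.logical(binaryMap), all(dim(binaryMap) == c(42, 42)))
  if (!any(binaryMap))
    return(new("EllipseFit", center = c(0, 0), semiAxes = c(0, 0),
               orientation = 0, lateralExtent = 0,
               relativeLateralExtent = 0, clusterSize = 0L))
  labels <- labelClustersWrap(binaryMap)
  sizes <- tabulate(labels[labels > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {   # ties -> smallest centroid row, then column
    cent <- t(vapply(best, function(l) {
      idx <- which(labels == l, arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]))
    }, numeric(2)))
    best <- best[order(cent[, 1], cent[, 2])]
  }
  idx <- which(labels == best[1], arr.ind = TRUE)
  nc <- ncol(binaryMap)
  cols <- unwrapClusterCols(idx[, 2], labels == best[1], nc)
  rows <- idx[, 1]
  cov <- matrix(0, 2, 2)
  cov[1, 1] <- meanSq(rows) + 1 / 12
  cov[2, 2] <- meanSq(cols) + 1 / 12
  cov[1, 2] <- cov[2, 1] <- mean((rows - mean(rows)) * (cols - mean(cols)))
  eg <- eigen(cov, symmetric = TRUE)
  semi <- 2 * sqrt(pmax(eg$values, 0))
  lat <- 4 * sqrt(cov[2, 2])
  new("EllipseFit",
      center = c(mean(rows), mean(cols) %% nc),
      semiAxes = semi,
      orientation = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
      lateralExtent = lat, relativeLateralExtent = lat / nc,
      clusterSize = nrow(idx))
}

meanSq <- function(v) mean((v - mean(v))^2)

# BFS connected components, 8-connectivity, columns periodic
labelClustersWrap <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  for (start in which(m & labels == 0L)) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% nr + 1; cc <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr
        if (rr < 1 || rr > nr) next
        ccc <- (cc + dc - 1) %% nc + 1          # wrap columns
        q <- rr + nr * (ccc - 1)
        if (m[q] && labels[q] == 0L) { labels[q] <- lab; queue <- c(queue, q) }
      }
    }
  }
  labels
}

# shift wrapped cluster columns so the cluster is contiguous before moments
unwrapClusterCols <- function(cols, mask, nc) {
  present <- sort(unique(cols))
  if (length(present) == nc) return(cols)       # full circumference
  if (1 %in% present && nc %in% present) {
    gapStart <- min(setdiff(seq_len(nc), present))
    cols[cols < gapStart] <- cols[cols < gapStart] + nc
  }
  cols
}

#' Buettner-style DSM parameters of a dose distribution
#'
#' Full chain: unwrap the rectal surface, interpolate to 42 x 42, EQD2
#' conversion, 51/61 Gy binary maps, relative 51 Gy area and relative
#' lateral extent of the largest 61 Gy cluster, with the published risk
#' cut-offs (0.374 and 0.591).
#'
#' @param dose dose \linkS4class{ImageGrid}.
#' @param rectumContours list of rectal \linkS4class{Contour}s.
#' @param fractions fractions delivering the dose.
#' @param nSamples circumferential samples per slice.
#' @return list(relArea51, relLatExtent61, flagArea51, flagExtent61,
#'   dsm = EQD2 \linkS4class{DoseSurfaceMap}).
#' @export
dsmParameters <- function(dose, rectumContours, fractions = 20,
                          nSamples = 100) {
  dsm <- eqd2DSM(interpolateDSM(unwrapSurface(dose, rectumContours,
                                              nSamples)),
                 fractions = fractions)
  b51 <- binarizeDSM(dsm, 51)
  b61 <- binarizeDSM(dsm, 61)
  fit <- largestClusterEllipse(b61$map)
  list(relArea51 = b51$relArea,
       relLatExtent61 = fit@relativeLateralExtent,
       flagArea51 = b51$relArea > 0.374,
       flagExtent61 = fit@relativeLateralExtent > 0.591,
       dsm = dsm)
}
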