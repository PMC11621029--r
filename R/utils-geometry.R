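## Geometry helpers shared across modules. Image coordinate convention
## throughout: origin top-left, y increases downward.

.splitOperands <- function(s) {
  trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}

#' Shoelace area of a polygon
#'
#' @param poly numeric matrix (vertices x 2), ordered along the boundary.
#' @return Absolute enclosed area.
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Scale a polygon about its centroid
#'
#' @param poly numeric matrix (vertices x 2).
#' @param factor positive scale factor.
#' @return Scaled polygon matrix.
#' @export
scalePolygon <- function(poly, factor) {
  ctr <- colMeans(poly)
  sweep(sweep(poly, 2, ctr, "-") * factor, 2, ctr, "+")
}

## Vectorized point-in-polygon. pts: n x 2. Boundary points count as inside
## (mgcv::in.out with boundary = TRUE semantics handled by tiny outward nudge
## is unnecessary for our thresholds; in.out treats boundary as in for
## typical use).
.pointsInPolygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  keep <- stats::complete.cases(pts)
  out <- rep(FALSE, nrow(pts))
  if (any(keep))
    out[keep] <- mgcv::in.out(bnd, pts[keep, , drop = FALSE])
  out
}

## Distance of each point to the nearest edge of a polygon (px or cm,
## whatever units pts/poly are in). pts: n x 2.
.distToPolygonBorder <- function(poly, pts) {
  nv <- nrow(poly)
  d <- matrix(Inf, nrow(pts), nv)
  for (e in seq_len(nv)) {
    a <- poly[e, ]
    b <- poly[if (e == nv) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a, "-")
    t <- if (len2 > 0) pmin(1, pmax(0, (ap[, 1] * ab[1] + ap[, 2] * ab[2]) / len2)) else 0
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d[, e] <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
  }
  apply(d, 1, min)
}

## Linear interpolation over masked frames; leading/trailing gaps filled with
## the nearest valid value. Returns the filled vector.
.fillSeries <- function(v, bad) {
  v[bad] <- NA_real_
  ok <- which(!is.na(v))
  if (length(ok) == 0L) return(v)  # caller raises
  if (length(ok) == length(v)) return(v)
  out <- stats::approx(ok, v[ok], xout = seq_along(v), rule = 2)$y
  out
}
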