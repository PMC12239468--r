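# 2D primitives for lateral-radiograph constructions.
#
# Coordinate frame (fixed for the whole package): x = anterior (+) / posterior (-),
# y = proximal (+) / distal (-), units mm. Positive angles are counter-clockwise
# in this frame; for the femur that is the flexion sense of a proximally-directed
# line, for the tibia it is the sense that increases posterior slope.

DEG <- 180 / pi
.EPS <- 1e-9

#' Create a point
#'
#' Points live in the package's fixed sagittal frame: `x` in mm along the
#' anterior(+)/posterior(-) axis, `y` in mm along the proximal(+)/distal(-) axis.
#'
#' @param x,y Coordinates in mm.
#' @return A numeric vector of length 2, named `c(x, y)`.
#' @export
#' @examples
#' pnt(3, -8)
pnt <- function(x, y) {
  p <- c(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  p
}

#' Create a directed line
#'
#' A line through `anchor` with unit `direction`. The direction is normalised on
#' construction; a zero-length direction is an error.
#'
#' @param anchor Point on the line (length-2 numeric, mm).
#' @param direction Direction vector (length-2 numeric); need not be unit length.
#' @return An object of class `directed_line` with fields `anchor` and
#'   `direction` (unit vector).
#' @export
#' @examples
#' directed_line(pnt(0, 0), c(0, 1))
directed_line <- function(anchor, direction) {
  anchor <- as.numeric(anchor)
  direction <- as.numeric(direction)
  stopifnot(length(anchor) == 2L, length(direction) == 2L)
  if (!all(is.finite(anchor), is.finite(direction)))
    stop("directed_line: inputs must be finite")
  nrm <- sqrt(sum(direction^2))
  if (nrm < .EPS) stop("directed_line: direction has zero length")
  structure(list(anchor = anchor, direction = direction / nrm),
            class = "directed_line")
}

#' @export
print.directed_line <- function(x, ...) {
  cat(sprintf("<directed_line> anchor (%.3f, %.3f) mm, direction (%.6f, %.6f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Create a polycurve (open polyline)
#'
#' An ordered polyline used for cortex, canal and articular contours. Must have
#' at least two points, distinct consecutive vertices and positive total arc
#' length.
#'
#' @param points A two-column numeric matrix (or object coercible to one), one
#'   vertex per row, in mm.
#' @return A matrix of class `polycurve` with columns `x`, `y`.
#' @export
polycurve <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 2L) stop("polycurve: points must have two columns")
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("polycurve: need at least 2 points")
  if (!all(is.finite(m))) stop("polycurve: coordinates must be finite")
  seg <- diff(m)
  len <- sqrt(rowSums(seg^2))
  if (any(len < .EPS)) stop("polycurve: consecutive points must be distinct")
  colnames(m) <- c("x", "y")
  class(m) <- c("polycurve", "matrix", "array")
  m
}

#' @export
print.polycurve <- function(x, ...) {
  cat(sprintf("<polycurve> %d vertices, arc length %.2f mm\n",
              nrow(x), curve_length(x)))
  invisible(x)
}

# cumulative arc length at each vertex (starts at 0)
curve_cumlen <- function(curve) {
  c(0, cumsum(sqrt(rowSums(diff(unclass(curve))^2))))
}

#' Total arc length of a polycurve
#' @param curve A [polycurve()].
#' @return Arc length in mm.
#' @export
curve_length <- function(curve) {
  sum(sqrt(rowSums(diff(unclass(curve))^2)))
}

rot_mat <- function(angle_deg) {
  a <- angle_deg / DEG
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

rotate_vec <- function(v, angle_deg) as.numeric(rot_mat(angle_deg) %*% v)

#' Signed acute angle between two directed lines
#'
#' Returns the signed angle from `a` to `b`, folded into (-90, +90] degrees.
#' Positive angles are counter-clockwise rotations in the (anterior, proximal)
#' frame; the +/-90 degree boundary is reported as +90. Away from the boundary
#' `signed_angle(a, b) == -signed_angle(b, a)`.
#'
#' @param a,b [directed_line()] objects.
#' @return Angle in degrees in (-90, 90].
#' @export
#' @examples
#' v <- directed_line(pnt(0, 0), c(0, 1))
#' signed_angle(v, rotate_line(v, pnt(0, 0), 3))  # +3
signed_angle <- function(a, b) {
  da <- a$direction; db <- b$direction
  ang <- atan2(da[1] * db[2] - da[2] * db[1], sum(da * db)) * DEG
  d <- ang %% 180            # [0, 180)
  if (d > 90 + .EPS) d <- d - 180
  if (d > 90) d <- 90        # clamp representation noise at the boundary
  if (abs(d - 90) < .EPS) d <- 90
  d
}

#' Perpendicular distance from a point to a directed line
#'
#' @param p Point (length-2 numeric, mm).
#' @param l A [directed_line()].
#' @return Non-negative distance in mm.
#' @export
point_line_distance <- function(p, l) {
  r <- as.numeric(p) - l$anchor
  abs(r[1] * l$direction[2] - r[2] * l$direction[1])
}

#' Rotate a directed line about a pivot
#'
#' Both the anchor and the direction are rotated by `angle` degrees
#' (counter-clockwise positive) about `pivot`.
#'
#' @param l A [directed_line()].
#' @param pivot Point to rotate about (mm).
#' @param angle Rotation in degrees, CCW positive.
#' @return The rotated [directed_line()].
#' @export
rotate_line <- function(l, pivot, angle) {
  R <- rot_mat(angle)
  pivot <- as.numeric(pivot)
  directed_line(as.numeric(R %*% (l$anchor - pivot)) + pivot,
                as.numeric(R %*% l$direction))
}

#' Supporting (tangent) line of a given direction to a polycurve
#'
#' Returns the line with direction `direction` through the extreme vertex of
#' `curve` on the stated side, so that every curve point lies in one closed
#' half-plane of the line. `side = "right"` means the line is pushed as far as
#' possible towards the right-hand normal `(dy, -dx)` of the direction (for a
#' proximally-directed line this is the anterior side); `side = "left"` is the
#' opposite. If the curve is itself a segment parallel to `direction`, the
#' segment's own line is returned.
#'
#' @param curve A [polycurve()].
#' @param direction Direction vector of the tangent line.
#' @param side `"left"` or `"right"`.
#' @return A [directed_line()] touching the curve.
#' @export
tangent_line_of_direction <- function(curve, direction, side = c("right", "left")) {
  side <- match.arg(side)
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < .EPS) stop("tangent_line_of_direction: zero direction")
  d <- direction / nrm
  n <- if (side == "right") c(d[2], -d[1]) else c(-d[2], d[1])
  s <- unclass(curve) %*% n
  i <- which.max(s)
  directed_line(unclass(curve)[i, ], d)
}

# nearest point on a polyline to p; returns list(point, arc, dist)
project_point_on_curve <- function(curve, p) {
  m <- unclass(curve)
  p <- as.numeric(p)
  cl <- curve_cumlen(curve)
  best <- list(point = m[1, ], arc = 0, dist = sqrt(sum((m[1, ] - p)^2)))
  for (i in seq_len(nrow(m) - 1L)) {
    a <- m[i, ]; b <- m[i + 1L, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    dq <- sqrt(sum((q - p)^2))
    if (dq < best$dist - .EPS) {
      best <- list(point = q, arc = cl[i] + t * sqrt(sum(ab^2)), dist = dq)
    }
  }
  best
}

#' Point at a given arc length along a polycurve
#'
#' `origin` is projected onto the curve and the returned point lies `s` mm
#' further along the curve's traversal direction (arc length measured along the
#' contour, matching a ruler run along the cortex on a radiograph).
#'
#' @param curve A [polycurve()].
#' @param origin Point on (or near) the curve, mm.
#' @param s Arc length to advance, mm; `s = 0` returns the projection of
#'   `origin`. Must not run past the end of the curve.
#' @return A point (length-2 numeric).
#' @export
point_at_curve_distance <- function(curve, origin, s) {
  if (!is.finite(s) || s < 0) stop("point_at_curve_distance: s must be >= 0")
  pr <- project_point_on_curve(curve, origin)
  target <- pr$arc + s
  cl <- curve_cumlen(curve)
  total <- cl[length(cl)]
  if (target > total + .EPS)
    stop(sprintf(paste0("insufficient contour coverage: requested arc %.2f mm, ",
                        "contour ends at %.2f mm"), target, total))
  target <- min(target, total)
  i <- findInterval(target, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(curve) - 1L)
  seg <- unclass(curve)[i + 1L, ] - unclass(curve)[i, ]
  seglen <- sqrt(sum(seg^2))
  frac <- if (seglen > 0) (target - cl[i]) / seglen else 0
  as.numeric(unclass(curve)[i, ] + frac * seg)
}

# all intersections of an infinite line with a polyline.
# Returns a matrix of intersection points (0 rows if none).
line_curve_intersections <- function(l, curve) {
  m <- unclass(curve)
  a0 <- l$anchor; d <- l$direction
  n <- c(-d[2], d[1])                      # line normal
  f <- as.numeric((m - matrix(a0, nrow(m), 2, byrow = TRUE)) %*% n)
  out <- NULL
  for (i in seq_len(nrow(m) - 1L)) {
    f1 <- f[i]; f2 <- f[i + 1L]
    if ((f1 > .EPS && f2 > .EPS) || (f1 < -.EPS && f2 < -.EPS)) next
    if (abs(f1 - f2) < .EPS) {             # segment lies on the line
      out <- rbind(out, m[i, ], m[i + 1L, ])
    } else {
      t <- f1 / (f1 - f2)
      out <- rbind(out, m[i, ] + t * (m[i + 1L, ] - m[i, ]))
    }
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else out
}

#' Midpoint of the outer cortical diameter at a cortex point
#'
#' Draws the chord through `at` perpendicular to `local_axis` and intersects it
#' with the opposite outer cortex contour; returns the midpoint of the chord
#' from `at` to the nearest such intersection. This is the "line bisecting the
#' outer cortical diameter" construction used by the reference-line and bowing
#' measurements.
#'
#' @param at Point on one cortex contour (mm).
#' @param opposite A [polycurve()]: the opposite outer cortex.
#' @param local_axis Local bone-axis direction at `at`; the chord is taken
#'   perpendicular to it.
#' @return The chord midpoint (length-2 numeric).
#' @export
cortical_midpoint <- function(at, opposite, local_axis) {
  at <- as.numeric(at)
  la <- as.numeric(local_axis)
  nrm <- sqrt(sum(la^2))
  if (nrm < .EPS) stop("cortical_midpoint: zero local_axis")
  la <- la / nrm
  chord <- directed_line(at, c(la[2], -la[1]))
  hits <- line_curve_intersections(chord, opposite)
  if (nrow(hits) == 0L)
    stop("contour coverage error: perpendicular chord does not reach the opposite cortex")
  d2 <- rowSums((hits - matrix(at, nrow(hits), 2, byrow = TRUE))^2)
  q <- hits[which.min(d2), ]
  as.numeric((at + q) / 2)
}

# local tangent direction of a polyline at a given arc position
curve_tangent_at <- function(curve, arc) {
  cl <- curve_cumlen(curve)
  i <- findInterval(arc, cl, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(curve) - 1L)
  seg <- unclass(curve)[i + 1L, ] - unclass(curve)[i, ]
  seg / sqrt(sum(seg^2))
}

# --- rigid motions (used by generators, io and tests) ------------------------

rigid_point <- function(p, angle = 0, shift = c(0, 0)) {
  as.numeric(rot_mat(angle) %*% as.numeric(p)) + as.numeric(shift)
}

rigid_curve <- function(curve, angle = 0, shift = c(0, 0)) {
  m <- unclass(curve) %*% t(rot_mat(angle))
  polycurve(sweep(m, 2, as.numeric(shift), "+"))
}

rigid_line <- function(l, angle = 0, shift = c(0, 0)) {
  directed_line(rigid_point(l$anchor, angle, shift),
                as.numeric(rot_mat(angle) %*% l$direction))
}

# fit a line to 2D points by total least squares (principal direction),
# oriented along `orient` if given
fit_line_tls <- function(points, orient = NULL) {
  m <- as.matrix(points)
  ctr <- colMeans(m)
  cc <- sweep(m, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(m), symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (!is.null(orient) && sum(d * orient) < 0) d <- -d
  directed_line(ctr, d)
}
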