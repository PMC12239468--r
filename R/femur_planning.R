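# Femoral sagittal planning: anterior cortex line (Line A), IM guide line
# (Line B), femur entry distance (FED), cortical-midline reference (Line C) and
# the preoperative gamma angle.
#
# Flexion of a proximally-directed femoral line is the counter-clockwise sense
# in the (anterior, proximal) frame: the proximal end of the line tips
# posteriorly, following the bowed canal, and the entry point moves anteriorly.

# arc-resample a polycurve every `step` mm
resample_curve <- function(curve, step = 2) {
  total <- curve_length(curve)
  s <- seq(0, total, by = step)
  cl <- curve_cumlen(curve)
  i <- pmin(pmax(findInterval(s, cl, rightmost.closed = TRUE), 1L), nrow(curve) - 1L)
  m <- unclass(curve)
  seg <- m[i + 1L, , drop = FALSE] - m[i, , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  frac <- (s - cl[i]) / seglen
  m[i, , drop = FALSE] + seg * frac
}

#' Fit the anterior femoral cortex line (Line A)
#'
#' Total-least-squares line through anterior-cortex samples over the distal
#' fit window, default 40-140 mm -- the span of the other shaft constructions.
#' Window positions are arc lengths along the anterior cortex from the
#' projection of the posterior Blumensaat point onto it, so the window tracks
#' the shaft and excludes the trochlear front. The direction points proximally.
#'
#' @param femur A [femur_silhouette()].
#' @param window Fit window in mm (arc length at the Blumensaat level).
#' @return A [directed_line()] (Line A).
#' @export
fit_anterior_cortex_line <- function(femur, window = c(40, 140)) {
  stopifnot(inherits(femur, "femur_silhouette"))
  # anterior-cortex point at the Blumensaat level: the chord through the
  # Blumensaat point perpendicular to the local posterior-cortex tangent
  pr <- project_point_on_curve(femur$posterior_cortex, femur$blumensaat_posterior)
  ax <- curve_tangent_at(femur$posterior_cortex, pr$arc)
  chord <- directed_line(femur$blumensaat_posterior, c(ax[2], -ax[1]))
  hits <- line_curve_intersections(chord, femur$anterior_cortex)
  if (nrow(hits) == 0L)
    stop("insufficient contour coverage: no anterior cortex at the Blumensaat level")
  d2 <- rowSums(sweep(hits, 2, femur$blumensaat_posterior)^2)
  origin <- as.numeric(hits[which.min(d2), ])
  s0 <- project_point_on_curve(femur$anterior_cortex, origin)$arc
  total <- curve_length(femur$anterior_cortex)
  if (s0 + window[2] > total + 1e-9)
    stop("insufficient contour coverage: anterior cortex does not span the fit window")
  s <- seq(window[1], window[2], by = 2)
  pts <- t(vapply(s, function(si)
    point_at_curve_distance(femur$anterior_cortex, origin, si), numeric(2)))
  # orient proximally: along the contour's overall traversal
  m <- unclass(femur$anterior_cortex)
  orient <- m[nrow(m), ] - m[1, ]
  fit_line_tls(pts, orient = orient)
}

#' Construct the femoral IM-guide line (Line B)
#'
#' Line A rotated into flexion by the implant's anterior flange angle, then
#' translated to be the supporting tangent of the posterior canal wall over the
#' rod-reachable region (the distal `im_rod_length` of the canal): the planned
#' IM rod path touches the posterior cortex of the medullary canal.
#'
#' @param femur A [femur_silhouette()].
#' @param implant An [implant_spec()] or implant name.
#' @return A [directed_line()] (Line B), direction pointing proximally.
#' @export
construct_im_guide_line <- function(femur, implant) {
  stopifnot(inherits(femur, "femur_silhouette"))
  implant <- get_implant(implant)
  line_a <- fit_anterior_cortex_line(femur)
  dir_b <- rotate_vec(line_a$direction, implant$anterior_flange_angle)
  wall <- femur$canal_posterior_wall
  cl <- curve_cumlen(wall)
  reach <- cl <= implant$im_rod_length
  if (sum(reach) < 2L)
    stop("planning error: rod-reachable canal region is degenerate")
  wall_sub <- polycurve(unclass(wall)[reach, , drop = FALSE])
  # support the wall from its anterior ("right" of proximal direction) side
  tangent_line_of_direction(wall_sub, dir_b, side = "right")
}

#' Femur entry distance (FED)
#'
#' The planned IM-rod entry: `a` is the Euclidean distance from the
#' intersection of Line B with the intercondylar groove profile to the most
#' distal notch roof; half the rod diameter is added, `fed = a + d/2` (4 mm for
#' the 8 mm rod). The value for surgical transfer is rounded to the nearest mm;
#' the stored value is unrounded.
#'
#' @param femur A [femur_silhouette()].
#' @param line_b The IM-guide [directed_line()].
#' @param implant An [implant_spec()] or implant name.
#' @return A list with `notch_distance_a`, `fed`, `fed_rounded` (mm) and the
#'   `entry_point`.
#' @export
compute_fed <- function(femur, line_b, implant) {
  implant <- get_implant(implant)
  hits <- line_curve_intersections(line_b, femur$groove_curve)
  if (nrow(hits) == 0L)
    stop("planning error: IM guide line does not intersect the intercondylar groove")
  d2 <- rowSums(sweep(hits, 2, femur$notch_roof)^2)
  entry <- hits[which.min(d2), ]
  a <- sqrt(sum((entry - femur$notch_roof)^2))
  fed <- a + implant$im_rod_diameter / 2
  list(notch_distance_a = a, fed = fed, fed_rounded = round(fed),
       entry_point = as.numeric(entry))
}

#' Femoral cortical-midline reference line (Line C)
#'
#' Through the midpoints of the outer cortical diameter at the posterior-cortex
#' points 7 cm and 11 cm (arc length) from the posterior Blumensaat point;
#' direction points proximally.
#'
#' @param femur A [femur_silhouette()].
#' @return A [directed_line()] (Line C).
#' @export
femur_reference_line <- function(femur) {
  stopifnot(inherits(femur, "femur_silhouette"))
  cortex_midline_line(femur$posterior_cortex, femur$anterior_cortex,
                      femur$blumensaat_posterior, c(70, 110))
}

# line through cortical midpoints at two arc positions along `ref_cortex`
# measured from `origin`; oriented from the first to the second position
cortex_midline_line <- function(ref_cortex, opposite, origin, arcs) {
  pr <- project_point_on_curve(ref_cortex, origin)
  mids <- lapply(arcs, function(s) {
    at <- point_at_curve_distance(ref_cortex, origin, s)
    ax <- curve_tangent_at(ref_cortex, pr$arc + s)
    cortical_midpoint(at, opposite, ax)
  })
  directed_line(mids[[1]], mids[[2]] - mids[[1]])
}

#' Preoperative gamma angle
#'
#' Signed angle between the planned IM-guide line and the femoral reference
#' line; positive values mean the planned distal resection plane is in flexion
#' relative to the cortical-midline axis.
#'
#' @param line_b Planned IM-guide [directed_line()].
#' @param line_c Femoral reference [directed_line()].
#' @return Angle in degrees; positive = flexion.
#' @export
preop_gamma <- function(line_b, line_c) {
  signed_angle(line_c, line_b)
}

#' Plan the femoral component's sagittal position
#'
#' Runs the full femoral construction: Line A (anterior cortex fit), Line B (IM
#' guide at the flange angle, tangent to the posterior canal), the entry
#' distance FED, Line C (cortical midline reference) and the preoperative gamma
#' angle.
#'
#' @param femur A [femur_silhouette()].
#' @param implant An [implant_spec()] or implant name.
#' @return An object of class `femur_plan` with fields `line_a`, `line_b`,
#'   `line_c`, `notch_distance_a`, `fed`, `fed_rounded`, `entry_point`,
#'   `preop_gamma` and `implant`.
#' @export
#' @examples
#' plan <- plan_femur(generate_femur(), "J2BCS")
#' plan$fed
plan_femur <- function(femur, implant) {
  implant <- get_implant(implant)
  line_a <- fit_anterior_cortex_line(femur)
  line_b <- construct_im_guide_line(femur, implant)
  fed <- compute_fed(femur, line_b, implant)
  line_c <- femur_reference_line(femur)
  structure(list(
    line_a = line_a, line_b = line_b, line_c = line_c,
    notch_distance_a = fed$notch_distance_a,
    fed = fed$fed, fed_rounded = fed$fed_rounded,
    entry_point = fed$entry_point,
    preop_gamma = preop_gamma(line_b, line_c),
    implant = implant
  ), class = "femur_plan")
}

#' @export
print.femur_plan <- function(x, ...) {
  cat("Femoral sagittal plan (", x$implant$name, ")\n", sep = "")
  cat(sprintf("  IM guide vs anterior cortex: %+.2f deg (anterior flange angle %g deg)\n",
              signed_angle(x$line_a, x$line_b), x$implant$anterior_flange_angle))
  cat(sprintf("  entry distance FED: %.1f mm (a = %.1f mm + rod radius %.1f mm); transfer %d mm\n",
              x$fed, x$notch_distance_a, x$implant$im_rod_diameter / 2,
              as.integer(x$fed_rounded)))
  cat(sprintf("  preoperative gamma angle: %+.2f deg (positive = flexion)\n",
              x$preop_gamma))
  invisible(x)
}
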