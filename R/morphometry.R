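# Radiographic morphometry: bowing angles, native tibial slope, soft-tissue
# thickness. All are positive-anterior/positive-posterior-slope signed per the
# radiographic convention and rigid-motion invariant.

#' Distal femur bowing angle (DFB)
#'
#' Angle between the cortical-midline of the 4-7 cm window and that of the
#' 11-14 cm window (arc length along the posterior cortex from the posterior
#' Blumensaat point). Positive = anterior bowing of the distal femur.
#'
#' @param femur A [femur_silhouette()].
#' @return Degrees.
#' @export
measure_dfb <- function(femur) {
  stopifnot(inherits(femur, "femur_silhouette"))
  near <- cortex_midline_line(femur$posterior_cortex, femur$anterior_cortex,
                              femur$blumensaat_posterior, c(40, 70))
  far <- cortex_midline_line(femur$posterior_cortex, femur$anterior_cortex,
                             femur$blumensaat_posterior, c(110, 140))
  # the far (proximal) segment tips anteriorly with anterior bowing; measuring
  # from the far to the near midline makes anterior bowing positive
  signed_angle(far, near)
}

#' Proximal tibia bowing angle (PTB)
#'
#' Angle between the cortical-midline of the 4-7 cm window and that of the
#' 11-14 cm window (arc length along the anterior cortex distal to the
#' tuberosity). Positive = anterior bowing of the proximal tibia.
#'
#' @param tibia A [tibia_silhouette()].
#' @return Degrees.
#' @export
measure_ptb <- function(tibia) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  near <- cortex_midline_line(tibia$anterior_cortex, tibia$posterior_cortex,
                              tibia$tuberosity, c(40, 70))
  far <- cortex_midline_line(tibia$anterior_cortex, tibia$posterior_cortex,
                             tibia$tuberosity, c(110, 140))
  # here the far segment tips anteriorly *distally*; with both midlines
  # traversed distally, near-to-far is the anterior-positive sense
  signed_angle(near, far)
}

#' Native posterior slope of the tibial plateau (TPS)
#'
#' Angle between the plateau line and the perpendicular of the tibial
#' cortical-midline reference axis (the 7/11 cm axis of
#' [tibia_reference_line()]); positive = posterior slope.
#'
#' @param tibia A [tibia_silhouette()].
#' @return Degrees.
#' @export
measure_tps <- function(tibia) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  if (is.null(tibia$plateau_line)) stop("tibia silhouette has no plateau line")
  ref <- tibia_reference_line(tibia)
  a_perp <- directed_line(ref$anchor, rotate_vec(ref$direction, -90))
  signed_angle(a_perp, tibia$plateau_line)
}

#' Anterior tibial soft-tissue thickness (TST)
#'
#' Perpendicular distance from the anterior-cortex point 7 cm distal to the
#' tuberosity to the anterior skin contour.
#'
#' @param tibia A [tibia_silhouette()].
#' @return Thickness in mm.
#' @export
measure_tst <- function(tibia) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  if (is.null(tibia$skin_anterior)) stop("tibia silhouette has no skin contour")
  p7 <- point_at_curve_distance(tibia$anterior_cortex, tibia$tuberosity, 70)
  project_point_on_curve(tibia$skin_anterior, p7)$dist
}

#' Morphometry report for a silhouette
#'
#' Runs the measurements that apply to the given bone: DFB for a femur; PTB,
#' TPS and TST for a tibia. The HKA angle is a coronal covariate carried
#' through the cohort table, never computed from sagittal geometry.
#'
#' @param sil A `femur_silhouette` or `tibia_silhouette`.
#' @return A named list of class `morphometry_report`.
#' @export
measure_silhouette <- function(sil) {
  rep <- if (inherits(sil, "femur_silhouette")) {
    list(bone = "femur", dfb = measure_dfb(sil))
  } else if (inherits(sil, "tibia_silhouette")) {
    list(bone = "tibia", ptb = measure_ptb(sil), tps = measure_tps(sil),
         tst = measure_tst(sil))
  } else stop("measure_silhouette: not a silhouette")
  structure(rep, class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat("<morphometry_report>", x$bone, "\n")
  for (nm in setdiff(names(x), "bone")) {
    unit <- if (nm == "tst") "mm" else "deg"
    cat(sprintf("  %s: %.2f %s\n", toupper(nm), x[[nm]], unit))
  }
  invisible(x)
}
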