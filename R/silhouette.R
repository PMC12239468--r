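# Silhouette containers: contours + named landmarks of one bone in the lateral
# view. These are the package's stand-in for an annotated radiograph.

FEMUR_CONTOURS <- c("anterior_cortex", "posterior_cortex",
                    "canal_anterior_wall", "canal_posterior_wall", "groove_curve")
FEMUR_LANDMARKS <- c("blumensaat_posterior", "notch_roof")
TIBIA_CONTOURS <- c("anterior_cortex", "posterior_cortex", "skin_anterior")
TIBIA_LANDMARKS <- c("tuberosity", "ankle_concavity")
TIBIA_LINES <- c("plateau_line", "fibular_axis")

#' Construct a femur silhouette
#'
#' Contours are ordered distal-to-proximal; `blumensaat_posterior` (the most
#' posterior point of the Blumensaat line) is the distal origin from which all
#' arc-length measurements along the posterior cortex are taken. Contours must
#' cover at least 140 mm of shaft so the 4-14 cm measurement windows exist.
#'
#' @param anterior_cortex,posterior_cortex Outer cortex [polycurve()]s.
#' @param canal_anterior_wall,canal_posterior_wall Medullary canal wall
#'   [polycurve()]s (strictly inside the outer cortices).
#' @param groove_curve Distal articular / intercondylar groove profile
#'   [polycurve()] crossed by the IM-guide line.
#' @param blumensaat_posterior,notch_roof Landmark points (mm).
#' @param provenance `"generated"` or `"annotated"`.
#' @return An object of class `femur_silhouette`.
#' @export
femur_silhouette <- function(anterior_cortex, posterior_cortex,
                             canal_anterior_wall, canal_posterior_wall,
                             groove_curve, blumensaat_posterior, notch_roof,
                             provenance = "annotated") {
  sil <- structure(list(
    anterior_cortex = polycurve(anterior_cortex),
    posterior_cortex = polycurve(posterior_cortex),
    canal_anterior_wall = polycurve(canal_anterior_wall),
    canal_posterior_wall = polycurve(canal_posterior_wall),
    groove_curve = polycurve(groove_curve),
    blumensaat_posterior = as.numeric(blumensaat_posterior),
    notch_roof = as.numeric(notch_roof),
    provenance = provenance
  ), class = "femur_silhouette")
  validate_femur_silhouette(sil)
  sil
}

validate_femur_silhouette <- function(sil) {
  pr <- project_point_on_curve(sil$posterior_cortex, sil$blumensaat_posterior)
  if (pr$dist > 1e-6)
    stop("femur silhouette: blumensaat_posterior must lie on the posterior cortex")
  reach <- curve_length(sil$posterior_cortex) - pr$arc
  if (reach < 140)
    stop(sprintf(paste0("femur silhouette: posterior cortex covers only %.0f mm ",
                        "beyond blumensaat_posterior; 140 mm required"), reach))
  invisible(sil)
}

#' Construct a tibia silhouette
#'
#' Contours are ordered proximal-to-distal; arc lengths along the anterior
#' cortex are measured distally from `tuberosity`. The skin contour carries the
#' anterior soft tissue; `plateau_line` carries the native posterior slope and
#' `fibular_axis` is the fibular shaft axis (FSA) used as the planning
#' reference.
#'
#' @param anterior_cortex,posterior_cortex Outer cortex [polycurve()]s.
#' @param skin_anterior Anterior skin [polycurve()].
#' @param tuberosity,ankle_concavity Landmark points (mm): the tibial
#'   tuberosity and the most concave anterior point around the ankle.
#' @param plateau_line [directed_line()] along the tibial plateau.
#' @param fibular_axis [directed_line()] along the fibular shaft, pointing
#'   proximally.
#' @param provenance `"generated"` or `"annotated"`.
#' @return An object of class `tibia_silhouette`.
#' @export
tibia_silhouette <- function(anterior_cortex, posterior_cortex, skin_anterior,
                             tuberosity, ankle_concavity, plateau_line,
                             fibular_axis, provenance = "annotated") {
  sil <- structure(list(
    anterior_cortex = polycurve(anterior_cortex),
    posterior_cortex = polycurve(posterior_cortex),
    skin_anterior = polycurve(skin_anterior),
    tuberosity = as.numeric(tuberosity),
    ankle_concavity = as.numeric(ankle_concavity),
    plateau_line = plateau_line,
    fibular_axis = fibular_axis,
    provenance = provenance
  ), class = "tibia_silhouette")
  validate_tibia_silhouette(sil)
  sil
}

validate_tibia_silhouette <- function(sil) {
  stopifnot(inherits(sil$plateau_line, "directed_line"),
            inherits(sil$fibular_axis, "directed_line"))
  pr <- project_point_on_curve(sil$anterior_cortex, sil$tuberosity)
  if (pr$dist > 1e-6)
    stop("tibia silhouette: tuberosity must lie on the anterior cortex")
  reach <- curve_length(sil$anterior_cortex) - pr$arc
  if (reach < 140)
    stop(sprintf(paste0("tibia silhouette: anterior cortex covers only %.0f mm ",
                        "distal to the tuberosity; 140 mm required"), reach))
  invisible(sil)
}

#' @export
print.femur_silhouette <- function(x, ...) {
  cat("<femur_silhouette>", x$provenance, "\n")
  cat(sprintf("  posterior cortex: %.0f mm of shaft beyond Blumensaat point\n",
              curve_length(x$posterior_cortex)))
  cat(sprintf("  notch roof at (%.1f, %.1f) mm\n", x$notch_roof[1], x$notch_roof[2]))
  invisible(x)
}

#' @export
print.tibia_silhouette <- function(x, ...) {
  cat("<tibia_silhouette>", x$provenance, "\n")
  cat(sprintf("  anterior cortex: %.0f mm distal to tuberosity\n",
              curve_length(x$anterior_cortex)))
  invisible(x)
}

#' Apply a rigid motion to a silhouette
#'
#' Rotates by `angle` degrees about the origin and then translates by `shift`.
#' All planning and measurement operations are invariant under this motion.
#'
#' @param sil A `femur_silhouette` or `tibia_silhouette`.
#' @param angle Rotation in degrees (CCW positive).
#' @param shift Length-2 translation in mm.
#' @return The transformed silhouette.
#' @export
rigid_transform <- function(sil, angle = 0, shift = c(0, 0)) {
  tr_curve <- function(cv) rigid_curve(cv, angle, shift)
  tr_pt <- function(p) rigid_point(p, angle, shift)
  if (inherits(sil, "femur_silhouette")) {
    femur_silhouette(
      tr_curve(sil$anterior_cortex), tr_curve(sil$posterior_cortex),
      tr_curve(sil$canal_anterior_wall), tr_curve(sil$canal_posterior_wall),
      tr_curve(sil$groove_curve), tr_pt(sil$blumensaat_posterior),
      tr_pt(sil$notch_roof), provenance = sil$provenance)
  } else if (inherits(sil, "tibia_silhouette")) {
    tibia_silhouette(
      tr_curve(sil$anterior_cortex), tr_curve(sil$posterior_cortex),
      tr_curve(sil$skin_anterior), tr_pt(sil$tuberosity),
      tr_pt(sil$ankle_concavity), rigid_line(sil$plateau_line, angle, shift),
      rigid_line(sil$fibular_axis, angle, shift), provenance = sil$provenance)
  } else stop("rigid_transform: not a silhouette")
}
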