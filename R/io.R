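# File interchange: JSON silhouettes and plan reports, CSV cohort tables.

SILHOUETTE_SCHEMA <- "sagplan-silhouette-1"
FRAME_NOTE <- "x: anterior(+)/posterior(-); y: proximal(+)/distal(-)"

line_to_list <- function(l) list(anchor = unname(l$anchor),
                                 direction = unname(l$direction))
line_from_list <- function(x) directed_line(as.numeric(x$anchor),
                                            as.numeric(x$direction))

#' Write a silhouette to a JSON interchange file
#'
#' The file declares schema, bone, units (mm), coordinate frame and
#' provenance, and stores named landmark points, named contour point lists and
#' named lines at full precision; [read_silhouette()] round-trips the values
#' exactly.
#'
#' @param sil A `femur_silhouette` or `tibia_silhouette`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_silhouette <- function(sil, path) {
  if (inherits(sil, "femur_silhouette")) {
    body <- list(
      schema = SILHOUETTE_SCHEMA, bone = "femur", units = "mm",
      frame = FRAME_NOTE, provenance = sil$provenance,
      landmarks = list(blumensaat_posterior = unname(sil$blumensaat_posterior),
                       notch_roof = unname(sil$notch_roof)),
      contours = stats::setNames(
        lapply(FEMUR_CONTOURS, function(nm) unclass(sil[[nm]])), FEMUR_CONTOURS),
      lines = list())
  } else if (inherits(sil, "tibia_silhouette")) {
    body <- list(
      schema = SILHOUETTE_SCHEMA, bone = "tibia", units = "mm",
      frame = FRAME_NOTE, provenance = sil$provenance,
      landmarks = list(tuberosity = unname(sil$tuberosity),
                       ankle_concavity = unname(sil$ankle_concavity)),
      contours = stats::setNames(
        lapply(TIBIA_CONTOURS, function(nm) unclass(sil[[nm]])), TIBIA_CONTOURS),
      lines = list(plateau_line = line_to_list(sil$plateau_line),
                   fibular_axis = line_to_list(sil$fibular_axis)))
  } else stop("write_silhouette: not a silhouette")
  jsonlite::write_json(body, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a silhouette from a JSON interchange file
#'
#' Validates schema, units and the presence of every required landmark,
#' contour and line for the declared bone; all geometric invariants are
#' re-checked on load.
#'
#' @param path Path to a file written by [write_silhouette()].
#' @return A `femur_silhouette` or `tibia_silhouette`.
#' @export
read_silhouette <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, SILHOUETTE_SCHEMA))
    stop("unrecognised silhouette schema: ", x$schema %||% "<missing>")
  if (!identical(x$units, "mm")) stop("silhouette units must be mm")
  need <- function(what, names, where) {
    miss <- setdiff(names, names(where))
    if (length(miss))
      stop(sprintf("silhouette file is missing %s: %s", what,
                   paste(miss, collapse = ", ")))
  }
  if (identical(x$bone, "femur")) {
    need("landmark(s)", FEMUR_LANDMARKS, x$landmarks)
    need("contour(s)", FEMUR_CONTOURS, x$contours)
    femur_silhouette(
      anterior_cortex = x$contours$anterior_cortex,
      posterior_cortex = x$contours$posterior_cortex,
      canal_anterior_wall = x$contours$canal_anterior_wall,
      canal_posterior_wall = x$contours$canal_posterior_wall,
      groove_curve = x$contours$groove_curve,
      blumensaat_posterior = x$landmarks$blumensaat_posterior,
      notch_roof = x$landmarks$notch_roof,
      provenance = x$provenance %||% "annotated")
  } else if (identical(x$bone, "tibia")) {
    need("landmark(s)", TIBIA_LANDMARKS, x$landmarks)
    need("contour(s)", TIBIA_CONTOURS, x$contours)
    need("line(s)", TIBIA_LINES, x$lines)
    tibia_silhouette(
      anterior_cortex = x$contours$anterior_cortex,
      posterior_cortex = x$contours$posterior_cortex,
      skin_anterior = x$contours$skin_anterior,
      tuberosity = x$landmarks$tuberosity,
      ankle_concavity = x$landmarks$ankle_concavity,
      plateau_line = line_from_list(x$lines$plateau_line),
      fibular_axis = line_from_list(x$lines$fibular_axis),
      provenance = x$provenance %||% "annotated")
  } else stop("silhouette file must declare bone 'femur' or 'tibia'")
}

#' Write a plan report to JSON
#'
#' A structured record of a femoral or tibial plan: the scalar results (FED
#' raw and mm-rounded, PSA, offsets, preoperative angle) and the constructed
#' lines (anchor + direction) for overlay plotting.
#'
#' @param plan A `femur_plan` or `tibia_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_report <- function(plan, path) {
  if (inherits(plan, "femur_plan")) {
    body <- list(
      type = "femur_plan", implant = plan$implant$name,
      fed = plan$fed, fed_rounded = plan$fed_rounded,
      notch_distance_a = plan$notch_distance_a,
      entry_point = unname(plan$entry_point),
      preop_gamma = plan$preop_gamma,
      lines = list(line_a = line_to_list(plan$line_a),
                   line_b = line_to_list(plan$line_b),
                   line_c = line_to_list(plan$line_c)))
  } else if (inherits(plan, "tibia_plan")) {
    body <- list(
      type = "tibia_plan", implant = plan$implant$name,
      psa = plan$psa,
      offset_b = plan$offset_b, offset_c = plan$offset_c,
      offset_diff = plan$offset_diff,
      offset_diff_rounded = plan$offset_diff_rounded,
      preop_delta = plan$preop_delta,
      lines = list(fsa_line = line_to_list(plan$fsa_line),
                   em_line = line_to_list(plan$em_line),
                   line_c = line_to_list(plan$line_c)))
  } else stop("write_plan_report: not a plan")
  jsonlite::write_json(body, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Write a cohort table to CSV
#'
#' Deterministic serialisation (full precision, no row names); identical
#' configuration and seed give byte-identical files.
#'
#' @param table A `tka_cohort` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
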