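# Tibial sagittal planning: planning slope angle (PSA), EM guide line from the
# fibular shaft axis, anterior offset distances, cortical-midline reference and
# the preoperative delta angle.
#
# The counter-clockwise sense in the (anterior, proximal) frame increases the
# posterior slope of the planned resection; the EM guide is drawn "in
# extension" by PSA in that sense relative to the FSA.

#' Planning-slope-angle policy
#'
#' The validation cohort's PSA was surgeon-chosen (baseline 0 deg to the FSA,
#' increased when the native slope was large, observed range -1 to 4 deg); no
#' formula is reported. The policy makes the choice explicit and auditable:
#' `fixed` always returns `fixed_value`; `slope_adaptive` returns
#' `gain * max(0, native_tps - threshold_tps)`, clamped to `[floor, cap]`.
#'
#' @param mode `"fixed"` or `"slope_adaptive"`.
#' @param fixed_value PSA in degrees for `fixed` mode.
#' @param threshold_tps Native slope above which extra PSA is added, degrees.
#' @param gain Degrees of PSA per degree of excess native slope.
#' @param cap,floor Output bounds in degrees (default the observed range
#'   `[-1, 4]`).
#' @return An object of class `psa_policy`.
#' @export
#' @examples
#' choose_psa(18, psa_policy("slope_adaptive", threshold_tps = 10, gain = 0.5))
psa_policy <- function(mode = c("fixed", "slope_adaptive"), fixed_value = 0,
                       threshold_tps = 10, gain = 0.5, cap = 4, floor = -1) {
  mode <- match.arg(mode)
  stopifnot(cap >= floor, gain >= 0)
  structure(list(mode = mode, fixed_value = fixed_value,
                 threshold_tps = threshold_tps, gain = gain,
                 cap = cap, floor = floor),
            class = "psa_policy")
}

#' Choose the planning slope angle
#'
#' @param native_tps Native posterior tibial slope, degrees.
#' @param policy A [psa_policy()].
#' @return PSA in degrees, clamped to the policy bounds.
#' @export
choose_psa <- function(native_tps, policy = psa_policy()) {
  stopifnot(inherits(policy, "psa_policy"), is.finite(native_tps))
  raw <- switch(policy$mode,
    fixed = policy$fixed_value,
    slope_adaptive = policy$gain * max(0, native_tps - policy$threshold_tps))
  min(max(raw, policy$floor), policy$cap)
}

#' Construct the tibial EM-guide line
#'
#' The fibular shaft axis rotated by `psa` degrees in the slope-increasing
#' (extension) sense, re-anchored in front of the tibia. The anchor choice does
#' not affect the offset difference or the delta angle (both depend only on the
#' line's direction and the anatomy).
#'
#' @param tibia A [tibia_silhouette()].
#' @param psa Planning slope angle, degrees.
#' @param anchor_offset Distance anterior to the tuberosity at which the guide
#'   line is anchored, mm.
#' @return A [directed_line()], direction pointing proximally.
#' @export
construct_em_guide_line <- function(tibia, psa, anchor_offset = 25) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  dir_em <- rotate_vec(tibia$fibular_axis$direction, psa)
  anterior <- rotate_vec(dir_em, -90)
  directed_line(tibia$tuberosity + anchor_offset * anterior, dir_em)
}

#' Anterior offset distances to the EM-guide line
#'
#' Distances from two anterior points to the guide line: `offset_b` at the
#' point 7 cm distal along the anterior cortex from the tuberosity and
#' `offset_c` at the most concave anterior point around the ankle. Their
#' difference `offset_c - offset_b` is the value transferred to the operating
#' field when positioning the EM guide.
#'
#' @param tibia A [tibia_silhouette()].
#' @param em_line The EM-guide [directed_line()].
#' @return A list with `offset_b`, `offset_c`, `offset_diff` (mm) and the 7 cm
#'   point used.
#' @export
compute_offsets <- function(tibia, em_line) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  p7 <- point_at_curve_distance(tibia$anterior_cortex, tibia$tuberosity, 70)
  b <- point_line_distance(p7, em_line)
  cc <- point_line_distance(tibia$ankle_concavity, em_line)
  list(offset_b = b, offset_c = cc, offset_diff = cc - b, point_7cm = p7)
}

#' Tibial cortical-midline reference line (Line C)
#'
#' Through the midpoints of the outer cortical diameter at the anterior-cortex
#' points 7 cm and 11 cm (arc length) distal to the tuberosity; direction
#' points proximally.
#'
#' @param tibia A [tibia_silhouette()].
#' @return A [directed_line()].
#' @export
tibia_reference_line <- function(tibia) {
  stopifnot(inherits(tibia, "tibia_silhouette"))
  l <- cortex_midline_line(tibia$anterior_cortex, tibia$posterior_cortex,
                           tibia$tuberosity, c(70, 110))
  # arcs run distally; flip so the direction points proximally
  directed_line(l$anchor, -l$direction)
}

#' Preoperative delta angle
#'
#' Signed angle between the EM-guide line and the tibial reference line;
#' positive values mean the planned resection has more posterior slope.
#'
#' @param em_line Planned EM-guide [directed_line()].
#' @param line_c Tibial reference [directed_line()].
#' @return Angle in degrees; positive = increased posterior slope.
#' @export
preop_delta <- function(em_line, line_c) {
  signed_angle(line_c, em_line)
}

#' Plan the tibial component's sagittal position
#'
#' Chooses the PSA (explicit value or policy applied to the measured native
#' slope), constructs the EM-guide line from the fibular shaft axis, computes
#' the two anterior offsets and their difference, the cortical-midline
#' reference and the preoperative delta angle.
#'
#' @param tibia A [tibia_silhouette()].
#' @param implant An [implant_spec()] or implant name (carried for the
#'   execution stage's slope-guide correction).
#' @param psa Planning slope angle in degrees; if `NULL`, chosen by `policy`
#'   from the measured native slope.
#' @param policy A [psa_policy()] used when `psa` is `NULL`.
#' @return An object of class `tibia_plan` with fields `fsa_line`, `em_line`,
#'   `line_c`, `psa`, `offset_b`, `offset_c`, `offset_diff`,
#'   `offset_diff_rounded`, `preop_delta` and `implant`.
#' @export
#' @examples
#' plan <- plan_tibia(generate_tibia(), "J2BCS")
#' plan$preop_delta
plan_tibia <- function(tibia, implant, psa = NULL, policy = psa_policy()) {
  implant <- get_implant(implant)
  if (is.null(psa)) psa <- choose_psa(measure_tps(tibia), policy)
  em <- construct_em_guide_line(tibia, psa)
  off <- compute_offsets(tibia, em)
  line_c <- tibia_reference_line(tibia)
  structure(list(
    fsa_line = tibia$fibular_axis, em_line = em, line_c = line_c,
    psa = psa,
    offset_b = off$offset_b, offset_c = off$offset_c,
    offset_diff = off$offset_diff,
    offset_diff_rounded = round(off$offset_diff),
    preop_delta = preop_delta(em, line_c),
    implant = implant
  ), class = "tibia_plan")
}

#' @export
print.tibia_plan <- function(x, ...) {
  cat("Tibial sagittal plan (", x$implant$name, ")\n", sep = "")
  cat(sprintf("  PSA: %+.2f deg relative to the fibular shaft axis\n", x$psa))
  cat(sprintf("  offsets to EM guide: b = %.1f mm (7 cm point), c = %.1f mm (ankle); c - b = %.1f mm (transfer %d mm)\n",
              x$offset_b, x$offset_c, x$offset_diff,
              as.integer(x$offset_diff_rounded)))
  cat(sprintf("  preoperative delta angle: %+.2f deg (positive = more posterior slope)\n",
              x$preop_delta))
  invisible(x)
}
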