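# Simulated surgical execution and validation: apply rotational execution
# error to the planned guide lines, re-measure the postoperative gamma/delta
# angles against the same cortical-midline references, correct for the implant
# slope guide, and classify against the +/-2 degree target range.

#' Execution error model
#'
#' Rotational execution error applied to the planned resection orientations:
#' gamma error rotates the femoral IM-guide line about the entry point, delta
#' error rotates the tibial guide about its anchor. The default values are a
#' demonstration model calibrated to reproduce cohort-scale accuracy; they are
#' not reported by the validation study. `zero_error_model()` gives exact
#' execution.
#'
#' @param gamma_bias,gamma_sd Femoral error bias / SD, degrees (positive bias =
#'   flexion).
#' @param delta_bias,delta_sd Tibial error bias / SD, degrees (positive bias =
#'   more posterior slope).
#' @param distribution `"normal"` or `"truncated_normal"` (+/- 3 SD).
#' @return An object of class `execution_error_model`.
#' @export
execution_error_model <- function(gamma_bias = 1.2, gamma_sd = 1.8,
                                  delta_bias = 0, delta_sd = 0.9,
                                  distribution = c("normal", "truncated_normal")) {
  distribution <- match.arg(distribution)
  stopifnot(gamma_sd >= 0, delta_sd >= 0)
  structure(list(gamma_bias = gamma_bias, gamma_sd = gamma_sd,
                 delta_bias = delta_bias, delta_sd = delta_sd,
                 distribution = distribution),
            class = "execution_error_model")
}

#' @rdname execution_error_model
#' @export
zero_error_model <- function() {
  execution_error_model(gamma_bias = 0, gamma_sd = 0,
                        delta_bias = 0, delta_sd = 0)
}

draw_error <- function(bias, sd, distribution) {
  if (sd == 0) return(bias)
  if (distribution == "truncated_normal") {
    repeat {
      x <- stats::rnorm(1, bias, sd)
      if (abs(x - bias) <= 3 * sd) return(x)
    }
  }
  stats::rnorm(1, bias, sd)
}

#' Execute a plan with simulated error
#'
#' The achieved femoral orientation is the planned IM-guide line rotated by a
#' sampled gamma error about the entry point; the achieved tibial orientation
#' is the planned EM-guide line rotated by the implant's slope-guide extra plus
#' a sampled delta error. Uses the current RNG state; seed upstream (e.g. in
#' [run_cohort()]) for reproducibility.
#'
#' @param femur_plan A [plan_femur()] result.
#' @param tibia_plan A [plan_tibia()] result.
#' @param error_model An [execution_error_model()].
#' @return An object of class `execution` with the achieved orientations
#'   (resection-plane perpendiculars, as [directed_line()]s) and the sampled
#'   errors.
#' @export
execute_plan <- function(femur_plan, tibia_plan,
                         error_model = execution_error_model()) {
  stopifnot(inherits(femur_plan, "femur_plan"), inherits(tibia_plan, "tibia_plan"),
            inherits(error_model, "execution_error_model"))
  ge <- draw_error(error_model$gamma_bias, error_model$gamma_sd,
                   error_model$distribution)
  de <- draw_error(error_model$delta_bias, error_model$delta_sd,
                   error_model$distribution)
  extra <- slope_guide_extra(tibia_plan$implant)
  achieved_f <- if (ge == 0) femur_plan$line_b else
    rotate_line(femur_plan$line_b, femur_plan$entry_point, ge)
  rot_t <- extra + de
  achieved_t <- if (rot_t == 0) tibia_plan$em_line else
    rotate_line(tibia_plan$em_line, tibia_plan$em_line$anchor, rot_t)
  structure(list(achieved_femoral = achieved_f, achieved_tibial = achieved_t,
                 gamma_error = ge, delta_error = de,
                 slope_guide_extra = extra),
            class = "execution")
}

#' Postoperative gamma angle
#'
#' Signed angle between the achieved distal-femur resection-plane perpendicular
#' and the femoral cortical-midline reference line, same sign convention as
#' [preop_gamma()] (positive = flexion).
#'
#' @param femur A [femur_silhouette()].
#' @param achieved_femoral Achieved orientation ([directed_line()], the
#'   resection-plane perpendicular).
#' @return Degrees.
#' @export
postop_gamma <- function(femur, achieved_femoral) {
  signed_angle(femur_reference_line(femur), achieved_femoral)
}

#' Postoperative delta angle
#'
#' Signed angle between the achieved proximal-tibia resection-plane
#' perpendicular and the tibial reference line, same sign convention as
#' [preop_delta()] (positive = more posterior slope).
#'
#' @param tibia A [tibia_silhouette()].
#' @param achieved_tibial Achieved orientation ([directed_line()]).
#' @return Degrees.
#' @export
postop_delta <- function(tibia, achieved_tibial) {
  signed_angle(tibia_reference_line(tibia), achieved_tibial)
}

#' Implant-corrected pre/post differences
#'
#' `gamma_diff = postop - preop`. For the tibia, systems with a tilted stem
#' (J2BCS, Exult) implement 3 degrees more posterior slope than planned through
#' their provided slope guide, so `delta_diff = postop - preop - extra`, with
#' `extra = 0` for neutral-stem systems (Physica, U2).
#'
#' @param preop_gamma,postop_gamma Femoral angles, degrees.
#' @param preop_delta,postop_delta Tibial angles, degrees.
#' @param implant An [implant_spec()] or implant name.
#' @return A list with `gamma_diff` and `delta_diff` (degrees).
#' @export
corrected_differences <- function(preop_gamma, postop_gamma,
                                  preop_delta, postop_delta, implant) {
  implant <- get_implant(implant)
  list(gamma_diff = postop_gamma - preop_gamma,
       delta_diff = postop_delta - preop_delta - slope_guide_extra(implant))
}

#' Target-range classification
#'
#' The target range for the pre/post angle difference is the closed interval
#' from -2 to +2 degrees (boundary inclusive).
#'
#' @param diff Angle difference, degrees.
#' @param target Half-width of the target interval, degrees.
#' @return Logical.
#' @export
within_target <- function(diff, target = 2) {
  stopifnot(is.finite(diff))
  abs(diff) <= target + 1e-12
}

#' Detect anterior femoral notching
#'
#' Models the anterior resection: its plane lies at the implant's anterior
#' flange angle in extension from the achieved IM axis (so exact execution
#' makes it parallel to the fitted anterior cortex line), anchored where the
#' distal resection (perpendicular to the achieved axis through the entry
#' point) exits the anterior cortex. The flange exit point -- `flange_reach` mm
#' up that plane -- is compared against the anterior cortex at the same level:
#' notching is flagged when the exit point lies posterior to the cortex, i.e.
#' the anterior cut has undermined it.
#'
#' @param femur A [femur_silhouette()].
#' @param achieved_femoral Achieved IM-axis [directed_line()].
#' @param implant An [implant_spec()] or implant name.
#' @param flange_reach Proximal extent of the anterior flange cut, mm.
#' @return Logical: `TRUE` if the flange cut transects the anterior cortex.
#' @export
detect_notching <- function(femur, achieved_femoral, implant,
                            flange_reach = 45) {
  implant <- get_implant(implant)
  hits <- line_curve_intersections(achieved_femoral, femur$groove_curve)
  if (nrow(hits) == 0L)
    stop("achieved axis does not reach the intercondylar groove")
  d2 <- rowSums(sweep(hits, 2, femur$notch_roof)^2)
  entry <- as.numeric(hits[which.min(d2), ])
  # distal resection: perpendicular to the achieved axis through the entry
  resect <- directed_line(entry, rotate_vec(achieved_femoral$direction, -90))
  ac_hits <- line_curve_intersections(resect, femur$anterior_cortex)
  if (nrow(ac_hits) == 0L)
    stop("contour coverage error: distal resection does not reach the anterior cortex")
  d2a <- rowSums(sweep(ac_hits, 2, entry)^2)
  p_a <- as.numeric(ac_hits[which.min(d2a), ])
  flange_dir <- rotate_vec(achieved_femoral$direction,
                           -implant$anterior_flange_angle)
  q <- p_a + flange_reach * flange_dir
  # compare against the cortex at q's level (chord perpendicular to the axis)
  level <- directed_line(q, rotate_vec(achieved_femoral$direction, -90))
  cx <- line_curve_intersections(level, femur$anterior_cortex)
  if (nrow(cx) == 0L) return(FALSE)   # flange exits beyond contour coverage
  d2c <- rowSums(sweep(cx, 2, q)^2)
  cq <- as.numeric(cx[which.min(d2c), ])
  anterior <- rotate_vec(achieved_femoral$direction, -90)
  sum((q - cq) * anterior) < -1e-9
}

#' Assemble a per-case validation record
#'
#' Combines plans and an executed case into the flat record used by the cohort
#' table: pre/post gamma and delta, implant-corrected differences, target-range
#' flags and the notching flag.
#'
#' @param femur,tibia The silhouettes.
#' @param femur_plan,tibia_plan The plans.
#' @param execution An [execute_plan()] result.
#' @return A list of class `case_result`.
#' @export
case_result <- function(femur, tibia, femur_plan, tibia_plan, execution) {
  pg <- femur_plan$preop_gamma
  qg <- postop_gamma(femur, execution$achieved_femoral)
  pd <- tibia_plan$preop_delta
  qd <- postop_delta(tibia, execution$achieved_tibial)
  diffs <- corrected_differences(pg, qg, pd, qd, femur_plan$implant)
  structure(list(
    preop_gamma = pg, postop_gamma = qg, gamma_diff = diffs$gamma_diff,
    preop_delta = pd, postop_delta = qd, delta_diff = diffs$delta_diff,
    gamma_within = within_target(diffs$gamma_diff),
    delta_within = within_target(diffs$delta_diff),
    notching = detect_notching(femur, execution$achieved_femoral,
                               femur_plan$implant),
    implant = femur_plan$implant$name
  ), class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result> %s\n", x$implant))
  cat(sprintf("  gamma: %+0.2f -> %+0.2f deg (diff %+0.2f, %s)\n",
              x$preop_gamma, x$postop_gamma, x$gamma_diff,
              if (x$gamma_within) "within target" else "outside target"))
  cat(sprintf("  delta: %+0.2f -> %+0.2f deg (corrected diff %+0.2f, %s)\n",
              x$preop_delta, x$postop_delta, x$delta_diff,
              if (x$delta_within) "within target" else "outside target"))
  cat(sprintf("  anterior notching: %s\n", if (x$notching) "YES" else "no"))
  invisible(x)
}
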