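# Implant configuration records.

#' Create an implant specification
#'
#' Sagittal configuration of a posterior-stabilised TKA system: the anterior
#' flange angle of the femoral component (degrees between the anterior flange
#' and the stem/IM axis), the sagittal tilt of the tibial stem, the angle of the
#' tibial slope guide supplied with the instrumentation, and the IM rod
#' geometry. Systems whose tibial stem is tilted ship a matching slope guide so
#' the stem clears the posterior tibial cortex; using it implements a posterior
#' slope that exceeds the plan by the guide angle, which the validation
#' arithmetic corrects for (see [corrected_differences()]).
#'
#' @param name Implant label.
#' @param anterior_flange_angle Degrees, >= 0.
#' @param tibia_stem_angle Sagittal stem tilt, degrees >= 0.
#' @param tibia_slope_guide Slope-guide angle, degrees >= 0.
#' @param im_rod_diameter IM rod diameter, mm > 0.
#' @param im_rod_length IM rod length, mm > 0.
#' @return An object of class `implant_spec`.
#' @export
#' @examples
#' implant_spec("J2BCS", 3, 3, 3)
implant_spec <- function(name, anterior_flange_angle, tibia_stem_angle,
                         tibia_slope_guide, im_rod_diameter = 8,
                         im_rod_length = 350) {
  stopifnot(anterior_flange_angle >= 0, tibia_stem_angle >= 0,
            tibia_slope_guide >= 0, im_rod_diameter > 0, im_rod_length > 0)
  structure(list(name = name,
                 anterior_flange_angle = anterior_flange_angle,
                 tibia_stem_angle = tibia_stem_angle,
                 tibia_slope_guide = tibia_slope_guide,
                 im_rod_diameter = im_rod_diameter,
                 im_rod_length = im_rod_length),
            class = "implant_spec")
}

#' @export
print.implant_spec <- function(x, ...) {
  cat(sprintf(paste0("<implant_spec> %s: flange %g deg, stem %g deg, ",
                     "slope guide %g deg, rod %g x %g mm\n"),
              x$name, x$anterior_flange_angle, x$tibia_stem_angle,
              x$tibia_slope_guide, x$im_rod_diameter, x$im_rod_length))
  invisible(x)
}

#' The four study implant systems
#'
#' Sagittal configuration of the four posterior-stabilised systems used in the
#' validation cohort: J2BCS (flange 3 deg, stem 3 deg, slope guide 3 deg),
#' Physica (5/0/0), U2 (5/0/0) and Exult (5/3/3). All use an 8 mm x 350 mm IM
#' rod.
#'
#' @return A named list of [implant_spec()] objects.
#' @export
#' @examples
#' implant_library()$Physica
implant_library <- function() {
  list(
    J2BCS   = implant_spec("J2BCS", 3, 3, 3),
    Physica = implant_spec("Physica", 5, 0, 0),
    U2      = implant_spec("U2", 5, 0, 0),
    Exult   = implant_spec("Exult", 5, 3, 3)
  )
}

get_implant <- function(implant) {
  if (inherits(implant, "implant_spec")) return(implant)
  if (is.character(implant) && length(implant) == 1L) {
    lib <- implant_library()
    if (!implant %in% names(lib))
      stop(sprintf("unknown implant '%s' (known: %s)", implant,
                   paste(names(lib), collapse = ", ")))
    return(lib[[implant]])
  }
  stop("implant must be an implant_spec or the name of a known implant")
}

# additional slope implemented by the provided slope guide of tilted-stem
# systems; 0 for neutral-stem systems
slope_guide_extra <- function(implant) {
  implant <- get_implant(implant)
  if (implant$tibia_stem_angle > 0) implant$tibia_slope_guide else 0
}
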