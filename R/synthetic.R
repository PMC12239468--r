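# Parametric lateral-silhouette generator.
#
# The bone model is piecewise linear with a single bowing hinge 90 mm from the
# distal reference landmark -- the midpoint between the 4-7 cm and 11-14 cm
# bowing measurement windows -- so that the window-midline bowing measurement
# recovers the generating parameter by construction. Anterior bowing (positive)
# tips the far shaft segment anteriorly, towards the mid-diaphyseal apex of the
# bow. Condylar/metaphyseal proportions are typical lateral-radiograph
# stand-ins, configurable, and not cohort-derived.

HINGE_MM <- 90

#' Femur generation parameters
#'
#' @param dfb Distal femur bowing in degrees; positive = anterior bowing.
#' @param shaft_length Shaft coverage proximal to the Blumensaat point, mm
#'   (>= 160 so all constructions out to 14 cm exist).
#' @param outer_diameter Outer cortical AP diameter of the shaft, mm.
#' @param canal_diameter Medullary canal AP diameter of the diaphysis, mm.
#' @param condyle_depth Distal extent of the condylar block below the
#'   Blumensaat level, mm.
#' @param notch_roof_offset Offset of the most distal intercondylar notch roof
#'   from the condylar origin, mm.
#' @return An object of class `femur_params`.
#' @export
femur_params <- function(dfb = 4.4, shaft_length = 230, outer_diameter = 28,
                         canal_diameter = 13, condyle_depth = 25,
                         notch_roof_offset = c(6, -8)) {
  stopifnot(is.finite(dfb), shaft_length >= 160,
            canal_diameter < outer_diameter, canal_diameter > 0,
            condyle_depth > 0, length(notch_roof_offset) == 2L)
  structure(list(dfb = dfb, shaft_length = shaft_length,
                 outer_diameter = outer_diameter,
                 canal_diameter = canal_diameter,
                 condyle_depth = condyle_depth,
                 notch_roof_offset = as.numeric(notch_roof_offset)),
            class = "femur_params")
}

#' Tibia generation parameters
#'
#' @param ptb Proximal tibia bowing in degrees; positive = anterior bowing.
#' @param native_tps Native posterior slope of the tibial plateau, degrees.
#' @param tst Anterior soft-tissue thickness at the 7 cm point, mm (>= 0).
#' @param shaft_length Shaft coverage distal to the tuberosity, mm (>= 160).
#' @param outer_diameter Outer cortical AP diameter of the shaft, mm.
#' @param fibula_offset Posterior offset of the fibular shaft axis from the
#'   posterior cortex, mm.
#' @return An object of class `tibia_params`.
#' @export
tibia_params <- function(ptb = 2.0, native_tps = 8.2, tst = 8.8,
                         shaft_length = 300, outer_diameter = 24,
                         fibula_offset = 12) {
  stopifnot(is.finite(ptb), is.finite(native_tps), tst >= 0,
            shaft_length >= 160, outer_diameter > 0)
  structure(list(ptb = ptb, native_tps = native_tps, tst = tst,
                 shaft_length = shaft_length, outer_diameter = outer_diameter,
                 fibula_offset = fibula_offset),
            class = "tibia_params")
}

# vertex parameters for the shaft: denser where the metaphyseal flare varies
shaft_breaks <- function(len, hinge = HINGE_MM, flare_end = 45) {
  sort(unique(c(seq(0, min(flare_end, len), by = 2.5),
                seq(min(flare_end, len), hinge, by = 5),
                hinge,
                seq(hinge, len, by = 5), len)))
}

#' Generate a synthetic lateral femur silhouette
#'
#' Builds a two-segment shaft (hinge 90 mm proximal to the Blumensaat point)
#' whose segment midlines meet at exactly `params$dfb`, with concentric canal
#' walls, a distal metaphyseal flare, and a condylar block carrying the
#' intercondylar groove profile and notch-roof landmark. The silhouette is
#' produced in the canonical frame (Blumensaat point near the origin); apply
#' [rigid_transform()] for an arbitrarily posed bone.
#'
#' @param params A [femur_params()] object.
#' @return A [femur_silhouette()].
#' @export
#' @examples
#' f <- generate_femur(femur_params(dfb = 4.4))
#' measure_dfb(f)
generate_femur <- function(params = femur_params()) {
  stopifnot(inherits(params, "femur_params"))
  L <- params$shaft_length
  od2 <- params$outer_diameter / 2
  cd2 <- params$canal_diameter / 2
  bow <- params$dfb / (180 / pi)

  # segment directions: distal along +y, proximal tipped anteriorly for
  # positive (anterior) bowing
  d1 <- c(0, 1)
  d2 <- c(sin(bow), cos(bow))
  mid <- function(t) {
    if (t <= HINGE_MM) c(0, t) else c(0, HINGE_MM) + (t - HINGE_MM) * d2
  }
  dirat <- function(t) if (t <= HINGE_MM) d1 else d2
  # anterior unit normal of the midline at t (rotate the proximally-pointing
  # direction clockwise by 90 degrees)
  ant <- function(t) { d <- dirat(t); c(d[2], -d[1]) }

  # anterior flare kept distal to the 4 cm fit/measurement windows
  flare_ant <- function(t) 10 * pmax(0, (22 - t) / 22)
  flare_post <- function(t) 4 * pmax(0, (25 - t) / 25)
  flare_canal <- function(t) 8 * pmax(0, (40 - t) / 40)
  if (cd2 + flare_canal(0) >= od2 + min(flare_ant(0), flare_post(0)))
    stop("generation error: canal exits the cortex for these parameters")

  ts <- shaft_breaks(L)
  offset_curve <- function(radius_fun, sign) {
    polycurve(t(vapply(ts, function(t) mid(t) + sign * radius_fun(t) * ant(t),
                       numeric(2))))
  }
  anterior_shaft <- offset_curve(function(t) od2 + flare_ant(t), +1)
  posterior_cortex <- offset_curve(function(t) od2 + flare_post(t), -1)
  ts_canal <- ts[ts <= L - 5]
  canal_anterior <- polycurve(t(vapply(ts_canal, function(t)
    mid(t) + (cd2 + flare_canal(t)) * ant(t), numeric(2))))
  canal_posterior <- polycurve(t(vapply(ts_canal, function(t)
    mid(t) - (cd2 + flare_canal(t)) * ant(t), numeric(2))))

  # anterior condylar (trochlear) front, prepended distally to the cortex
  front_x <- od2 + flare_ant(0)
  dscale <- params$condyle_depth / 25
  condyle_front <- rbind(c(front_x + 5, -12 * dscale),
                         c(front_x + 4, -6 * dscale),
                         c(front_x + 2, -2 * dscale))
  anterior_cortex <- polycurve(rbind(condyle_front, unclass(anterior_shaft)))

  # distal articular / intercondylar groove profile, anterior to posterior
  groove <- polycurve(rbind(
    c(front_x + 6, -3 * dscale),
    c(front_x, -8 * dscale),
    c(12, -11 * dscale),
    c(6, -12 * dscale),
    c(0, -13 * dscale),
    c(-8, -12 * dscale),
    c(-16, -10 * dscale),
    c(-(od2 + flare_post(0)) - 2, -6 * dscale)))

  femur_silhouette(
    anterior_cortex = anterior_cortex,
    posterior_cortex = posterior_cortex,
    canal_anterior_wall = canal_anterior,
    canal_posterior_wall = canal_posterior,
    groove_curve = groove,
    blumensaat_posterior = mid(0) - (od2 + flare_post(0)) * ant(0),
    notch_roof = params$notch_roof_offset,
    provenance = "generated")
}

#' Generate a synthetic lateral lower-leg (tibia) silhouette
#'
#' Two-segment shaft with the bowing hinge 90 mm distal to the tuberosity, a
#' proximal metaphyseal flare up to the plateau, a parallel anterior skin
#' contour offset by `tst`, a fibular shaft axis parallel to the proximal shaft
#' axis (offset posteriorly), and a plateau line tilted posteriorly by
#' `native_tps` relative to the perpendicular of the 7/11 cm cortical-midline
#' reference axis -- the same axis [measure_tps()] uses, so the measurement
#' recovers the parameter by construction.
#'
#' @param params A [tibia_params()] object.
#' @return A [tibia_silhouette()].
#' @export
#' @examples
#' t <- generate_tibia(tibia_params(ptb = 2, native_tps = 8.2))
#' measure_tps(t)
generate_tibia <- function(params = tibia_params()) {
  stopifnot(inherits(params, "tibia_params"))
  L <- params$shaft_length
  od2 <- params$outer_diameter / 2
  bow <- params$ptb / (180 / pi)

  # t = arc distal from the tuberosity level; negative t extends proximally to
  # the plateau. Distal segment tipped anteriorly for positive bowing.
  d1 <- c(0, -1)
  d2 <- c(sin(bow), -cos(bow))
  mid <- function(t) {
    if (t <= HINGE_MM) c(0, -t) else c(0, -HINGE_MM) + (t - HINGE_MM) * d2
  }
  dirat <- function(t) if (t <= HINGE_MM) d1 else d2
  # anterior unit normal: rotate the distally-pointing direction CCW by 90
  ant <- function(t) { d <- dirat(t); c(-d[2], d[1]) }

  prox_ext <- 32                       # plateau sits this far above tuberosity
  flare <- function(t) 13 * pmax(0, -t / prox_ext)

  ts <- c(seq(-prox_ext, 0, by = 4), shaft_breaks(L)[-1])
  ts <- sort(unique(ts))
  side <- function(sgn) {
    polycurve(t(vapply(ts, function(t) mid(t) + sgn * (od2 + flare(t)) * ant(t),
                       numeric(2))))
  }
  anterior_cortex <- side(+1)
  posterior_cortex <- side(-1)

  ts_skin <- ts[ts >= 0]
  skin <- polycurve(t(vapply(ts_skin, function(t)
    mid(t) + (od2 + params$tst) * ant(t), numeric(2))))

  tuberosity <- mid(0) + od2 * ant(0)
  ankle_concavity <- as.numeric(mid(L - 12) + (od2 + flare(L - 12)) * ant(L - 12))

  fibular_axis <- directed_line(
    mid(60) - (od2 + params$fibula_offset) * ant(60), c(0, 1))

  sil <- structure(list(
    anterior_cortex = anterior_cortex,
    posterior_cortex = posterior_cortex,
    skin_anterior = skin,
    tuberosity = tuberosity,
    ankle_concavity = ankle_concavity,
    plateau_line = directed_line(c(0, prox_ext), c(1, 0)),  # provisional
    fibular_axis = fibular_axis,
    provenance = "generated"
  ), class = "tibia_silhouette")

  # tilt the plateau by native_tps posteriorly relative to the perpendicular of
  # the same reference axis the slope measurement uses
  ref <- tibia_reference_line(sil)
  a_perp <- rotate_vec(ref$direction, -90)    # anterior-pointing perpendicular
  plateau_dir <- rotate_vec(a_perp, params$native_tps)
  sil$plateau_line <- directed_line(mid(-30), plateau_dir)
  validate_tibia_silhouette(sil)
  sil
}

#' Cohort parameter distributions
#'
#' Per-parameter means and standard deviations of the validation cohort
#' (normal, truncated at +/-3 SD and at physiologic floors when sampled):
#' distal femur bowing 4.4 +/- 1.7 deg, proximal tibia bowing 2.0 +/- 1.5 deg,
#' native tibial slope 8.2 +/- 4.3 deg, anterior soft tissue 8.8 +/- 3.8 mm,
#' HKA angle 8.9 +/- 3.7 deg, DXA T-score -0.7 +/- 1.1, age 72.4 +/- 6.3 y,
#' BMI 27.4 +/- 3.3 kg/m2; implant mix J2BCS 20 : Physica 26 : U2 34 :
#' Exult 13; 17/93 men.
#'
#' @param ... Named overrides, each a `c(mean, sd)` pair, plus optionally
#'   `implant_mix` (named counts) and `prop_men`.
#' @return An object of class `cohort_distributions`.
#' @export
cohort_distributions <- function(...) {
  d <- list(
    dfb = c(4.4, 1.7), ptb = c(2.0, 1.5), tps = c(8.2, 4.3), tst = c(8.8, 3.8),
    hka = c(8.9, 3.7), dxa = c(-0.7, 1.1), age = c(72.4, 6.3), bmi = c(27.4, 3.3),
    implant_mix = c(J2BCS = 20, Physica = 26, U2 = 34, Exult = 13),
    prop_men = 17 / 93)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(d)) stop("unknown cohort parameter: ", nm)
    d[[nm]] <- over[[nm]]
  }
  for (nm in setdiff(names(d), c("implant_mix", "prop_men")))
    if (d[[nm]][2] <= 0) stop("cohort SDs must be positive")
  structure(d, class = "cohort_distributions")
}

# truncated-normal sampler: +/- 3 SD, optional floor
rtrunc3 <- function(n, m, s, floor = -Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  lo <- max(m - 3 * s, floor)
  hi <- m + 3 * s
  while (length(need)) {
    x <- stats::rnorm(length(need), m, s)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Sample a synthetic cohort's anatomy parameters and covariates
#'
#' Draws per-case bowing, slope, soft tissue, covariates, sex and implant from
#' [cohort_distributions()]. Reproducible given `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param dists A [cohort_distributions()] object.
#' @param seed Optional integer seed.
#' @return A data.frame with one row per case: `case`, `dfb`, `ptb`, `tps`,
#'   `tst`, `hka`, `dxa`, `age`, `bmi`, `sex_men` (0/1), `implant`.
#' @export
sample_cohort <- function(n, dists = cohort_distributions(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- function(nm, floor = -Inf) rtrunc3(n, dists[[nm]][1], dists[[nm]][2], floor)
  mix <- dists$implant_mix
  data.frame(
    case = seq_len(n),
    dfb = g("dfb"), ptb = g("ptb"), tps = g("tps"), tst = g("tst", floor = 1),
    hka = g("hka"), dxa = g("dxa"), age = g("age"), bmi = g("bmi"),
    sex_men = stats::rbinom(n, 1, dists$prop_men),
    implant = sample(names(mix), n, replace = TRUE, prob = mix / sum(mix)),
    stringsAsFactors = FALSE)
}
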