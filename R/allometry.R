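#' Allometric parameter set
#'
#' Bundles the coefficients linking anterior tooth crown height (mm), total
#' body length (cm) and body mass (g) for a sand tiger shark. The simulator
#' evolves mass, while measurements are crown heights, so these transforms
#' close the loop between the two.
#'
#' The default coefficient set is calibrated so that a 295 cm total-length
#' animal carries a 26.11 mm anterior crown (the largest individual in the
#' Delaware Bay tagging data), with a linear tooth-length relation through the
#' origin, and an isometric (cubic) length-mass relation scaled so a female at
#' the 296 cm asymptotic length weighs roughly 160 kg.
#'
#' @param tooth_length_slope Crown height gained per cm of total length
#'   (mm/cm). Must be positive.
#' @param tooth_length_intercept Crown height at zero length (mm). The default
#'   0 keeps the relation proportional.
#' @param mass_coeff Coefficient of the power-law length-mass relation
#'   (g per cm^`mass_exp`). Must be positive.
#' @param mass_exp Exponent of the length-mass power law (3 = isometry).
#' @param length_range Valid total-length range in cm; transforms outside it
#'   raise a domain error.
#' @param species_label Free-text species tag carried through outputs.
#'
#' @return An object of class `allometry_params`.
#' @examples
#' ap <- allometry_params()
#' length_to_tooth(295, ap) # ~26.11 mm
#' @export
allometry_params <- function(tooth_length_slope = 26.11 / 295,
                             tooth_length_intercept = 0,
                             mass_coeff = 6.2e-3,
                             mass_exp = 3,
                             length_range = c(1, 400),
                             species_label = "Carcharias taurus") {
  stopifnot(tooth_length_slope > 0, mass_coeff > 0, mass_exp > 0,
            length(length_range) == 2, length_range[1] > 0,
            length_range[2] > length_range[1])
  if (tooth_length_intercept + tooth_length_slope * length_range[1] <= 0) {
    stop("tooth-length relation must be positive over the valid length range")
  }
  structure(
    list(tooth_length_slope = tooth_length_slope,
         tooth_length_intercept = tooth_length_intercept,
         mass_coeff = mass_coeff,
         mass_exp = mass_exp,
         length_range = length_range,
         species_label = species_label),
    class = "allometry_params"
  )
}

#' @export
print.allometry_params <- function(x, ...) {
  cat("Allometry (", x$species_label, ")\n", sep = "")
  cat(sprintf("  crown height = %.5f mm/cm * L + %.3f mm\n",
              x$tooth_length_slope, x$tooth_length_intercept))
  cat(sprintf("  mass = %.4g g/cm^%g * L^%g, valid L in [%g, %g] cm\n",
              x$mass_coeff, x$mass_exp, x$mass_exp,
              x$length_range[1], x$length_range[2]))
  invisible(x)
}

check_length_domain <- function(total_length, params) {
  if (any(!is.finite(total_length)) || any(total_length <= 0)) {
    stop("total length must be positive and finite")
  }
  if (any(total_length < params$length_range[1]) ||
      any(total_length > params$length_range[2])) {
    stop(sprintf("total length outside valid range [%g, %g] cm",
                 params$length_range[1], params$length_range[2]))
  }
  invisible(TRUE)
}

#' Convert total body length to anterior tooth crown height
#'
#' @param total_length Total length in cm (vectorised).
#' @param params An [allometry_params()] object.
#' @return Crown height in mm.
#' @export
length_to_tooth <- function(total_length, params = allometry_params()) {
  check_length_domain(total_length, params)
  params$tooth_length_intercept + params$tooth_length_slope * total_length
}

#' Convert anterior tooth crown height to total body length
#'
#' Exact inverse of [length_to_tooth()] on the valid length range.
#'
#' @param crown_height Crown height in mm (vectorised).
#' @inheritParams length_to_tooth
#' @return Total length in cm.
#' @export
tooth_to_length <- function(crown_height, params = allometry_params()) {
  if (any(!is.finite(crown_height)) || any(crown_height <= 0)) {
    stop("crown height must be positive and finite")
  }
  len <- (crown_height - params$tooth_length_intercept) / params$tooth_length_slope
  check_length_domain(len, params)
  len
}

#' Convert total body length to body mass
#'
#' Power law `mass = mass_coeff * length^mass_exp`; zero length maps to zero
#' mass.
#'
#' @inheritParams length_to_tooth
#' @return Mass in g.
#' @export
length_to_mass <- function(total_length, params = allometry_params()) {
  if (any(!is.finite(total_length)) || any(total_length < 0)) {
    stop("total length must be non-negative and finite")
  }
  params$mass_coeff * total_length^params$mass_exp
}

#' Convert body mass to total body length
#'
#' @param mass Mass in g (vectorised, non-negative).
#' @inheritParams length_to_tooth
#' @return Total length in cm.
#' @export
mass_to_length <- function(mass, params = allometry_params()) {
  if (any(!is.finite(mass)) || any(mass < 0)) {
    stop("mass must be non-negative and finite")
  }
  (mass / params$mass_coeff)^(1 / params$mass_exp)
}

#' Convert body mass to anterior tooth crown height
#'
#' Composition `length_to_tooth(mass_to_length(mass))`, used to map the
#' simulator's mass bins to crown-height bins.
#'
#' @inheritParams mass_to_length
#' @return Crown height in mm.
#' @export
mass_to_tooth <- function(mass, params = allometry_params()) {
  length_to_tooth(mass_to_length(mass, params), params)
}

#' Convert anterior tooth crown height to body mass
#'
#' @inheritParams tooth_to_length
#' @return Mass in g.
#' @export
tooth_to_mass <- function(crown_height, params = allometry_params()) {
  length_to_mass(tooth_to_length(crown_height, params), params)
}
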