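# Cylindrical pore + access resistance conductance model.
#
# A nanopore of diameter d and length L filled with electrolyte of
# conductivity sigma has resistance
#   R = 4 L / (sigma pi d^2)        (cylindrical channel)
#     + 1 / (sigma d)               (two hemispherical access resistances,
#                                    Hille convergence term, both mouths)
# so the single-channel conductance is
#   G = sigma * [ 4 L / (pi d^2) + 1 / d ]^(-1).
# All quantities are SI (meters, Siemens); user-facing helpers convert
# at the boundary.

#' Electrolyte conductivity of aqueous NaCl
#'
#' Molar-conductivity model with a square-root (Kohlrausch) concentration
#' correction, `Lambda(c) = Lambda0 - K sqrt(c)`, calibrated against
#' standard conductivity tables for NaCl around the working range of
#' planar-bilayer recording buffers (`Lambda0 = 126.45 S cm^2/mol`,
#' `K = 47.31`), plus a linear 2 %/degree temperature scaling about
#' 25 degrees C.  Accuracy is a few percent over 0.05--1 M; the model is
#' exact at 0.5 M / 25 C (4.65 S/m) by calibration.
#'
#' @param c salt concentration, mol/L; must lie in (0, 2].
#' @param temperature_C temperature, degrees Celsius (default 25).
#' @return conductivity in S/m.
#' @examples
#' electrolyte_conductivity(0.5)        # ~4.65 S/m
#' @export
electrolyte_conductivity <- function(c, temperature_C = 25) {
  if (any(c <= 0) || any(c > 2))
    stop("salt concentration must lie in (0, 2] mol/L")
  lambda <- 126.45 - 47.31 * sqrt(c)      # S cm^2 / mol
  kappa25 <- lambda * c / 10              # S/m
  kappa25 * (1 + 0.02 * (temperature_C - 25))
}

#' Parameters of the conductance model
#'
#' @param salt_M NaCl concentration, mol/L (default 0.5, the recording
#'   buffer).
#' @param temperature_C temperature, degrees C (default 25).
#' @param length_m channel length L in meters; the default 3.5 nm is the
#'   hydrophobic span of a DPhPC bilayer plus headgroup region.
#' @param sigma electrolyte conductivity, S/m; computed from
#'   `salt_M`/`temperature_C` via [electrolyte_conductivity()] when NULL.
#' @return a `conductance_params` list with fields `sigma`, `length`,
#'   `salt_M`, `temperature_C`.
#' @export
conductance_params <- function(salt_M = 0.5, temperature_C = 25,
                               length_m = 3.5e-9, sigma = NULL) {
  if (is.null(sigma)) sigma <- electrolyte_conductivity(salt_M, temperature_C)
  if (sigma <= 0) stop("sigma must be positive")
  if (length_m <= 0) stop("channel length must be positive")
  structure(list(sigma = sigma, length = length_m,
                 salt_M = salt_M, temperature_C = temperature_C),
            class = "conductance_params")
}

#' @export
print.conductance_params <- function(x, ...) {
  cat(sprintf("Conductance model: sigma = %.3f S/m (%.2g M NaCl, %.0f C), L = %.2g nm\n",
              x$sigma, x$salt_M, x$temperature_C, x$length * 1e9))
  invisible(x)
}

#' Conductance of a cylindrical pore with access resistance
#'
#' @param d pore diameter in meters (> 0).
#' @param params a [conductance_params()] object.
#' @return conductance in Siemens.
#' @examples
#' p <- conductance_params()
#' conductance_from_diameter(7e-10, p) * 1e12   # ~440 pS at 7 A
#' @export
conductance_from_diameter <- function(d, params = conductance_params()) {
  if (any(d <= 0)) stop("pore diameter must be positive")
  params$sigma / (4 * params$length / (pi * d^2) + 1 / d)
}

#' Pore diameter from single-channel conductance
#'
#' Inverts [conductance_from_diameter()] by bracketed root finding; the
#' model is strictly increasing in d so the positive root is unique.
#'
#' @param G single-channel conductance in Siemens (> 0).
#' @param params a [conductance_params()] object.
#' @return pore diameter in meters.
#' @examples
#' p <- conductance_params()
#' diameter_from_conductance(108e-12, p) * 1e10   # ~3.4 A
#' @export
diameter_from_conductance <- function(G, params = conductance_params()) {
  if (any(G <= 0)) stop("conductance must be positive")
  vapply(G, function(g) {
    f <- function(d) conductance_from_diameter(d, params) - g
    lo <- 1e-13; hi <- 1e-7
    if (f(lo) > 0 || f(hi) < 0)
      stop("no bracketing interval for G = ", g, " S: unphysical parameters")
    stats::uniroot(f, c(lo, hi), tol = 1e-18)$root
  }, numeric(1))
}

#' Predict conductance from a pore profile
#'
#' Converts a profiled channel to a conductance using the constriction
#' (minimum) diameter by default, or the average diameter.
#'
#' @param profile a `pore_profile` (Angstrom scale).
#' @param params a [conductance_params()] object.
#' @param use which summary diameter drives the model.
#' @return list of class `conductance_result` with `G` (Siemens),
#'   `d` (meters) and `model` tag.
#' @export
predict_from_profile <- function(profile, params = conductance_params(),
                                 use = c("min", "average")) {
  use <- match.arg(use)
  s <- summary(profile)
  d_A <- if (use == "min") s$min_diameter else s$average_diameter
  if (d_A <= 0) {
    warning("occluded constriction: predicted conductance is 0")
    return(structure(list(G = 0, d = 0, model = "access-resistance"),
                     class = "conductance_result"))
  }
  d <- d_A * 1e-10
  structure(list(G = conductance_from_diameter(d, params), d = d,
                 model = "access-resistance"),
            class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  cat(sprintf("Predicted conductance %.1f pS (pore diameter %.2f A, %s model)\n",
              x$G * 1e12, x$d * 1e10, x$model))
  invisible(x)
}
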