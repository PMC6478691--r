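#' Fluid and tissue parameters
#'
#' The parameter set of the steady lung microfluidic model, with defaults
#' equal to the literature-derived values used by the study: interstitial
#' fluid viscosity and density, interstitial Darcy permeability and
#' porosity, the external interstitial pressure, and per-vessel-class
#' inlet velocities, outlet pressures and wall hydraulic conductivities.
#'
#' Porosity `phi` does not enter the steady Darcy/Stokes equations; it is
#' carried so that the pore (seepage) velocity `u / phi` can be reported
#' as a diagnostic.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param rho mass density, kg m^-3 (carried; the steady incompressible
#'   model does not use it).
#' @param k interstitial permeability, m^2.
#' @param phi interstitial porosity, dimensionless in (0, 1].
#' @param p_int external interstitial pressure, Pa.
#' @param u_L lymphatic inlet velocity normal to the opening, m s^-1.
#' @param p_L lymphatic outlet pressure, Pa.
#' @param K_L lymphatic wall hydraulic conductivity, m s^-1 Pa^-1.
#' @param u_B blood inlet velocity, m s^-1.
#' @param p_B blood outlet pressure, Pa.
#' @param K_B blood wall hydraulic conductivity, m s^-1 Pa^-1.
#' @return object of class `fluid_parameters`.
#' @export
fluid_parameters <- function(mu = 1.2e-3, rho = 1030, k = 4.4e-18,
                             phi = 0.13, p_int = -1064,
                             u_L = 3e-4, p_L = -1200, K_L = 1.9e-12,
                             u_B = 3e-3, p_B = 2000, K_B = 2.71e-12) {
  p <- structure(list(mu = mu, rho = rho, k = k, phi = phi, p_int = p_int,
                      u_L = u_L, p_L = p_L, K_L = K_L,
                      u_B = u_B, p_B = p_B, K_B = K_B),
                 class = "fluid_parameters")
  if (any(vapply(p[c("mu", "rho", "k", "K_L", "K_B")], function(v)
    !is.finite(v) || v <= 0, logical(1))))
    stop("mu, rho, k, K_L and K_B must be positive")
  if (!is.finite(phi) || phi <= 0 || phi > 1)
    stop("phi must lie in (0, 1]")
  p
}

#' @exportS3Method base::print
print.fluid_parameters <- function(x, ...) {
  cat("fluid_parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-5s %g\n", nm, x[[nm]]))
  invisible(x)
}
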