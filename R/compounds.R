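#' Liquid properties of the aerosolized perfluorocarbon
#'
#' Two perfluorocarbon (PFC) liquids are supported: perfluorodecalin (PFD,
#' density 1.95 g/mL) and FC75 (density 1.78 g/mL).  Densities are the
#' measured values for the compounds as used; surface tension and liquid
#' viscosity are not part of the source measurements and default to
#' externally sourced handbook values for perfluorocarbon liquids at room
#' temperature -- treat them as configurable model inputs, not measured
#' constants.
#'
#' @param name "PFD" or "FC75".
#' @param liquid_density kg/m^3 override (defaults: 1950 PFD, 1780 FC75).
#' @param surface_tension N/m override (defaults: 0.019 PFD, 0.015 FC75;
#'   externally sourced).
#' @param liquid_viscosity Pa s override (defaults: 5.1e-3 PFD, 1.4e-3 FC75;
#'   externally sourced).
#' @return An object of class `compound_properties`.
#' @examples
#' compound_properties("PFD")$liquid_density  # 1950
#' @export
compound_properties <- function(name = c("PFD", "FC75"),
                                liquid_density = NULL,
                                surface_tension = NULL,
                                liquid_viscosity = NULL) {
  name <- match.arg(name)
  defaults <- list(
    PFD  = list(rho = 1950, sigma = 0.019, mu = 5.1e-3),
    FC75 = list(rho = 1780, sigma = 0.015, mu = 1.4e-3)
  )[[name]]
  out <- list(
    name = name,
    liquid_density = if (is.null(liquid_density)) defaults$rho else liquid_density,
    surface_tension = if (is.null(surface_tension)) defaults$sigma else surface_tension,
    liquid_viscosity = if (is.null(liquid_viscosity)) defaults$mu else liquid_viscosity
  )
  if (any(unlist(out[-1]) <= 0)) stop("compound properties must be positive")
  structure(out, class = "compound_properties")
}
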