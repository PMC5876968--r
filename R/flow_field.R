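#' Surrogate carrier-gas jet for the inhalation-catheter aerosol
#'
#' The compressed air leaving the catheter tip forms a small, very fast
#' turbulent round jet.  Rather than solving the compressible RANS equations
#' for that jet, the package uses a classical self-similar round-jet
#' correlation -- a constant-velocity potential core followed by a `1/x`
#' centerline decay with a Gaussian radial profile and linear spreading --
#' calibrated so that the centerline axial velocity at the droplet-injection
#' plane (x = 2 mm by default) equals a measured anchor value: 247 m/s at a
#' driving pressure of 4 bar and 293 m/s at 5 bar.  The droplet phase only
#' needs a plausible calibrated velocity and turbulence field, not the full
#' thermodynamic state, so compressibility is not modelled.
#'
#' Turbulent kinetic energy follows a configurable turbulence-intensity
#' profile, `k = 3/2 (I u)^2`, and the dissipation rate is closed with the
#' duct-flow dissipation length scale `l_eps = 0.07 L` (with `L` the width
#' of the equivalent-area annular air ring) via
#' `epsilon = C_mu^(1/2) k^(3/2) / l_eps`, `C_mu = 0.09`.
#'
#' @param driving_pressure bar, 4 or 5; selects the preset air mass flow and
#'   injector-plane anchor velocity.
#' @param air_mass_flow kg/s through the annular ring.  Defaults to
#'   1.1344e-5 (4 bar) or 1.14766e-5 (5 bar).
#' @param injector_plane_velocity m/s, centerline axial velocity to impose
#'   at `injector_plane_x`.  Defaults to 247 (4 bar) or 293 (5 bar).
#' @param injector_plane_x m, axial position of the droplet injectors
#'   downstream of the catheter tip (default 2e-3).
#' @param annulus_width_L m, width of the annular air ring; only the
#'   dissipation length scale depends on it.  The lumen geometry is not
#'   publicly documented, so this is a free parameter (default 1e-4).
#' @param gas_density kg/m^3 (default air at 20 C, 1.204).
#' @param gas_viscosity Pa s (default 1.81e-5).
#' @param C_mu dimensionless turbulence-model constant (default 0.09).
#' @param turbulence_intensity dimensionless ratio of rms fluctuation to
#'   local mean axial velocity (default 0.1, typical of high-shear jets).
#' @param domain_length m, axial extent of the tracked region: 0.060 for
#'   PFD and 0.052 for FC75 runs (default 0.060).
#' @param potential_core_length m, end of the constant-velocity core
#'   (default 4e-3).
#' @param jet_half_width_0 m, velocity half-width at the tip (default 2e-4).
#' @param spreading_rate dimensionless half-width growth `d r_half / d x`
#'   (default 0.094, the classical round-jet value).
#'
#' @return An object of class `jet_flow_config`.
#' @examples
#' cfg <- jet_flow_config(4)
#' sample_flow(2e-3, 0, cfg)$axial_velocity  # 247 m/s by calibration
#' @export
jet_flow_config <- function(driving_pressure = 4,
                            air_mass_flow = NULL,
                            injector_plane_velocity = NULL,
                            injector_plane_x = 2e-3,
                            annulus_width_L = 1e-4,
                            gas_density = 1.204,
                            gas_viscosity = 1.81e-5,
                            C_mu = 0.09,
                            turbulence_intensity = 0.1,
                            domain_length = 0.060,
                            potential_core_length = 4e-3,
                            jet_half_width_0 = 2e-4,
                            spreading_rate = 0.094) {
  if (!driving_pressure %in% c(4, 5))
    stop("driving_pressure must be 4 or 5 bar")
  presets <- list(`4` = list(mdot = 1.1344e-5, u = 247),
                  `5` = list(mdot = 1.14766e-5, u = 293))
  ps <- presets[[as.character(driving_pressure)]]
  if (is.null(air_mass_flow)) air_mass_flow <- ps$mdot
  if (is.null(injector_plane_velocity)) injector_plane_velocity <- ps$u

  num <- c(air_mass_flow = air_mass_flow,
           injector_plane_velocity = injector_plane_velocity,
           injector_plane_x = injector_plane_x,
           annulus_width_L = annulus_width_L,
           gas_density = gas_density, gas_viscosity = gas_viscosity,
           C_mu = C_mu, turbulence_intensity = turbulence_intensity,
           domain_length = domain_length,
           potential_core_length = potential_core_length,
           jet_half_width_0 = jet_half_width_0,
           spreading_rate = spreading_rate)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all jet_flow_config parameters must be finite and positive")
  if (injector_plane_x > domain_length)
    stop("injector_plane_x must lie inside the domain")

  # core velocity such that the centerline value at the injector plane
  # matches the calibration anchor
  u_core <- if (injector_plane_x <= potential_core_length) {
    injector_plane_velocity
  } else {
    injector_plane_velocity * injector_plane_x / potential_core_length
  }

  structure(list(
    driving_pressure = driving_pressure,
    air_mass_flow = air_mass_flow,
    injector_plane_velocity = injector_plane_velocity,
    injector_plane_x = injector_plane_x,
    annulus_width_L = annulus_width_L,
    gas_density = gas_density,
    gas_viscosity = gas_viscosity,
    C_mu = C_mu,
    turbulence_intensity = turbulence_intensity,
    domain_length = domain_length,
    potential_core_length = potential_core_length,
    jet_half_width_0 = jet_half_width_0,
    spreading_rate = spreading_rate,
    core_velocity = u_core,
    l_eps = dissipation_length_scale(annulus_width_L)
  ), class = "jet_flow_config")
}

#' @export
print.jet_flow_config <- function(x, ...) {
  cat(sprintf("Surrogate round-jet flow field (%d bar)\n", x$driving_pressure))
  cat(sprintf("  centerline anchor : %g m/s at x = %g mm\n",
              x$injector_plane_velocity, 1e3 * x$injector_plane_x))
  cat(sprintf("  potential core    : %g mm (core velocity %g m/s)\n",
              1e3 * x$potential_core_length, x$core_velocity))
  cat(sprintf("  domain length     : %g mm\n", 1e3 * x$domain_length))
  cat(sprintf("  air mass flow     : %g kg/s\n", x$air_mass_flow))
  cat(sprintf("  l_eps = 0.07 L    : %g m\n", x$l_eps))
  invisible(x)
}

#' Dissipation length scale of the annular air ring
#'
#' For fully developed duct flows the characteristic size of the
#' energy-dissipating eddies is 7% of the duct width: `l_eps = 0.07 L`.
#'
#' @param annulus_width_L m, width of the annular ring (> 0).
#' @return Length scale in metres.
#' @examples
#' dissipation_length_scale(1e-3)  # 7e-5
#' @export
dissipation_length_scale <- function(annulus_width_L) {
  if (any(!is.finite(annulus_width_L)) || any(annulus_width_L <= 0))
    stop("annulus_width_L must be positive")
  0.07 * annulus_width_L
}

#' Turbulent dissipation rate from k and a length scale
#'
#' `epsilon = C_mu^(1/2) k^(3/2) / l_eps`, the standard k-epsilon closure
#' used to reconstruct the dissipation rate from the turbulent kinetic
#' energy and the dissipation length scale.
#'
#' @param k m^2/s^2 turbulent kinetic energy (>= 0).
#' @param l_eps m dissipation length scale (> 0).
#' @param C_mu dimensionless model constant (default 0.09).
#' @return Dissipation rate in m^2/s^3.
#' @examples
#' turbulent_dissipation(1, 0.07)  # 0.3 / 0.07 = 4.2857
#' @export
turbulent_dissipation <- function(k, l_eps, C_mu = 0.09) {
  if (any(!is.finite(l_eps)) || any(l_eps <= 0))
    stop("l_eps must be positive")
  if (any(k < 0)) stop("k must be non-negative")
  sqrt(C_mu) * k^1.5 / l_eps
}

# centerline axial velocity of the surrogate jet (vectorized, internal)
jet_centerline <- function(x, config) {
  xc <- config$potential_core_length
  ifelse(x <= xc, config$core_velocity, config$core_velocity * xc / x)
}

#' Sample the surrogate jet flow field
#'
#' Returns the local mean gas state at axial position `x` (measured from the
#' catheter tip) and radius `r`.  The field is exactly axisymmetric by
#' construction.  The axial velocity is the self-similar centerline value
#' times a Gaussian radial profile with half-width
#' `r_half(x) = jet_half_width_0 + spreading_rate * x`; the mean radial
#' velocity is taken as zero.  `k` follows the turbulence-intensity profile
#' and `epsilon` is closed via [turbulent_dissipation()].
#'
#' @param x m axial coordinate(s), `0 <= x <= domain_length`.
#' @param r m radial coordinate(s), `r >= 0`.
#' @param config a [jet_flow_config()] object.
#' @return A data frame with columns `axial_velocity`, `radial_velocity`,
#'   `k`, `epsilon`, `gas_density` (one row per sampled point).
#' @examples
#' cfg <- jet_flow_config(5)
#' sample_flow(2e-3, 0, cfg)$axial_velocity  # 293
#' @export
sample_flow <- function(x, r, config) {
  stopifnot(inherits(config, "jet_flow_config"))
  n <- max(length(x), length(r))
  x <- rep_len(x, n); r <- rep_len(r, n)
  if (any(!is.finite(x)) || any(x < 0) || any(x > config$domain_length))
    stop("axial coordinate outside [0, domain_length]")
  if (any(!is.finite(r)) || any(r < 0))
    stop("radial coordinate must be >= 0")
  st <- flow_state_core(x, r, config)
  data.frame(axial_velocity = st$u, radial_velocity = 0,
             k = st$k, epsilon = st$eps, gas_density = config$gas_density)
}

# fast internal sampler used by the transport loop: no validation,
# returns plain vectors
flow_state_core <- function(x, r, config) {
  uc <- jet_centerline(pmin(pmax(x, 0), config$domain_length), config)
  rh <- config$jet_half_width_0 + config$spreading_rate * x
  u <- uc * exp(-log(2) * (r / rh)^2)
  k <- 1.5 * (config$turbulence_intensity * u)^2
  eps <- sqrt(config$C_mu) * k^1.5 / config$l_eps
  list(u = u, k = k, eps = eps)
}
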