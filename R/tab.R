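#' Constants of the Taylor Analogy Breakup model
#'
#' The TAB model treats a distorting droplet as a forced, damped
#' spring-mass system: aerodynamic pressure forces the distortion, surface
#' tension restores it, and liquid viscosity damps it.  The canonical
#' O'Rourke-Amsden constants are used by default: `C_F = 1/3` (forcing),
#' `C_k = 8` (restoring), `C_d = 5` (damping), `C_b = 0.5` (critical
#' distortion amplitude), and `K_energy = 10/3` (fraction of distortion
#' energy converted to child kinetic energy in the breakup energy balance).
#' Child diameters are drawn from a Rosin-Rammler distribution with spread
#' exponent `child_spread_q` whose Sauter mean follows the energy balance.
#'
#' @param C_b,C_k,C_d,C_F,K_energy TAB oscillator/energy constants.
#' @param child_spread_q Rosin-Rammler spread exponent (default 3.5).
#' @param max_children parcels created per breakup event (default 10).
#' @return An object of class `tab_constants`.
#' @export
tab_constants <- function(C_b = 0.5, C_k = 8, C_d = 5, C_F = 1 / 3,
                          K_energy = 10 / 3, child_spread_q = 3.5,
                          max_children = 10L) {
  out <- list(C_b = C_b, C_k = C_k, C_d = C_d, C_F = C_F,
              K_energy = K_energy, child_spread_q = child_spread_q,
              max_children = as.integer(max_children))
  if (any(unlist(out) <= 0)) stop("all TAB constants must be positive")
  structure(out, class = "tab_constants")
}

#' Weber number of a droplet
#'
#' `We = rho_g u_rel^2 D / sigma`: the ratio of the disrupting aerodynamic
#' stress to the restoring surface-tension stress.  TAB secondary breakup
#' is valid at low Weber numbers (`We < 100`).
#'
#' @param gas_density kg/m^3.
#' @param rel_speed m/s, droplet-gas relative speed.
#' @param diameter m, droplet diameter (> 0).
#' @param surface_tension N/m (> 0).
#' @return Dimensionless Weber number (vectorized).
#' @examples
#' weber_number(1.2, 50, 5e-6, 0.019)  # 0.789
#' @export
weber_number <- function(gas_density, rel_speed, diameter, surface_tension) {
  if (any(surface_tension <= 0)) stop("surface_tension must be > 0")
  if (any(diameter <= 0)) stop("diameter must be > 0")
  gas_density * rel_speed^2 * diameter / surface_tension
}

#' Advance the TAB distortion state of droplets
#'
#' Integrates the forced damped oscillator for the dimensionless distortion
#' `y` over `dt` using the exact analytic solution with coefficients frozen
#' over the step: equilibrium distortion proportional to the Weber number,
#' natural frequency set by surface tension, damping by liquid viscosity.
#' Because the update is analytic it is unconditionally stable, and for an
#' inviscid liquid it conserves the oscillation amplitude exactly.
#' A droplet whose distortion exceeds 1 is flagged for breakup.
#'
#' @param y,ydot current distortion and distortion rate (dimensionless, 1/s).
#' @param diameter m, droplet diameter.
#' @param rel_speed m/s, droplet-gas relative speed.
#' @param gas_density kg/m^3.
#' @param props [compound_properties()].
#' @param consts [tab_constants()].
#' @param dt s (> 0).
#' @return List with updated `y`, `ydot`, and logical `breakup` flags.
#' @export
tab_advance_distortion <- function(y, ydot, diameter, rel_speed, gas_density,
                                   props, consts = tab_constants(), dt) {
  if (dt <= 0) stop("dt must be > 0")
  r <- diameter / 2
  rho_l <- props$liquid_density
  sigma <- props$surface_tension
  mu_l <- props$liquid_viscosity

  omega0_sq <- consts$C_k * sigma / (rho_l * r^3)
  inv_td <- consts$C_d * mu_l / (2 * rho_l * r^2)
  # forcing / omega0^2: equilibrium distortion, We here on droplet radius
  y_eq <- consts$C_F * gas_density * rel_speed^2 * r /
    (consts$C_b * consts$C_k * sigma)

  n <- max(length(y), length(ydot), length(diameter), length(rel_speed))
  y <- rep_len(y, n); ydot <- rep_len(ydot, n)
  omega0_sq <- rep_len(omega0_sq, n); inv_td <- rep_len(inv_td, n)
  y_eq <- rep_len(y_eq, n)
  a0 <- y - y_eq
  y1 <- ydot1 <- numeric(n)
  w2 <- omega0_sq - inv_td^2
  om <- sqrt(abs(w2))

  under <- w2 > 0 & om * dt > 1e-8 * pmax(inv_td * dt, 1)
  over <- w2 < 0 & om * dt > 1e-8 * pmax(inv_td * dt, 1)
  crit <- !under & !over

  if (any(under)) {            # oscillatory: damped cosine/sine
    i <- which(under)
    Ed <- exp(-dt * inv_td[i])
    b0 <- (ydot[i] + a0[i] * inv_td[i]) / om[i]
    cs <- cos(om[i] * dt); sn <- sin(om[i] * dt)
    y1[i] <- y_eq[i] + Ed * (a0[i] * cs + b0 * sn)
    ydot1[i] <- Ed * (-inv_td[i] * (a0[i] * cs + b0 * sn) +
                        om[i] * (b0 * cs - a0[i] * sn))
  }
  if (any(over)) {             # overdamped: two real decaying exponentials
    i <- which(over)
    # s_plus written cancellation-free; both roots are <= 0, so the
    # exponentials cannot overflow however stiff the damping
    s_p <- -omega0_sq[i] / (inv_td[i] + om[i])
    s_m <- -(inv_td[i] + om[i])
    A <- (ydot[i] - s_m * a0[i]) / (s_p - s_m)
    B <- a0[i] - A
    ep <- exp(s_p * dt); em <- exp(s_m * dt)
    y1[i] <- y_eq[i] + A * ep + B * em
    ydot1[i] <- A * s_p * ep + B * s_m * em
  }
  if (any(crit)) {             # critically damped (or negligible stiffness)
    i <- which(crit)
    Ed <- exp(-dt * inv_td[i])
    cc <- ydot[i] + a0[i] * inv_td[i]
    y1[i] <- y_eq[i] + (a0[i] + cc * dt) * Ed
    ydot1[i] <- (cc - inv_td[i] * (a0[i] + cc * dt)) * Ed
  }
  list(y = y1, ydot = ydot1, breakup = y1 > 1)
}

#' Break a parent droplet parcel into Rosin-Rammler children
#'
#' Replaces a parent parcel flagged for breakup with `max_children` child
#' parcels.  The children's Sauter mean diameter follows the TAB breakup
#' energy balance (surface plus distortion energy of the parent equals the
#' surface energy of the children plus kinetic energy fed by the distortion
#' rate); individual child diameters are drawn from a mass-weighted
#' Rosin-Rammler distribution with spread `child_spread_q`, truncated
#' strictly below the parent diameter.  Each child carries an equal share
#' of the parent's liquid mass, so breakup conserves mass to machine
#' precision by construction; the child distortion state is reset to (0,0).
#'
#' @param diameter m, parent droplet diameter.
#' @param mass kg, total liquid mass of the parent parcel.
#' @param ydot 1/s, parent distortion rate at breakup (default 0).
#' @param props [compound_properties()].
#' @param consts [tab_constants()].
#' @return Data frame with one row per child: `diameter` (m), `mass` (kg),
#'   `count` (droplets per child parcel).
#' @export
tab_breakup <- function(diameter, mass, ydot = 0, props,
                        consts = tab_constants()) {
  if (diameter <= 0 || mass <= 0) stop("parent diameter and mass must be > 0")
  r <- diameter / 2
  rho_l <- props$liquid_density
  sigma <- props$surface_tension
  K <- consts$K_energy
  # Sauter mean radius from the TAB energy balance at breakup (y = 1)
  r32 <- r / (1 + 8 * K / 20 +
                rho_l * r^3 * ydot^2 / sigma * (6 * K - 5) / 120)
  smd <- 2 * r32
  q <- consts$child_spread_q
  scale <- smd * gamma(1 - 1 / q)      # Rosin-Rammler scale from the SMD
  n <- consts$max_children
  dmax <- 0.999 * diameter
  Fmax <- 1 - exp(-(dmax / scale)^q)   # exact truncated inverse-CDF sampling
  u <- stats::runif(n) * Fmax
  d <- scale * (-log(1 - u))^(1 / q)
  child_mass <- mass / n
  data.frame(diameter = d, mass = child_mass,
             count = child_mass / (rho_l * pi / 6 * d^3))
}
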