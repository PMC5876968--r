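#' Binned mass-versus-diameter distribution
#'
#' @param bin_edges_um strictly increasing bin edges, micrometres.
#' @param mass per-bin mass (kg or any consistent unit; `length(edges)-1`
#'   values, all >= 0).
#' @return Object of class `size_distribution`.
#' @export
size_distribution <- function(bin_edges_um, mass) {
  if (any(diff(bin_edges_um) <= 0))
    stop("bin edges must be strictly increasing")
  if (length(mass) != length(bin_edges_um) - 1)
    stop("need one mass value per bin")
  if (any(mass < 0)) stop("bin masses must be >= 0")
  structure(list(bin_edges_um = as.numeric(bin_edges_um),
                 mass = as.numeric(mass)),
            class = "size_distribution")
}

#' Coerce to a size distribution
#'
#' @param x a `size_distribution` (returned unchanged), an `aps_sample`
#'   (per-bin mass reconstructed from particle counts and the cube of the
#'   bin geometric midpoint, unit density), or numeric particle diameters
#'   (um) binned with weights `mass`.
#' @param mass optional per-particle masses for numeric input (default:
#'   proportional to diameter cubed).
#' @param bin_edges_um bin edges for numeric input (default: 52 log bins
#'   spanning the data).
#' @return A [size_distribution()].
#' @export
as_size_distribution <- function(x, mass = NULL, bin_edges_um = NULL) {
  if (inherits(x, "size_distribution")) return(x)
  if (inherits(x, "aps_sample")) {
    mid <- sqrt(x$bin_edges_um[-1] * x$bin_edges_um[-length(x$bin_edges_um)])
    return(size_distribution(x$bin_edges_um, x$counts * mid^3))
  }
  if (is.numeric(x)) {
    if (is.null(mass)) mass <- x^3
    if (is.null(bin_edges_um))
      bin_edges_um <- exp(seq(log(min(x)) - 1e-9, log(max(x)) + 1e-9,
                              length.out = 53))
    idx <- findInterval(x, bin_edges_um, rightmost.closed = TRUE,
                        all.inside = TRUE)
    m <- vapply(seq_len(length(bin_edges_um) - 1),
                function(b) sum(mass[idx == b]), numeric(1))
    return(size_distribution(bin_edges_um, m))
  }
  stop("cannot coerce to size_distribution")
}

# weighted quantile of diameter by mass; log-linear interpolation.
# x: diameters (particle input) or size_distribution.
mass_quantile <- function(x, probs, mass = NULL) {
  if (inherits(x, "size_distribution")) {
    tot <- sum(x$mass)
    if (tot <= 0) stop("distribution has zero total mass")
    nz <- which(x$mass > 0)
    if (length(nz) == 1L) {   # mass concentrated in a single bin: point mass
      d0 <- sqrt(x$bin_edges_um[nz] * x$bin_edges_um[nz + 1])
      return(rep(d0, length(probs)))
    }
    cum <- c(0, cumsum(x$mass)) / tot
    le <- log(x$bin_edges_um)
    vapply(probs, function(p) {
      p <- min(max(p, 0), 1)
      i <- findInterval(p, cum, rightmost.closed = TRUE, all.inside = TRUE)
      dc <- cum[i + 1] - cum[i]
      f <- if (dc > 0) (p - cum[i]) / dc else 0.5
      exp(le[i] + f * (le[i + 1] - le[i]))
    }, numeric(1))
  } else {
    d <- as.numeric(x)
    if (is.null(mass)) mass <- d^3
    if (length(d) == 0 || sum(mass) <= 0) stop("zero total mass")
    o <- order(d)
    d <- d[o]; w <- mass[o] / sum(mass)
    if (d[length(d)] - d[1] <= 0) return(rep(d[1], length(probs)))
    cum <- cumsum(w) - w / 2    # mass centred on each particle
    vapply(probs, function(p) {
      p <- min(max(p, 0), 1)
      if (p <= cum[1]) return(d[1])
      if (p >= cum[length(cum)]) return(d[length(d)])
      exp(stats::approx(cum, log(d), xout = p, ties = "ordered")$y)
    }, numeric(1))
  }
}

#' Cumulative mass distribution over droplet size
#'
#' The fraction of total mass carried by droplets below each diameter
#' (`Y_dg`): a non-decreasing curve from 0 to 1.
#'
#' @param x a [size_distribution()] or numeric particle diameters (um).
#' @param mass optional per-particle masses for numeric input.
#' @return Data frame with `diameter_um` and `cum_fraction`.
#' @export
cumulative_mass_distribution <- function(x, mass = NULL) {
  if (inherits(x, "size_distribution")) {
    tot <- sum(x$mass)
    if (tot <= 0) stop("distribution has zero total mass")
    data.frame(diameter_um = x$bin_edges_um,
               cum_fraction = c(0, cumsum(x$mass)) / tot)
  } else {
    d <- as.numeric(x)
    if (is.null(mass)) mass <- d^3
    if (length(d) == 0 || sum(mass) <= 0) stop("zero total mass")
    o <- order(d)
    data.frame(diameter_um = d[o],
               cum_fraction = cumsum(mass[o]) / sum(mass))
  }
}

#' Mass median aerodynamic diameter
#'
#' The diameter below which 50% of the aerosol mass lies, located by
#' log-linear interpolation within the crossing bin (standard
#' cascade-impactor / particle-sizer practice).
#'
#' @inheritParams cumulative_mass_distribution
#' @return MMAD in micrometres.
#' @export
mmad <- function(x, mass = NULL) mass_quantile(x, 0.5, mass)

#' Geometric standard deviation of a size distribution
#'
#' `GSD = sqrt(d_84.1 / d_15.9)` using the mass-weighted quantile
#' diameters at one geometric standard deviation on either side of the
#' median.  For an exactly lognormal distribution this equals
#' `exp(sd(ln d))`; a GSD above 1.25 marks a heterodisperse aerosol.
#'
#' @inheritParams cumulative_mass_distribution
#' @return Dimensionless GSD (>= 1).
#' @export
gsd <- function(x, mass = NULL) {
  q <- mass_quantile(x, stats::pnorm(c(-1, 1)), mass)
  max(1, sqrt(q[2] / q[1]))
}

#' Summarize an aerosol sample
#'
#' @param x an `aps_sample` or [size_distribution()].
#' @param liquid_density g/cm^3 of the droplet liquid, used to convert the
#'   aerodynamic MMAD to a geometric diameter (default 1: no conversion).
#' @return List of class `aerosol_summary`: `Da` (count-mean aerodynamic
#'   diameter, um; `NA` unless counts are available), `MMAD` (um), `GSD`,
#'   `MMGD` (geometric mass median, um), and logical `heterodisperse`
#'   (GSD > 1.25).
#' @export
aerosol_summary <- function(x, liquid_density = 1) {
  da <- NA_real_
  if (inherits(x, "aps_sample")) {
    mid <- sqrt(x$bin_edges_um[-1] * x$bin_edges_um[-length(x$bin_edges_um)])
    if (sum(x$counts) > 0) da <- sum(x$counts * mid) / sum(x$counts)
  }
  dist <- as_size_distribution(x)
  m <- mmad(dist); g <- gsd(dist)
  structure(list(Da = da, MMAD = m, GSD = g,
                 MMGD = aerodynamic_to_geometric(m, liquid_density),
                 heterodisperse = g > 1.25),
            class = "aerosol_summary")
}

#' @export
print.aerosol_summary <- function(x, ...) {
  cat(sprintf("Da = %.3g um, MMAD = %.3g um, GSD = %.3g (%s)\n",
              x$Da, x$MMAD, x$GSD,
              if (x$heterodisperse) "heterodisperse" else "monodisperse-like"))
  invisible(x)
}

#' Convert between aerodynamic and geometric diameter
#'
#' `Dg = Da sqrt(rho0 / rho)`: a droplet of density `rho` settles like a
#' unit-density sphere of its aerodynamic diameter; the physical
#' (geometric) diameter is smaller for the dense perfluorocarbons.
#'
#' @param Da,Dg diameters in micrometres.
#' @param liquid_density g/cm^3 (> 0), e.g. 1.95 for PFD, 1.78 for FC75.
#' @param unit_density g/cm^3 (default 1).
#' @return Converted diameter in micrometres.
#' @examples
#' aerodynamic_to_geometric(4.33, 1.95)  # 3.10 um
#' @export
aerodynamic_to_geometric <- function(Da, liquid_density, unit_density = 1) {
  if (any(liquid_density <= 0) || any(unit_density <= 0))
    stop("densities must be > 0")
  Da * sqrt(unit_density / liquid_density)
}

#' @rdname aerodynamic_to_geometric
#' @export
geometric_to_aerodynamic <- function(Dg, liquid_density, unit_density = 1) {
  if (any(liquid_density <= 0) || any(unit_density <= 0))
    stop("densities must be > 0")
  Dg * sqrt(liquid_density / unit_density)
}

#' Aerosolization rate from a chamber weighing
#'
#' `AR = (m_before - m_after) / (t_pulse * rho)`: the liquid volume
#' aerosolized per unit time, from the mass lost by the liquid chamber over
#' an aerosolization pulse.
#'
#' @param mass_before,mass_after g, chamber mass before/after the pulse.
#' @param pulse_duration min (> 0).
#' @param liquid_density g/mL.
#' @return Rate in mL/min.
#' @examples
#' aerosolization_rate(10.1, 10.0, 1, 1.95)  # 0.0513 mL/min
#' @export
aerosolization_rate <- function(mass_before, mass_after, pulse_duration,
                                liquid_density) {
  if (pulse_duration <= 0) stop("pulse_duration must be > 0")
  if (mass_after > mass_before)
    stop("chamber gained mass during the pulse; check the measurement")
  (mass_before - mass_after) / (pulse_duration * liquid_density)
}

#' Classify particles into the four sizer events
#'
#' The aerodynamic particle sizer classifies every detection into exactly
#' one of four events: (1) diameter below 0.5 um, (2) within the 0.5-20 um
#' measuring range, (3) coincidence -- two particles crossing the beams at
#' once, flagged by the instrument, and (4) above 20 um.
#'
#' @param diameters_um aerodynamic diameters (>= 0).
#' @param coincidence logical flags, recycled (default FALSE).
#' @param range_um measuring range (default `c(0.5, 20)`).
#' @return Named integer vector `event1..event4` summing to
#'   `length(diameters_um)`.
#' @export
classify_aps_events <- function(diameters_um, coincidence = FALSE,
                                range_um = c(0.5, 20)) {
  if (any(diameters_um < 0)) stop("diameters must be >= 0")
  n <- length(diameters_um)
  coincidence <- rep_len(coincidence, n)
  e3 <- coincidence
  e1 <- !e3 & diameters_um < range_um[1]
  e4 <- !e3 & diameters_um > range_um[2]
  e2 <- !e3 & !e1 & !e4
  c(event1 = sum(e1), event2 = sum(e2), event3 = sum(e3), event4 = sum(e4))
}
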