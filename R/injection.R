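#' Build an injection table
#'
#' An injection table describes the ten-point discrete-phase source that
#' stands in for the measured droplet population at the injection plane:
#' one geometric diameter and one liquid mass flow per injector, with the
#' injectors placed 2 mm downstream of the catheter tip and distributed
#' uniformly along a radial injection line.
#'
#' @param compound "PFD" or "FC75".
#' @param pressure bar, 4 or 5.
#' @param Dg_um geometric diameters, micrometres (> 0).
#' @param mass_flow kg/s liquid mass flow per injector (>= 0, same length).
#' @return Object of class `injection_table` with the recomputed
#'   `total_mass_flow`.
#' @export
injection_table <- function(compound, pressure, Dg_um, mass_flow) {
  if (length(Dg_um) != length(mass_flow))
    stop("Dg_um and mass_flow must have equal length")
  if (any(Dg_um <= 0)) stop("geometric diameters must be > 0")
  if (any(mass_flow < 0)) stop("mass flows must be >= 0")
  structure(list(compound = compound, pressure = pressure,
                 Dg_um = as.numeric(Dg_um),
                 mass_flow = as.numeric(mass_flow),
                 total_mass_flow = sum(as.numeric(mass_flow))),
            class = "injection_table")
}

#' @export
print.injection_table <- function(x, ...) {
  cat(sprintf("Injection table: %s at %g bar, %d injectors, total %.3g kg/s\n",
              x$compound, x$pressure, length(x$Dg_um), x$total_mass_flow))
  print(data.frame(injection = seq_along(x$Dg_um), Dg_um = x$Dg_um,
                   mass_flow_kg_s = x$mass_flow), row.names = FALSE)
  invisible(x)
}

#' Load a packaged injection table
#'
#' Returns the measured droplet initial conditions (geometric diameter and
#' liquid mass flow for each of the ten injectors) packaged with this
#' package for the four study scenarios: (PFD, FC75) x (4, 5 bar).  The
#' total mass flow is always recomputed from the per-injector column.
#'
#' @param compound "PFD" or "FC75".
#' @param pressure 4 or 5 (bar).
#' @return An [injection_table()].
#' @examples
#' tb <- load_injection_table("PFD", 4)
#' signif(tb$total_mass_flow, 3)  # 1.28e-06 kg/s
#' @export
load_injection_table <- function(compound, pressure) {
  if (!compound %in% c("PFD", "FC75") || !pressure %in% c(4, 5))
    stop("unknown scenario: valid compounds are PFD, FC75 at 4 or 5 bar")
  f <- system.file("extdata",
                   sprintf("injections_%s_%dbar.csv", tolower(compound), pressure),
                   package = "pfcaerosol", mustWork = TRUE)
  d <- utils::read.csv(f)
  injection_table(compound, pressure, d$Dg_um, d$mass_flow_kg_s)
}

#' All four packaged injection tables
#'
#' @return Named list of [injection_table()] objects
#'   (`PFD_4bar`, `PFD_5bar`, `FC75_4bar`, `FC75_5bar`).
#' @export
packaged_injection_tables <- function() {
  out <- list()
  for (cmp in c("PFD", "FC75")) for (pb in c(4, 5))
    out[[sprintf("%s_%dbar", cmp, pb)]] <- load_injection_table(cmp, pb)
  out
}

#' Rebin a particle-sizer histogram onto injection points
#'
#' Mass-conserving rebinning in log-diameter: the measured (or synthetic)
#' histogram's diameter range is divided into `n_injections` equal
#' logarithmic bins; each source bin's mass is distributed over the target
#' bins in proportion to log-overlap (mass uniform in log-diameter within a
#' source bin), and the representative geometric diameter of each injection
#' is the mass-weighted geometric mean over its overlap segments.
#'
#' @param sample an `aps_sample` (see [generate_aps_sample()]) or a
#'   [size_distribution()].
#' @param n_injections number of injection points (default 10).
#' @param total_mass_flow kg/s to distribute over the injections; defaults
#'   to the sample's total mass interpreted as a flux.
#' @param compound,pressure metadata carried into the result.
#' @return An [injection_table()].
#' @export
rebin_aps_to_injections <- function(sample, n_injections = 10,
                                    total_mass_flow = NULL,
                                    compound = "PFD", pressure = 4) {
  dist <- as_size_distribution(sample)
  edges <- dist$bin_edges_um
  mass <- dist$mass
  if (sum(mass) <= 0) stop("sample has no mass")
  if (is.null(total_mass_flow)) total_mass_flow <- sum(mass)

  le <- log(edges)
  tgt <- seq(le[1], le[length(le)], length.out = n_injections + 1)
  m_t <- numeric(n_injections)
  mlogd_t <- numeric(n_injections)
  for (i in seq_along(mass)) {
    if (mass[i] <= 0) next
    a <- le[i]; b <- le[i + 1]; w <- b - a
    for (j in seq_len(n_injections)) {
      lo <- max(a, tgt[j]); hi <- min(b, tgt[j + 1])
      if (hi <= lo) next
      frac <- if (w > 0) (hi - lo) / w else 1
      m_t[j] <- m_t[j] + mass[i] * frac
      mlogd_t[j] <- mlogd_t[j] + mass[i] * frac * (lo + hi) / 2
    }
  }
  dg <- ifelse(m_t > 0, exp(mlogd_t / pmax(m_t, .Machine$double.xmin)),
               exp((tgt[-length(tgt)] + tgt[-1]) / 2))
  injection_table(compound, pressure, dg,
                  total_mass_flow * m_t / sum(m_t))
}

# deterministic largest-remainder allocation of parcels to injections,
# guaranteeing >= 1 parcel per active injection when enough are available
allocate_parcels <- function(mass_flow, total_n) {
  active <- mass_flow > 0
  n_act <- sum(active)
  if (n_act == 0) return(integer(length(mass_flow)))
  if (total_n < n_act)
    stop("parcels_per_step must be at least the number of active injections")
  alloc <- integer(length(mass_flow))
  quota <- total_n * mass_flow[active] / sum(mass_flow[active])
  base <- floor(quota)
  rem <- total_n - sum(base)
  frac_order <- order(quota - base, decreasing = TRUE)
  if (rem > 0) base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  # enforce the minimum of one parcel per active injection
  while (any(base == 0)) {
    i0 <- which(base == 0)[1]
    imax <- which.max(base)
    base[imax] <- base[imax] - 1L
    base[i0] <- base[i0] + 1L
  }
  alloc[active] <- base
  alloc
}

#' Emit parcels for one time-step
#'
#' Creates the parcels injected during a single time-step.  Parcels are
#' allocated to injections proportionally to mass flow with
#' largest-remainder rounding (every active injection emits at least one
#' parcel when `parcels_per_step` allows), the per-parcel droplet count is
#' chosen so that the emitted liquid mass equals `total_mass_flow * dt`
#' exactly, parcels are placed on the injection plane uniformly along the
#' radial injection line, and their initial velocity is the local mean gas
#' velocity.  Emission is fully deterministic.
#'
#' @param table an [injection_table()].
#' @param parcels_per_step total parcels to emit (>= number of active
#'   injections).
#' @param dt s, time-step (> 0).
#' @param flow a [jet_flow_config()] providing the injection-plane position
#'   and local gas velocity.
#' @param injection_line_length m, radial extent of the injection line.
#' @param liquid_density kg/m^3; defaults to the table's compound density.
#' @return A [parcels()] object.
#' @export
emit_parcels <- function(table, parcels_per_step, dt, flow,
                         injection_line_length = 1e-4,
                         liquid_density = NULL) {
  stopifnot(inherits(table, "injection_table"))
  if (dt <= 0) stop("dt must be > 0")
  if (is.null(liquid_density))
    liquid_density <- compound_properties(table$compound)$liquid_density
  n_inj <- length(table$Dg_um)
  alloc <- allocate_parcels(table$mass_flow, as.integer(parcels_per_step))
  r_pos <- (seq_len(n_inj) - 0.5) / n_inj * injection_line_length

  idx <- rep.int(seq_len(n_inj), alloc)
  d_m <- table$Dg_um[idx] * 1e-6
  parcel_mass <- (table$mass_flow / pmax(alloc, 1L) * dt)[idx]
  cnt <- parcel_mass / (liquid_density * pi / 6 * d_m^3)
  x0 <- rep(flow$injector_plane_x, length(idx))
  y0 <- r_pos[idx]
  u0 <- flow_state_core(x0, y0, flow)$u
  parcels(x = x0, y = y0, z = 0, vx = u0, vy = 0, vz = 0,
          diameter = d_m, count = cnt)
}
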