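#' Specification of a synthetic heterodisperse aerosol
#'
#' The synthetic generator emulates a time-of-flight sizer sample from a
#' lognormal aerosol -- the lognormal's two parameters (mass-median
#' diameter and geometric standard deviation) are exactly the statistics by
#' which these aerosols are summarized.  Diameters are drawn mass-weighted
#' (each draw is an equal share of aerosol mass), classified into the four
#' instrument events, and the in-range draws are binned into 52
#' logarithmic intervals over the measuring range.
#'
#' @param mass_median_um mass-median diameter, um (> 0).
#' @param sigma_g geometric standard deviation (>= 1).
#' @param n_particles number of mass-weighted draws (> 0).
#' @param instrument_range_um measuring range (default `c(0.5, 20)`).
#' @param n_bins number of log intervals (default 52).
#' @param coincidence_fraction fraction of draws flagged as coincidence
#'   events (default 0, must be in `[0, 1)`).
#' @param seed integer RNG seed.
#' @return Object of class `synthetic_aerosol_spec`.
#' @export
synthetic_aerosol_spec <- function(mass_median_um, sigma_g, n_particles,
                                   instrument_range_um = c(0.5, 20),
                                   n_bins = 52, coincidence_fraction = 0,
                                   seed = 1L) {
  if (mass_median_um <= 0) stop("mass_median_um must be > 0")
  if (sigma_g < 1) stop("sigma_g must be >= 1")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (coincidence_fraction < 0 || coincidence_fraction >= 1)
    stop("coincidence_fraction must be in [0, 1)")
  structure(list(mass_median_um = mass_median_um, sigma_g = sigma_g,
                 n_particles = as.integer(n_particles),
                 instrument_range_um = instrument_range_um,
                 n_bins = as.integer(n_bins),
                 coincidence_fraction = coincidence_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_aerosol_spec")
}

#' Generate a synthetic particle-sizer sample
#'
#' Draws `n_particles` mass-weighted diameters from the lognormal law of
#' the spec, classifies each draw into the four instrument events
#' (coincidence draws first, then below-range, in-range, above-range), and
#' bins the in-range draws into the spec's logarithmic intervals.  The
#' per-bin `particle_count` is scaled from the bin mass by the cube of the
#' bin geometric midpoint so that count-weighted and mass-weighted readings
#' of the histogram are mutually consistent; counts are therefore
#' real-valued.  The output is a pure function of the spec (including its
#' seed).
#'
#' @param spec a [synthetic_aerosol_spec()].
#' @return An [aps_sample()].
#' @examples
#' s <- generate_aps_sample(synthetic_aerosol_spec(7.2, 1.9, 1e4, seed = 42))
#' aerosol_summary(s)
#' @export
generate_aps_sample <- function(spec) {
  stopifnot(inherits(spec, "synthetic_aerosol_spec"))
  if (spec$n_particles == 0) stop("n_particles must be > 0")
  set.seed(spec$seed)
  n <- spec$n_particles
  d <- exp(stats::rnorm(n, log(spec$mass_median_um), log(max(spec$sigma_g, 1 + 1e-12))))
  coinc <- stats::runif(n) < spec$coincidence_fraction
  ev <- classify_aps_events(d, coinc, spec$instrument_range_um)
  rng <- spec$instrument_range_um
  in_range <- !coinc & d >= rng[1] & d <= rng[2]
  edges <- exp(seq(log(rng[1]), log(rng[2]), length.out = spec$n_bins + 1))
  idx <- findInterval(d[in_range], edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mass_frac <- tabulate(idx, nbins = spec$n_bins) / max(sum(in_range), 1)
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  counts <- mass_frac / mid^3
  if (sum(counts) > 0) counts <- counts * sum(in_range) / sum(counts)
  aps_sample(edges, counts, events = ev, seed = spec$seed)
}

#' Generate a synthetic mesh-convergence series
#'
#' Constructs mesh-level observables `v_i = v0 + C h_i^p` (optionally with
#' additive Gaussian noise) on a geometric sequence of mesh sizes
#' `h_i = h1 r^(i-1)`, as a test harness for the Richardson / GCI
#' verification arithmetic: with zero noise the procedure must recover
#' `(p, v0)` exactly.
#'
#' @param v0 exact (zero-mesh-size) value.
#' @param C error-term coefficient.
#' @param p convergence order (> 0).
#' @param r refinement ratio (> 1, default 2).
#' @param n_levels number of levels, fine to coarse (default 3).
#' @param h1 finest mesh size (default 1).
#' @param noise_sd additive noise standard deviation (default 0).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return Data frame with `label`, `h`, `cell_count` (a nominal 2-D count
#'   proportional to `h^-2`), and `value`, ordered fine to coarse.
#' @export
generate_mesh_series <- function(v0, C, p, r = 2, n_levels = 3, h1 = 1,
                                 noise_sd = 0, seed = 1L) {
  if (r <= 1) stop("refinement ratio r must be > 1")
  if (n_levels < 3) stop("need at least three levels")
  h <- h1 * r^(seq_len(n_levels) - 1)
  v <- v0 + C * h^p
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    v <- v + stats::rnorm(n_levels, 0, noise_sd)
  }
  data.frame(label = paste0("M", seq_len(n_levels)), h = h,
             cell_count = round(4e5 * (h1 / h)^2), value = v)
}
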