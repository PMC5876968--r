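#' Observed order of accuracy from three mesh levels
#'
#' For solutions `v1` (fine), `v2` (medium), `v3` (coarse) on meshes
#' refined by a constant ratio `r`, the observed order of the
#' discretization scheme is `p = ln((v3 - v2)/(v2 - v1)) / ln(r)`.
#' Requires monotone convergence: the two successive differences must be
#' nonzero and of the same sign.
#'
#' @param v1,v2,v3 monitored observable on the fine, medium and coarse mesh.
#' @param r mesh refinement ratio (> 1, default 2).
#' @return Observed order `p`.
#' @examples
#' observed_order(9.58, 9.41, 8.92)  # 1.527
#' @export
observed_order <- function(v1, v2, v3, r = 2) {
  if (r <= 1) stop("refinement ratio r must be > 1")
  d21 <- v2 - v1; d32 <- v3 - v2
  if (d21 == 0 || d32 == 0)
    stop("converged pair: successive mesh solutions are identical")
  if (sign(d21) != sign(d32))
    stop("oscillatory convergence: successive differences change sign")
  log(d32 / d21) / log(r)
}

#' Richardson extrapolation to zero mesh size
#'
#' `v_h=0 = v1 + (v1 - v2) / (r^p - 1)`.
#'
#' @param v1,v2 fine and medium mesh solutions.
#' @param r refinement ratio (> 1).
#' @param p observed (or assumed) order of accuracy (> 0).
#' @return Extrapolated value.
#' @export
richardson_extrapolate <- function(v1, v2, r = 2, p) {
  if (r <= 1) stop("refinement ratio r must be > 1")
  if (p <= 0) stop("order p must be > 0")
  v1 + (v1 - v2) / (r^p - 1)
}

#' Grid convergence index of a mesh pair
#'
#' `GCI = Fs |v_fine - v_coarse| / |v_ref| / (r^p - 1) * 100` (percent),
#' with safety factor `Fs` (1.25 for a three-mesh study) and the reference
#' `v_ref` taken as the coarser solution of the pair.
#'
#' @param v_fine,v_coarse solutions on the finer / coarser mesh of the pair.
#' @param r refinement ratio (> 1).
#' @param p observed order.
#' @param Fs safety factor (default 1.25).
#' @param normalize `"coarse"` (default) or `"fine"`: which solution of the
#'   pair provides the normalizing magnitude.
#' @return GCI in percent.
#' @export
gci <- function(v_fine, v_coarse, r = 2, p, Fs = 1.25,
                normalize = c("coarse", "fine")) {
  if (r <= 1) stop("refinement ratio r must be > 1")
  if (Fs <= 0) stop("safety factor must be > 0")
  normalize <- match.arg(normalize)
  v_ref <- if (normalize == "coarse") v_coarse else v_fine
  if (v_ref == 0) stop("reference solution is zero; GCI undefined")
  Fs * abs(v_fine - v_coarse) / abs(v_ref) / (r^p - 1) * 100
}

#' Asymptotic-range check of a three-mesh study
#'
#' `ratio = GCI23 / (r^p GCI12)`; values near 1 indicate that the three
#' solutions lie in the asymptotic range of convergence.
#'
#' @param gci23,gci12 grid convergence indices (percent) of the
#'   medium/coarse and fine/medium pairs.
#' @param r refinement ratio.
#' @param p observed order.
#' @return Dimensionless ratio.
#' @export
asymptotic_ratio <- function(gci23, gci12, r = 2, p) {
  if (gci12 == 0) stop("GCI12 is zero; ratio undefined")
  gci23 / (r^p * gci12)
}

#' Per-level discretization errors against the extrapolated value
#'
#' @param values mesh-level solutions.
#' @param extrapolated Richardson-extrapolated value (nonzero).
#' @return Percent errors `100 |v_i - v_ext| / |v_ext|`.
#' @export
per_level_errors <- function(values, extrapolated) {
  if (extrapolated == 0) stop("extrapolated value is zero")
  100 * abs(values - extrapolated) / abs(extrapolated)
}

#' Full solution-verification report for a three-mesh study
#'
#' Runs the complete Richardson / grid-convergence-index procedure on three
#' mesh levels ordered fine-to-coarse: observed order, extrapolated value,
#' per-level errors, GCI of both pairs, and the asymptotic-range ratio.
#'
#' @param values length-3 numeric: fine, medium, coarse solutions (m/s or
#'   any consistent unit).
#' @param cell_counts optional length-3 cell counts for reporting.
#' @param labels mesh labels (default M1, M2, M3).
#' @param r refinement ratio (default 2).
#' @param Fs safety factor (default 1.25).
#' @param normalize GCI normalization convention, see [gci()].
#' @return Object of class `gci_report`.
#' @examples
#' rep <- gci_report(c(9.58, 9.41, 8.92))
#' round(rep$asymptotic_ratio, 2)  # 1.05
#' @export
gci_report <- function(values, cell_counts = NULL,
                       labels = c("M1", "M2", "M3"), r = 2, Fs = 1.25,
                       normalize = c("coarse", "fine")) {
  if (length(values) != 3) stop("need exactly three mesh-level values")
  normalize <- match.arg(normalize)
  v1 <- values[1]; v2 <- values[2]; v3 <- values[3]
  p <- observed_order(v1, v2, v3, r)
  vext <- richardson_extrapolate(v1, v2, r, p)
  g12 <- gci(v1, v2, r, p, Fs, normalize)
  g23 <- gci(v2, v3, r, p, Fs, normalize)
  structure(list(values = values, cell_counts = cell_counts,
                 labels = labels, refinement_ratio_r = r,
                 safety_factor_Fs = Fs, normalize = normalize,
                 observed_order_p = p, extrapolated_value = vext,
                 per_level_error_pct = per_level_errors(values, vext),
                 gci_12 = g12, gci_23 = g23,
                 asymptotic_ratio = asymptotic_ratio(g23, g12, r, p)),
            class = "gci_report")
}

#' @export
print.gci_report <- function(x, ...) {
  cat("Three-mesh solution verification (Richardson / GCI)\n")
  cat(sprintf("  refinement ratio r = %g, Fs = %g, %s-grid normalization\n",
              x$refinement_ratio_r, x$safety_factor_Fs, x$normalize))
  cat(sprintf("  observed order p     : %.4f\n", x$observed_order_p))
  cat(sprintf("  extrapolated value   : %.4f\n", x$extrapolated_value))
  for (i in 1:3)
    cat(sprintf("  %-3s value %.4g  error %.2f%%%s\n", x$labels[i],
                x$values[i], x$per_level_error_pct[i],
                if (!is.null(x$cell_counts))
                  sprintf("  (%s cells)", format(x$cell_counts[i], big.mark = ","))
                else ""))
  cat(sprintf("  GCI12 = %.2f%%, GCI23 = %.2f%%\n", x$gci_12, x$gci_23))
  cat(sprintf("  asymptotic ratio GCI23/(r^p GCI12) = %.3f %s\n",
              x$asymptotic_ratio,
              if (abs(x$asymptotic_ratio - 1) < 0.1)
                "(within asymptotic range)" else ""))
  invisible(x)
}

#' Read mesh levels from a CSV file
#'
#' Expects columns `label`, `cell_count`, `value`, one row per mesh level,
#' ordered fine to coarse.
#'
#' @param path CSV path.
#' @return Data frame of mesh levels suitable for [gci_report()].
#' @export
read_mesh_levels <- function(path) {
  d <- utils::read.csv(path)
  need <- c("label", "cell_count", "value")
  if (!all(need %in% names(d)))
    stop("mesh-level CSV needs columns: ", paste(need, collapse = ", "))
  d
}
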