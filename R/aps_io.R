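#' Aerodynamic particle sizer sample
#'
#' A 52-interval particle-size histogram in the style of a time-of-flight
#' particle sizer: logarithmic bins spanning the 0.5-20 um measuring range,
#' a (possibly real-valued) particle count per bin, and the four-event
#' bookkeeping (below range / in range / coincidence / above range).
#'
#' @param bin_edges_um ascending bin edges (`n_bins + 1` values).
#' @param counts particle count per bin (>= 0; real-valued counts are
#'   allowed, e.g. when derived from equal-mass sampling).
#' @param events named or unnamed length-4 vector of event totals.
#' @param sample_time_s sampling time metadata (default 10).
#' @param seed optional generating seed metadata.
#' @return Object of class `aps_sample`.
#' @export
aps_sample <- function(bin_edges_um, counts,
                       events = c(event1 = 0, event2 = sum(counts),
                                  event3 = 0, event4 = 0),
                       sample_time_s = 10, seed = NA_integer_) {
  if (any(diff(bin_edges_um) <= 0)) stop("bin edges must be strictly increasing")
  if (length(counts) != length(bin_edges_um) - 1)
    stop("need one count per bin")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(events) != 4) stop("events must have length 4")
  events <- stats::setNames(as.numeric(events), paste0("event", 1:4))
  structure(list(bin_edges_um = as.numeric(bin_edges_um),
                 counts = as.numeric(counts), events = events,
                 sample_time_s = sample_time_s, seed = seed),
            class = "aps_sample")
}

#' @export
print.aps_sample <- function(x, ...) {
  cat(sprintf("APS sample: %d bins over %.3g-%.3g um, %g in-range particles\n",
              length(x$counts), min(x$bin_edges_um), max(x$bin_edges_um),
              x$events["event2"]))
  cat("  events:", paste(sprintf("%s=%g", names(x$events), x$events),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write / read an APS sample as CSV
#'
#' Plain-text dialect: comment header lines (`# key=value`) carrying the
#' sample time, event totals and generating seed, followed by a table with
#' columns `bin_lower_um, bin_upper_um, particle_count`.
#'
#' @param sample an [aps_sample()].
#' @param path file path.
#' @return `write_aps_sample` returns `path` invisibly; `read_aps_sample`
#'   returns the reconstructed [aps_sample()].
#' @export
write_aps_sample <- function(sample, path) {
  stopifnot(inherits(sample, "aps_sample"))
  hdr <- c(sprintf("# sample_time_s=%s", format(sample$sample_time_s)),
           sprintf("# events=%s",
                   paste(format(sample$events, trim = TRUE), collapse = ",")),
           sprintf("# seed=%s", format(sample$seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  e <- sample$bin_edges_um
  utils::write.csv(data.frame(bin_lower_um = e[-length(e)],
                              bin_upper_um = e[-1],
                              particle_count = sample$counts),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aps_sample
#' @export
read_aps_sample <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default = NA) {
    m <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (!length(m)) return(default)
    sub(sprintf("^# %s=", key), "", m[1])
  }
  d <- utils::read.csv(text = lines[!grepl("^#", lines)])
  events <- suppressWarnings(as.numeric(strsplit(get("events", "0,0,0,0"), ",")[[1]]))
  aps_sample(c(d$bin_lower_um, d$bin_upper_um[nrow(d)]), d$particle_count,
             events = events,
             sample_time_s = suppressWarnings(as.numeric(get("sample_time_s", 10))),
             seed = suppressWarnings(as.integer(get("seed", NA))))
}
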