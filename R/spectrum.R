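#' Drift velocity from a frame-pair of band locations
#'
#' `v = (x_cm(t1) - x_cm(t0)) / dt` in micrometres per second. With positions
#' measured as distances from the convex electrode edge, repulsion (negative
#' DEP) gives a positive drift velocity.
#'
#' @param loc_t0,loc_t1 `band_location` objects at the start and end of the
#'   negative-DEP window.
#' @param dt_ms Time between the two frames in ms (> 0).
#' @return Drift velocity in um/s.
#' @examples
#' a <- locate_band(intensity_profile(0:4, c(2, 8, 10, 9, 3)))
#' compute_drift(a, a, 40) # identical locations: zero drift
#' @export
compute_drift <- function(loc_t0, loc_t1, dt_ms) {
  stopifnot(dt_ms > 0)
  (loc_t1$x_cm_um - loc_t0$x_cm_um) / (dt_ms * 1e-3)
}

#' Assemble a replicate-averaged DEP spectrum
#'
#' Aggregates per-replicate drift measurements into a spectrum: at each
#' frequency the mean and the sample (n-1 denominator) standard deviation of
#' the replicate velocities, sorted by ascending frequency. At least two
#' replicates per frequency are required (the standard deviation is undefined
#' otherwise).
#'
#' @param measurements Data frame with columns `frequency_hz`, `velocity_um_s`,
#'   `replicate` and optionally `label`.
#' @param label Spectrum label; defaults to the single label present in
#'   `measurements`.
#' @return An object of class `dep_spectrum`: list with `frequencies_hz`,
#'   `mean_velocity_um_s`, `std_velocity_um_s`, `n_replicates`, `label`.
#' @examples
#' m <- data.frame(frequency_hz = rep(5e5, 3), velocity_um_s = c(1, 2, 3),
#'                 replicate = 1:3)
#' assemble_spectrum(m, label = "A")
#' @export
assemble_spectrum <- function(measurements, label = NULL) {
  stopifnot(all(c("frequency_hz", "velocity_um_s") %in% names(measurements)))
  if (is.null(label)) {
    labs <- unique(measurements$label)
    if (length(labs) != 1) {
      stop("measurements carry ", length(labs),
           " labels; pass `label` or subset first", call. = FALSE)
    }
    label <- labs
  }
  freqs <- sort(unique(measurements$frequency_hz))
  n <- vapply(freqs, function(f) {
    sum(measurements$frequency_hz == f)
  }, integer(1))
  if (any(n < 2)) {
    stop("every frequency needs >= 2 replicates (std undefined); offending: ",
         paste(freqs[n < 2], collapse = ", "), call. = FALSE)
  }
  mean_v <- vapply(freqs, function(f) {
    mean(measurements$velocity_um_s[measurements$frequency_hz == f])
  }, numeric(1))
  std_v <- vapply(freqs, function(f) {
    stats::sd(measurements$velocity_um_s[measurements$frequency_hz == f])
  }, numeric(1))
  structure(
    list(frequencies_hz = freqs,
         mean_velocity_um_s = mean_v,
         std_velocity_um_s = std_v,
         n_replicates = n,
         label = as.character(label)),
    class = "dep_spectrum"
  )
}

#' @export
print.dep_spectrum <- function(x, ...) {
  cat("<dep_spectrum>", x$label, "-", length(x$frequencies_hz),
      "frequencies,", paste(range(x$n_replicates), collapse = "-"),
      "replicates\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
as.data.frame.dep_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequencies_hz,
             mean_velocity_um_s = x$mean_velocity_um_s,
             std_velocity_um_s = x$std_velocity_um_s,
             n = x$n_replicates,
             label = x$label)
}

#' Plot a DEP spectrum with +/- 1 sd error bars
#'
#' @param x A `dep_spectrum`.
#' @param add Add to an existing plot.
#' @param col Line/point color.
#' @param xlim,ylim Optional axis limits.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dep_spectrum <- function(x, add = FALSE, col = "black",
                              xlim = NULL, ylim = NULL, ...) {
  f_khz <- x$frequencies_hz / 1e3
  lo <- x$mean_velocity_um_s - x$std_velocity_um_s
  hi <- x$mean_velocity_um_s + x$std_velocity_um_s
  if (!add) {
    graphics::plot(f_khz, x$mean_velocity_um_s, type = "o", pch = 16,
                   col = col,
                   xlim = xlim %||% range(f_khz),
                   ylim = ylim %||% range(c(lo, hi)),
                   xlab = "frequency (kHz)",
                   ylab = "drift velocity (um/s)", ...)
  } else {
    graphics::lines(f_khz, x$mean_velocity_um_s, type = "o", pch = 16,
                    col = col)
  }
  bar <- hi > lo  # zero-spread replicates draw no bar
  if (any(bar)) {
    # bars narrower than device resolution warn as zero-length arrows
    suppressWarnings(
      graphics::arrows(f_khz[bar], lo[bar], f_khz[bar], hi[bar], angle = 90,
                       code = 3, length = 0.03, col = col))
  }
  invisible(x)
}

#' Per-frequency error-bar overlap between two spectra
#'
#' At each shared frequency, tests whether the mean +/- 1 sd intervals of the
#' two spectra intersect. Frequencies where they do not are the "separating"
#' frequencies: a measurement at any one of them suffices to tell the two
#' variants apart. The two spectra must be on identical frequency grids; no
#' interpolation is attempted.
#'
#' @param spec_a,spec_b `dep_spectrum` objects on the same grid.
#' @param k Half-width of the interval in standard deviations (default 1,
#'   matching error bars of +/- one sd of the replicate mean).
#' @return List with `frequencies_hz`, logical `overlap`, and
#'   `separating_frequencies_hz` (frequencies with no overlap).
#' @examples
#' m <- data.frame(frequency_hz = rep(c(5e5, 1e6), each = 2),
#'                 velocity_um_s = c(10, 11, 20, 21), replicate = c(1, 2, 1, 2))
#' s1 <- assemble_spectrum(m, "A")
#' m$velocity_um_s <- m$velocity_um_s + 30
#' s2 <- assemble_spectrum(m, "B")
#' ci_overlap(s1, s2)$separating_frequencies_hz
#' @export
ci_overlap <- function(spec_a, spec_b, k = 1) {
  if (length(spec_a$frequencies_hz) != length(spec_b$frequencies_hz) ||
      any(spec_a$frequencies_hz != spec_b$frequencies_hz)) {
    stop("spectra are on different frequency grids", call. = FALSE)
  }
  lo_a <- spec_a$mean_velocity_um_s - k * spec_a$std_velocity_um_s
  hi_a <- spec_a$mean_velocity_um_s + k * spec_a$std_velocity_um_s
  lo_b <- spec_b$mean_velocity_um_s - k * spec_b$std_velocity_um_s
  hi_b <- spec_b$mean_velocity_um_s + k * spec_b$std_velocity_um_s
  overlap <- pmax(lo_a, lo_b) <= pmin(hi_a, hi_b)
  list(frequencies_hz = spec_a$frequencies_hz,
       overlap = overlap,
       separating_frequencies_hz = spec_a$frequencies_hz[!overlap])
}

#' Write / read a spectrum CSV
#'
#' Canonical on-disk form: columns `frequency_hz`, `mean_velocity_um_s`,
#' `std_velocity_um_s`, `n`, `label`.
#'
#' @param spectrum A `dep_spectrum`.
#' @param path CSV path.
#' @return `write_spectrum_csv`: invisibly, `path`. `read_spectrum_csv`: a
#'   `dep_spectrum`.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("cannot parse spectrum CSV ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  required <- c("frequency_hz", "mean_velocity_um_s", "std_velocity_um_s",
                "n", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("malformed spectrum CSV ", path, " (line 1): missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- lapply(df[required[1:4]], function(col) {
    suppressWarnings(as.numeric(col))
  })
  bad <- which(Reduce(`|`, lapply(num, function(col) !is.finite(col))) |
                 num$frequency_hz <= 0)
  if (length(bad) > 0) {
    stop("malformed spectrum CSV ", path, " (line ", bad[1] + 1,
         "): non-numeric or non-positive frequency/velocity", call. = FALSE)
  }
  df[required[1:4]] <- num
  ord <- order(df$frequency_hz)
  df <- df[ord, ]
  structure(
    list(frequencies_hz = df$frequency_hz,
         mean_velocity_um_s = df$mean_velocity_um_s,
         std_velocity_um_s = df$std_velocity_um_s,
         n_replicates = as.integer(df$n),
         label = as.character(df$label[1])),
    class = "dep_spectrum"
  )
}
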