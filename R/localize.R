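#' Intensity profile along the band-motion axis
#'
#' @param positions_um Strictly increasing positions in micrometres measured
#'   from the convex electrode edge (negative values lie over the electrode).
#' @param intensities Nonnegative intensities, one per position.
#' @return An object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions_um, intensities) {
  stopifnot(length(positions_um) == length(intensities),
            length(positions_um) >= 1)
  if (any(diff(positions_um) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  structure(list(positions_um = positions_um, intensities = intensities),
            class = "intensity_profile")
}

#' Extract the ROI intensity profile from a frame
#'
#' Averages the region of interest across the axis perpendicular to the band
#' motion, producing one intensity per pixel column, with column positions
#' converted to micrometres from the convex electrode edge (using the edge
#' side recorded in the sequence metadata, so profiles read the same way
#' whether the electrode is on the left or the right of the frame).
#'
#' @param frames A `frame_sequence`.
#' @param frame_index Which frame of the sequence to profile.
#' @param roi Region of interest `list(x0, y0, width, height)`; defaults to
#'   the ROI stored in the sequence.
#' @return An `intensity_profile`.
#' @export
extract_profile <- function(frames, frame_index = 1L, roi = NULL) {
  roi <- roi %||% frames$roi
  frame <- frames$frames[[frame_index]]
  if (length(dim(frame)) == 3) frame <- apply(frame, c(1, 2), mean)
  h <- nrow(frame)
  w <- ncol(frame)
  if (is.null(roi) || roi$width < 1 || roi$height < 1) {
    stop("empty ROI", call. = FALSE)
  }
  if (roi$x0 < 1 || roi$y0 < 1 ||
      roi$x0 + roi$width - 1 > w || roi$y0 + roi$height - 1 > h) {
    stop("ROI outside frame bounds", call. = FALSE)
  }
  cols <- seq(roi$x0, roi$x0 + roi$width - 1)
  rows <- seq(roi$y0, roi$y0 + roi$height - 1)
  intensity <- colMeans(frame[rows, cols, drop = FALSE])
  meta <- frames$metadata
  ext <- meta$electrode_extent %||% 0L
  edge_side <- meta$edge_side %||% "left"
  px <- frames$pixel_size_um
  if (edge_side == "left") {
    pos <- (cols - ext - 0.5) * px
  } else {
    pos <- ((meta$frame_width %||% w) - ext + 0.5 - cols) * px
    pos <- rev(pos)
    intensity <- rev(intensity)
  }
  intensity_profile(pos, intensity)
}

#' Localize the bead band by thresholded center of mass
#'
#' The band location is the intensity-weighted center of mass
#' `x_cm = sum(I_i x_i) / sum(I_i)` computed over the pixels whose intensity
#' strictly exceeds two-thirds of the peak intensity of the profile. A pixel
#' at exactly two-thirds of the peak is excluded. If several disconnected
#' runs of pixels exceed the threshold, all of them enter the sum and a
#' warning is issued.
#'
#' @param profile An `intensity_profile` with at least one positive value.
#' @return An object of class `band_location`: list with `x_cm_um`,
#'   `threshold` and `n_included`.
#' @export
locate_band <- function(profile) {
  int <- profile$intensities
  if (max(int) <= 0) {
    stop("no band detected: profile has no positive intensity",
         call. = FALSE)
  }
  threshold <- (2 / 3) * max(int)
  included <- int > threshold
  runs <- rle(included)
  if (sum(runs$values) > 1) {
    warning("band threshold exceeded in ", sum(runs$values),
            " disconnected regions; all are included", call. = FALSE)
  }
  x_cm <- sum(int[included] * profile$positions_um[included]) /
    sum(int[included])
  structure(list(x_cm_um = x_cm,
                 threshold = threshold,
                 n_included = sum(included)),
            class = "band_location")
}

#' @export
print.band_location <- function(x, ...) {
  cat("<band_location> x_cm =", signif(x$x_cm_um, 6), "um  (",
      x$n_included, "pixels above", signif(x$threshold, 4), ")\n")
  invisible(x)
}

#' Subtract a constant background estimate from a profile
#'
#' Estimates the background as the profile minimum (default) or a low
#' percentile, subtracts it, and clips at zero. Because the center of mass is
#' computed over near-peak pixels only, a uniform background shifts it
#' slightly; subtracting the pedestal first makes the location invariant to
#' the background level.
#'
#' @param profile An `intensity_profile`.
#' @param method `"min"` or `"percentile"`.
#' @param prob Percentile used when `method = "percentile"`.
#' @return A background-subtracted `intensity_profile`.
#' @export
background_subtract <- function(profile, method = c("min", "percentile"),
                                prob = 0.05) {
  method <- match.arg(method)
  bg <- switch(method,
    min = min(profile$intensities),
    percentile = as.numeric(stats::quantile(profile$intensities, prob))
  )
  intensity_profile(profile$positions_um,
                    pmax(profile$intensities - bg, 0))
}

#' @export
plot.intensity_profile <- function(x, ...) {
  graphics::plot(x$positions_um, x$intensities, type = "l",
                 xlab = "distance from electrode edge (um)",
                 ylab = "intensity (counts)", ...)
  invisible(x)
}
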