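# Frame sequences on disk: one multi-page grayscale TIFF per sequence plus a
# JSON sidecar carrying timestamps, geometry and ground truth. Intensities
# are stored as 16-bit samples scaled by `intensity_scale` camera counts.

INTENSITY_SCALE <- 255

#' Write a frame sequence as TIFF + JSON sidecar
#'
#' @param frames A `frame_sequence`.
#' @param path Path of the `.tif` file to write; the sidecar is written next
#'   to it with extension `.json`.
#' @return Invisibly, `path`.
#' @export
write_frame_sequence <- function(frames, path) {
  pages <- lapply(frames$frames, function(m) {
    pmin(pmax(m / INTENSITY_SCALE, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- sub("\\.tiff?$", ".json", path)
  meta <- frames$metadata
  jsonlite::write_json(
    list(timestamps_ms = frames$timestamps_ms,
         pixel_size_um = frames$pixel_size_um,
         roi = frames$roi,
         intensity_scale = INTENSITY_SCALE,
         frequency_hz = meta$frequency_hz,
         replicate = meta$replicate,
         label = meta$label,
         ground_truth_x_um = meta$ground_truth_x_um,
         band_offset_um = meta$band_offset_um,
         edge_side = meta$edge_side,
         electrode_extent = meta$electrode_extent,
         frame_width = meta$frame_width,
         seed = meta$seed),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a frame sequence from TIFF + JSON sidecar
#'
#' Color pages are converted to grayscale by channel mean. A missing sidecar
#' is an error naming the frame file.
#'
#' @param path Path of the `.tif` file.
#' @return A `frame_sequence`.
#' @export
read_frame_sequence <- function(path) {
  sidecar <- sub("\\.tiff?$", ".json", path)
  if (!file.exists(path)) {
    stop("frame file not found: ", path, call. = FALSE)
  }
  if (!file.exists(sidecar)) {
    stop("missing JSON sidecar for frame file: ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- meta$intensity_scale %||% INTENSITY_SCALE
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)  # color -> gray
    p * scale
  })
  structure(
    list(frames = frames,
         timestamps_ms = meta$timestamps_ms,
         roi = as.list(meta$roi),
         pixel_size_um = meta$pixel_size_um,
         metadata = list(label = meta$label,
                         frequency_hz = meta$frequency_hz,
                         replicate = meta$replicate,
                         ground_truth_x_um = meta$ground_truth_x_um,
                         band_offset_um = meta$band_offset_um,
                         edge_side = meta$edge_side,
                         electrode_extent = meta$electrode_extent,
                         frame_width = meta$frame_width,
                         seed = meta$seed)),
    class = "frame_sequence"
  )
}
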