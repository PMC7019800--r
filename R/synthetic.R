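#' Electric-field model of the convex electrode edge
#'
#' Single-exponential spatial decay of the field-intensity gradient away from
#' the convex edge of an interdigitated electrode:
#' `grad|E|^2(x) = grad_e2_at_edge * exp(-x / decay_length)`.
#'
#' The default edge value 1e18 V^2/m^3 is the scale implied by a ~10 V
#' peak-to-peak drive across micrometre-scale electrode gaps (E of order
#' 3 MV/m decaying over `decay_length`); it reproduces the micrometre-scale
#' 40 ms band displacements the measurement is built around. `peak_field`
#' (default 1.8e4 V/m) is carried as descriptive metadata only and does not
#' enter any computation.
#'
#' @param grad_e2_at_edge Gradient of the squared field magnitude at the edge,
#'   V^2/m^3 (> 0).
#' @param decay_length Exponential decay length in m (> 0).
#' @param peak_field Maximum field magnitude in V/m, metadata only.
#' @return An object of class `electrode_field_model`.
#' @export
electrode_field_model <- function(grad_e2_at_edge = 1e18,
                                  decay_length = 10e-6,
                                  peak_field = 1.8e4) {
  stopifnot(grad_e2_at_edge > 0, decay_length > 0)
  structure(
    list(grad_e2_at_edge = grad_e2_at_edge,
         decay_length = decay_length,
         peak_field = peak_field),
    class = "electrode_field_model"
  )
}

#' Field-intensity gradient at a distance from the edge
#'
#' @param field_model An [electrode_field_model()].
#' @param x Distance from the edge in m (vectorized).
#' @return `grad|E|^2(x)` in V^2/m^3.
#' @export
grad_e2 <- function(field_model, x) {
  field_model$grad_e2_at_edge * exp(-x / field_model$decay_length)
}

#' Frequency-sweep protocol configuration
#'
#' Timing and sweep parameters of the alternating positive/negative DEP
#' protocol: the band is collected at the convex edge with a 10 kHz field for
#' 1000 ms (positive DEP), then a frequency from the 0.5-2 MHz sweep is
#' applied for 40 ms (negative DEP) while frames are taken at 0 and 40 ms.
#' Six replicates per frequency is the default replication depth.
#'
#' @param positive_freq Collection frequency in Hz.
#' @param positive_duration_ms Collection time in ms.
#' @param negative_duration_ms Repulsion window in ms (frame pair spacing).
#' @param sweep_start,sweep_stop Sweep range in Hz, `sweep_start < sweep_stop`.
#' @param n_steps Number of linear sweep frequencies (>= 2).
#' @param voltage_pp Drive amplitude in V peak-to-peak (metadata).
#' @param n_replicates Replicates per frequency.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(positive_freq = 1e4,
                            positive_duration_ms = 1000,
                            negative_duration_ms = 40,
                            sweep_start = 5e5,
                            sweep_stop = 2e6,
                            n_steps = 16L,
                            voltage_pp = 10,
                            n_replicates = 6L) {
  stopifnot(sweep_start < sweep_stop, n_steps >= 2,
            positive_duration_ms > 0, negative_duration_ms > 0,
            n_replicates >= 1)
  structure(
    list(positive_freq = positive_freq,
         positive_duration_ms = positive_duration_ms,
         negative_duration_ms = negative_duration_ms,
         sweep_start = sweep_start,
         sweep_stop = sweep_stop,
         n_steps = as.integer(n_steps),
         voltage_pp = voltage_pp,
         n_replicates = as.integer(n_replicates)),
    class = "protocol_config"
  )
}

#' Sweep frequencies of a protocol
#' @param protocol A [protocol_config()].
#' @return Vector of `n_steps` linearly spaced frequencies in Hz.
#' @export
sweep_frequencies <- function(protocol) {
  seq(protocol$sweep_start, protocol$sweep_stop,
      length.out = protocol$n_steps)
}

#' Synthetic imaging configuration
#'
#' Optical and camera parameters of the rendered frames. The bead band is a
#' Gaussian intensity ridge parallel to the electrode edge; the electrode
#' itself appears as a darker region on `edge_side` of the frame. The band's
#' resting center sits `band_offset_um` away from the edge (the accumulated
#' bead layer has finite thickness, so its center of mass is offset from the
#' electrode wall by about a band width).
#'
#' @param pixel_size_um Pixel pitch in micrometres per pixel.
#' @param frame_width,frame_height Frame size in pixels.
#' @param band_sigma_um Gaussian half-width of the band in micrometres.
#' @param band_amplitude Band peak intensity above background, camera counts.
#' @param background_level Background intensity, camera counts.
#' @param noise_sigma Additive Gaussian pixel noise sd, camera counts.
#' @param electrode_extent Width of the dark electrode region in pixels.
#' @param band_offset_um Resting band-center standoff from the edge, um.
#' @param edge_side `"left"` or `"right"`: which side of the frame the
#'   electrode (and its convex edge) is on.
#' @param seed Integer seed controlling the pixel noise.
#' @param roi Region of interest `list(x0, y0, width, height)` in 1-based
#'   pixel coordinates, or `NULL` for a default ROI spanning the medium side
#'   of the edge.
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_size_um = 0.5,
                           frame_width = 640L,
                           frame_height = 480L,
                           band_sigma_um = 2,
                           band_amplitude = 180,
                           background_level = 20,
                           noise_sigma = 2,
                           electrode_extent = 40L,
                           band_offset_um = 4,
                           edge_side = c("left", "right"),
                           seed = 1L,
                           roi = NULL) {
  edge_side <- match.arg(edge_side)
  stopifnot(pixel_size_um > 0, band_amplitude >= 0, background_level >= 0,
            noise_sigma >= 0, band_sigma_um > 0,
            electrode_extent >= 0, electrode_extent < frame_width)
  structure(
    list(pixel_size_um = pixel_size_um,
         frame_width = as.integer(frame_width),
         frame_height = as.integer(frame_height),
         band_sigma_um = band_sigma_um,
         band_amplitude = band_amplitude,
         background_level = background_level,
         noise_sigma = noise_sigma,
         electrode_extent = as.integer(electrode_extent),
         band_offset_um = band_offset_um,
         edge_side = edge_side,
         seed = as.integer(seed),
         roi = roi),
    class = "imaging_config"
  )
}

default_roi <- function(imaging) {
  w <- imaging$frame_width
  h <- imaging$frame_height
  ext <- imaging$electrode_extent
  width <- min(400L, w - ext)
  y0 <- max(1L, as.integer(h / 2) - 59L)
  height <- min(120L, h - y0 + 1L)
  x0 <- if (imaging$edge_side == "left") ext + 1L else w - ext - width + 1L
  list(x0 = as.integer(x0), y0 = y0,
       width = as.integer(width), height = height)
}

# Distance (um) of each pixel-column center from the convex electrode edge.
# The edge is the boundary between the electrode region and the medium.
column_positions_um <- function(imaging, cols) {
  ext <- imaging$electrode_extent
  if (imaging$edge_side == "left") {
    (cols - ext - 0.5) * imaging$pixel_size_um
  } else {
    ((imaging$frame_width - ext + 0.5) - cols) * imaging$pixel_size_um
  }
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Integrate a band trajectory under DEP repulsion
#'
#' Integrates `dx/dt = v(x)` with fixed-step fourth-order Runge-Kutta, where
#' `v(x)` is the Stokes drift velocity driven by the DEP force in the
#' exponentially decaying field-gradient, and `x(0) = 0` at the convex
#' electrode edge. Under negative DEP (`Re[K] < 0`) the band moves away from
#' the edge and the positions are nondecreasing; if `Re[K] > 0` at the
#' requested frequency a warning is issued and the trajectory is clipped at
#' `x = 0` (the band stays pressed against the edge).
#'
#' @param bead A [functionalized_bead()].
#' @param medium A [dielectric_medium()].
#' @param field_model An [electrode_field_model()].
#' @param frequency Applied frequency in Hz.
#' @param duration_ms Integration span in ms.
#' @param dt_ms Fixed RK4 step in ms (default 0.1).
#' @return An object of class `band_trajectory`: list with `time_ms`,
#'   `position_um` (distance from the edge), `frequency`, `re_k` and the
#'   repulsion speed `edge_speed_um_s` at `x = 0`.
#' @export
simulate_band_trajectory <- function(bead, medium, field_model, frequency,
                                     duration_ms = 40, dt_ms = 0.1) {
  stopifnot(dt_ms > 0, dt_ms <= duration_ms)
  re_k <- Re(clausius_mossotti(bead, medium, frequency))
  if (re_k > 0) {
    warning("Re[K] > 0 at ", frequency,
            " Hz: positive DEP holds the band at the edge", call. = FALSE)
  }
  # repulsion speed, m/s, positive away from the edge when Re[K] < 0
  v_of_x <- function(x) {
    -drift_velocity_from_force(
      dep_force(bead, medium, field_model, x, frequency), bead, medium)
  }
  n <- floor(duration_ms / dt_ms)
  dt <- dt_ms * 1e-3
  x <- numeric(n + 1)
  xi <- 0
  for (i in seq_len(n)) {
    k1 <- v_of_x(xi)
    k2 <- v_of_x(max(0, xi + dt / 2 * k1))
    k3 <- v_of_x(max(0, xi + dt / 2 * k2))
    k4 <- v_of_x(max(0, xi + dt * k3))
    xi <- max(0, xi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    x[i + 1] <- xi
  }
  structure(
    list(time_ms = seq(0, by = dt_ms, length.out = n + 1),
         position_um = x * 1e6,
         frequency = frequency,
         re_k = re_k,
         edge_speed_um_s = v_of_x(0) * 1e6),
    class = "band_trajectory"
  )
}

#' @export
print.band_trajectory <- function(x, ...) {
  cat("<band_trajectory> f =", x$frequency / 1e3, "kHz  Re[K] =",
      signif(x$re_k, 4), "\n  ", length(x$time_ms), "points over",
      max(x$time_ms), "ms; final x =",
      signif(x$position_um[length(x$position_um)], 4), "um\n")
  invisible(x)
}

trajectory_position_at <- function(trajectory, t_ms) {
  span <- range(trajectory$time_ms)
  if (any(t_ms < span[1] - 1e-9) || any(t_ms > span[2] + 1e-9)) {
    stop("timestamps outside the trajectory span", call. = FALSE)
  }
  stats::approx(trajectory$time_ms, trajectory$position_um, xout = t_ms,
                rule = 2)$y
}

#' Render microscope frames along a band trajectory
#'
#' Draws, for each requested timestamp, a grayscale frame containing a
#' Gaussian-profile bright band centered at the trajectory position
#' (plus the resting standoff `band_offset_um`), a uniform background, a
#' darker electrode region, and seeded additive Gaussian pixel noise. The
#' true band-center positions are stored in the metadata so downstream
#' localization can be validated against ground truth. Rendering is
#' deterministic: the same `imaging$seed` yields bit-identical frames.
#'
#' @param trajectory A [simulate_band_trajectory()] result.
#' @param imaging An [imaging_config()].
#' @param timestamps_ms Times (ms) within the trajectory span to render.
#' @param metadata Optional named list merged into the sequence metadata
#'   (e.g. label, replicate).
#' @return An object of class `frame_sequence`: list with `frames` (list of
#'   height x width intensity matrices), `timestamps_ms`, `roi`,
#'   `pixel_size_um` and `metadata` (including `ground_truth_x_um`).
#' @export
render_frames <- function(trajectory, imaging, timestamps_ms,
                          metadata = list()) {
  roi <- if (is.null(imaging$roi)) default_roi(imaging) else imaging$roi
  gt_x <- imaging$band_offset_um + trajectory_position_at(trajectory,
                                                          timestamps_ms)
  w <- imaging$frame_width
  h <- imaging$frame_height
  xs <- column_positions_um(imaging, seq_len(w))
  span <- range(xs)
  if (any(gt_x < span[1]) || any(gt_x > span[2])) {
    stop("band center falls outside the frame", call. = FALSE)
  }
  electrode_cols <- if (imaging$electrode_extent == 0) integer(0)
    else if (imaging$edge_side == "left") seq_len(imaging$electrode_extent)
    else seq(w - imaging$electrode_extent + 1L, w)
  frames <- with_seed(imaging$seed, lapply(gt_x, function(cx) {
    row_profile <- rep(imaging$background_level, w)
    row_profile[electrode_cols] <- 0.4 * imaging$background_level
    row_profile <- row_profile + imaging$band_amplitude *
      exp(-(xs - cx)^2 / (2 * imaging$band_sigma_um^2))
    frame <- matrix(row_profile, nrow = h, ncol = w, byrow = TRUE)
    if (imaging$noise_sigma > 0) {
      frame <- frame + matrix(stats::rnorm(h * w, sd = imaging$noise_sigma),
                              nrow = h)
    }
    pmax(frame, 0)
  }))
  structure(
    list(frames = frames,
         timestamps_ms = timestamps_ms,
         roi = roi,
         pixel_size_um = imaging$pixel_size_um,
         metadata = c(metadata,
                      list(ground_truth_x_um = gt_x,
                           frequency_hz = trajectory$frequency,
                           re_k = trajectory$re_k,
                           band_offset_um = imaging$band_offset_um,
                           edge_side = imaging$edge_side,
                           electrode_extent = imaging$electrode_extent,
                           frame_width = w,
                           seed = imaging$seed))),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("<frame_sequence>", length(x$frames), "frames", d[1], "x", d[2],
      " t =", paste(x$timestamps_ms, collapse = ", "), "ms\n")
  if (!is.null(x$metadata$label))
    cat("  label:", x$metadata$label,
        " f =", x$metadata$frequency_hz / 1e3, "kHz",
        " replicate:", x$metadata$replicate %||% NA, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one 0/40 ms frame pair
#'
#' Convenience wrapper: integrate the trajectory at one frequency and render
#' the two frames the protocol acquires (at 0 ms and at the end of the
#' negative-DEP window).
#'
#' @inheritParams simulate_band_trajectory
#' @param imaging An [imaging_config()].
#' @param negative_duration_ms Length of the repulsion window in ms.
#' @param metadata Optional metadata list (see [render_frames()]).
#' @return A `frame_sequence` with two frames.
#' @export
simulate_frame_pair <- function(bead, medium, field_model, frequency, imaging,
                                negative_duration_ms = 40, metadata = list()) {
  traj <- simulate_band_trajectory(bead, medium, field_model, frequency,
                                   duration_ms = negative_duration_ms)
  render_frames(traj, imaging, c(0, negative_duration_ms),
                metadata = c(list(label = bead$label), metadata))
}

#' Run the full sweep protocol and write a labeled dataset
#'
#' Simulates every (label, frequency, replicate) combination of the protocol:
#' one trajectory per label and frequency, rendered `n_replicates` times with
#' replicate-specific noise seeds, written as multi-page TIFF frame pairs
#' with JSON sidecars plus a manifest CSV holding the ground truth. Replicate
#' `k` of item `i` uses seed `imaging$seed + 1e5*label_index +
#' 1e3*frequency_index + k`, so the whole dataset is reproducible from the
#' single top-level seed.
#'
#' @param protocol A [protocol_config()].
#' @param beads Named list of [functionalized_bead()] (e.g.
#'   [nucleotide_bead_table()]).
#' @param medium A [dielectric_medium()].
#' @param field_model An [electrode_field_model()].
#' @param imaging An [imaging_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (one row per frame pair) that
#'   was written to `file.path(out_dir, "manifest.csv")`.
#' @export
run_protocol <- function(protocol, beads, medium, field_model, imaging,
                         out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  frames_dir <- file.path(out_dir, "frames")
  if (!dir.exists(frames_dir)) dir.create(frames_dir)
  freqs <- sweep_frequencies(protocol)
  rows <- list()
  for (i_lab in seq_along(beads)) {
    bead <- beads[[i_lab]]
    for (i_f in seq_along(freqs)) {
      traj <- simulate_band_trajectory(bead, medium, field_model, freqs[i_f],
                                       duration_ms =
                                         protocol$negative_duration_ms)
      for (k in seq_len(protocol$n_replicates)) {
        seed_k <- imaging$seed + 100000L * i_lab + 1000L * i_f + k
        img_k <- imaging
        img_k$seed <- seed_k
        fs <- render_frames(traj, img_k,
                            c(0, protocol$negative_duration_ms),
                            metadata = list(label = bead$label,
                                            replicate = k))
        stem <- sprintf("%s_f%08.0f_r%02d", bead$label, freqs[i_f], k)
        tif <- file.path(frames_dir, paste0(stem, ".tif"))
        write_frame_sequence(fs, tif)
        gt <- fs$metadata$ground_truth_x_um
        rows[[length(rows) + 1]] <- data.frame(
          label = bead$label,
          frequency_hz = freqs[i_f],
          replicate = k,
          seed = seed_k,
          file = file.path("frames", paste0(stem, ".tif")),
          sidecar = file.path("frames", paste0(stem, ".json")),
          gt_x0_um = gt[1],
          gt_x1_um = gt[2],
          gt_displacement_um = gt[2] - gt[1],
          gt_velocity_um_s = (gt[2] - gt[1]) /
            (protocol$negative_duration_ms * 1e-3),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  cfg <- list(protocol = unclass(protocol),
              imaging = unclass(imaging),
              medium = unclass(medium),
              field_model = unclass(field_model),
              beads = lapply(beads, unclass))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
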