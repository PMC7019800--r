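# Independent oracles and shared fixtures for the test suite.

EPS0_ORACLE <- 8.8541878128e-12

# Brute-force Clausius-Mossotti evaluation, written independently of the
# package internals (scalar arithmetic, no package calls).
cm_oracle <- function(f, eps_p, sig_p, eps_m, sig_m) {
  w <- 2 * pi * f
  ep <- EPS0_ORACLE * eps_p - 1i * sig_p / w
  em <- EPS0_ORACLE * eps_m - 1i * sig_m / w
  (ep - em) / (ep + 2 * em)
}

# Locate the Re[K] sign change by scanning a frequency grid at `res` Hz
# resolution; returns the midpoint of the bracketing step, or NULL.
crossover_oracle <- function(eps_p, sig_p, eps_m, sig_m,
                             f_lo, f_hi, res = 100) {
  grid <- seq(f_lo, f_hi, by = res)
  re_k <- Re(cm_oracle(grid, eps_p, sig_p, eps_m, sig_m))
  flip <- which(re_k[-1] * re_k[-length(re_k)] < 0)
  if (length(flip) == 0) return(NULL)
  (grid[flip[1]] + grid[flip[1] + 1]) / 2
}

# Independent strict two-thirds-of-peak center of mass (explicit loop).
locate_oracle <- function(positions, intensities) {
  thr <- (2 / 3) * max(intensities)
  num <- 0
  den <- 0
  for (i in seq_along(intensities)) {
    if (intensities[i] > thr) {
      num <- num + intensities[i] * positions[i]
      den <- den + intensities[i]
    }
  }
  num / den
}

# Small-frame imaging configuration for fast pipeline tests.
small_imaging <- function(seed = 1L, noise_sigma = 2, ...) {
  imaging_config(frame_width = 220L, frame_height = 60L,
                 noise_sigma = noise_sigma,
                 roi = list(x0 = 41L, y0 = 6L, width = 170L, height = 50L),
                 seed = seed, ...)
}

default_parts <- function() {
  list(bead = functionalized_bead(),
       medium = dielectric_medium(),
       field = electrode_field_model())
}

# Rebuild a replicate-resolved spectrum from a dataset's manifest and the
# analysis processing log, keeping only the given replicates (used to split
# calibration replicates from held-out ones).
measured_spectrum <- function(out_dir, sp_dir, label, reps, dt_s = 0.04) {
  manifest <- utils::read.csv(file.path(out_dir, "manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(label = "character"))
  log <- utils::read.csv(file.path(sp_dir, "processing_log.csv"),
                         stringsAsFactors = FALSE)
  rows <- manifest[manifest$label == label & manifest$replicate %in% reps, ]
  vel <- vapply(seq_len(nrow(rows)), function(i) {
    xs <- log$x_cm_um[log$file == rows$file[i]]
    (xs[2] - xs[1]) / dt_s
  }, numeric(1))
  assemble_spectrum(data.frame(frequency_hz = rows$frequency_hz,
                               velocity_um_s = vel,
                               replicate = rows$replicate,
                               label = label))
}
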