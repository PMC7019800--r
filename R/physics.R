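# Vacuum permittivity, F/m (2018 CODATA).
EPS0 <- 8.8541878128e-12

#' Suspending medium parameters
#'
#' Electrical and mechanical properties of the aqueous buffer entering the
#' Clausius-Mossotti factor and the Stokes drag. Defaults describe a dilute
#' (0.01x) phosphate-buffered saline: relative permittivity 78, conductivity
#' 0.01 S/m, viscosity 8.9e-4 Pa s.
#'
#' @param rel_permittivity Relative permittivity (dimensionless, >= 1).
#' @param conductivity Electrical conductivity in S/m (>= 0).
#' @param viscosity Dynamic viscosity in Pa s (> 0).
#' @return An object of class `dielectric_medium`.
#' @examples
#' dielectric_medium()
#' @export
dielectric_medium <- function(rel_permittivity = 78,
                              conductivity = 0.01,
                              viscosity = 8.9e-4) {
  stopifnot(rel_permittivity >= 1, conductivity >= 0, viscosity > 0)
  structure(
    list(rel_permittivity = rel_permittivity,
         conductivity = conductivity,
         viscosity = viscosity),
    class = "dielectric_medium"
  )
}

#' Functionalized polystyrene microsphere
#'
#' A dielectric sphere with a conducting surface layer. The surface
#' conductance `K_s` is the handle through which the terminal nucleotides of a
#' tethered ssDNA strand modulate the particle's effective polarizability: the
#' effective conductivity entering the Clausius-Mossotti factor is
#' `sigma_eff = bulk_conductivity + 2 * surface_conductance / radius`
#' (standard thin-surface-layer model).
#'
#' @param radius Particle radius in m. Default 375e-9 (750 nm diameter beads).
#' @param rel_permittivity Relative permittivity of the particle core
#'   (default 2.55, polystyrene).
#' @param bulk_conductivity Core conductivity in S/m (default 0; latex is an
#'   insulator).
#' @param surface_conductance Surface conductance `K_s` in S (>= 0). The
#'   default 1.88e-9 S places the DEP crossover of the default bead/medium
#'   pair near 147 kHz, inside the regime bracketed by the sweep protocol.
#' @param label Free-text label identifying the ssDNA variant carried by the
#'   bead (e.g. the nucleotide at the queried position).
#' @return An object of class `functionalized_bead`.
#' @examples
#' functionalized_bead(label = "A")
#' @export
functionalized_bead <- function(radius = 375e-9,
                                rel_permittivity = 2.55,
                                bulk_conductivity = 0,
                                surface_conductance = 1.88e-9,
                                label = "bead") {
  stopifnot(radius > 0, rel_permittivity >= 1,
            bulk_conductivity >= 0, surface_conductance >= 0)
  structure(
    list(radius = radius,
         rel_permittivity = rel_permittivity,
         bulk_conductivity = bulk_conductivity,
         surface_conductance = surface_conductance,
         label = as.character(label)),
    class = "functionalized_bead"
  )
}

#' @export
print.dielectric_medium <- function(x, ...) {
  cat("<dielectric_medium> eps_r =", x$rel_permittivity,
      " sigma =", x$conductivity, "S/m  eta =", x$viscosity, "Pa s\n")
  invisible(x)
}

#' @export
print.functionalized_bead <- function(x, ...) {
  cat("<functionalized_bead>", x$label,
      " r =", x$radius * 1e9, "nm  eps_r =", x$rel_permittivity,
      " K_s =", x$surface_conductance, "S",
      " sigma_eff =", signif(bead_effective_conductivity(x), 4), "S/m\n")
  invisible(x)
}

#' Effective conductivity of a surface-conducting sphere
#'
#' `sigma_eff = sigma_bulk + 2 K_s / r`.
#'
#' @param bead A [functionalized_bead()].
#' @return Effective conductivity in S/m.
#' @export
bead_effective_conductivity <- function(bead) {
  bead$bulk_conductivity + 2 * bead$surface_conductance / bead$radius
}

#' Complex permittivity of a lossy dielectric
#'
#' `eps* = eps0 * eps_r - i * sigma / (2 pi f)` in F/m.
#'
#' @param rel_permittivity Relative permittivity (dimensionless).
#' @param conductivity Conductivity in S/m.
#' @param frequency Field frequency in Hz (> 0); may be a vector.
#' @return Complex permittivity in F/m (same length as `frequency`).
#' @examples
#' complex_permittivity(78, 0.01, 1e4)
#' @export
complex_permittivity <- function(rel_permittivity, conductivity, frequency) {
  if (any(frequency <= 0)) {
    stop("frequency must be positive", call. = FALSE)
  }
  EPS0 * rel_permittivity - 1i * conductivity / (2 * pi * frequency)
}

#' Clausius-Mossotti factor of a bead in a medium
#'
#' The complex frequency-dependent contrast
#' `K(w) = (eps_p* - eps_m*) / (eps_p* + 2 eps_m*)` between the particle and
#' medium complex permittivities. Its real part sets the sign and magnitude of
#' the time-averaged DEP force: `Re[K] > 0` gives positive DEP (attraction to
#' high field), `Re[K] < 0` negative DEP (repulsion). For physical parameters
#' `Re[K]` is bounded in (-0.5, 1.0). The bead side uses the effective
#' conductivity from [bead_effective_conductivity()].
#'
#' @param bead A [functionalized_bead()].
#' @param medium A [dielectric_medium()].
#' @param frequency Field frequency in Hz (> 0); may be a vector.
#' @return Complex `K` (same length as `frequency`).
#' @examples
#' Re(clausius_mossotti(functionalized_bead(), dielectric_medium(), 1e4))
#' @export
clausius_mossotti <- function(bead, medium, frequency) {
  ep <- complex_permittivity(bead$rel_permittivity,
                             bead_effective_conductivity(bead), frequency)
  em <- complex_permittivity(medium$rel_permittivity,
                             medium$conductivity, frequency)
  den <- ep + 2 * em
  if (any(Mod(den) == 0)) {
    stop("degenerate Clausius-Mossotti denominator", call. = FALSE)
  }
  (ep - em) / den
}

#' DEP crossover frequency
#'
#' Locates the frequency at which `Re[K]` changes sign by bisection to a
#' relative tolerance of 1e-9. A coarse logarithmic scan first brackets the
#' sign change; if the scan finds more than one sign change an error asks for
#' a narrower bracket, and if it finds none the function returns `NULL`.
#'
#' @param bead A [functionalized_bead()].
#' @param medium A [dielectric_medium()].
#' @param f_lo,f_hi Bracket in Hz, `0 < f_lo < f_hi`.
#' @param rel_tol Relative tolerance on the root (default 1e-9).
#' @param n_scan Number of log-spaced points in the bracketing scan.
#' @return The crossover frequency in Hz, or `NULL` when `Re[K]` does not
#'   change sign over the bracket.
#' @examples
#' crossover_frequency(functionalized_bead(), dielectric_medium(), 1e3, 1e7)
#' @export
crossover_frequency <- function(bead, medium, f_lo = 1e3, f_hi = 1e7,
                                rel_tol = 1e-9, n_scan = 400L) {
  stopifnot(f_lo > 0, f_lo < f_hi)
  grid <- exp(seq(log(f_lo), log(f_hi), length.out = n_scan))
  re_k <- Re(clausius_mossotti(bead, medium, grid))
  flips <- which(re_k[-1] * re_k[-n_scan] < 0)
  if (length(flips) == 0) {
    # a grid point landing exactly on zero with no strict sign change around
    # it does not count as a crossing
    return(NULL)
  }
  if (length(flips) > 1) {
    stop("multiple sign changes of Re[K] in [f_lo, f_hi]; ",
         "narrow the bracket", call. = FALSE)
  }
  lo <- grid[flips]
  hi <- grid[flips + 1]
  f_at <- function(f) Re(clausius_mossotti(bead, medium, f))
  s_lo <- sign(f_at(lo))
  while ((hi - lo) / ((hi + lo) / 2) > rel_tol) {
    mid <- (lo + hi) / 2
    v <- f_at(mid)
    if (v == 0) return(mid)
    if (sign(v) == s_lo) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Time-averaged DEP force on a bead
#'
#' `F(x) = 2 pi r^3 eps0 eps_m Re[K] grad|E|^2(x)` with the field-intensity
#' gradient evaluated at distance `x` from the convex electrode edge by the
#' supplied [electrode_field_model()]. The sign of the force equals the sign
#' of `Re[K]`; positive values point toward the edge (up the field gradient).
#'
#' @param bead A [functionalized_bead()].
#' @param medium A [dielectric_medium()].
#' @param field_model An [electrode_field_model()].
#' @param x Distance from the convex electrode edge in m (>= 0); vectorized.
#' @param frequency Field frequency in Hz.
#' @return Force in N (length of `x` or `frequency`, recycled).
#' @export
dep_force <- function(bead, medium, field_model, x, frequency) {
  if (any(x < 0)) stop("x must be >= 0 (distance from electrode edge)",
                       call. = FALSE)
  re_k <- Re(clausius_mossotti(bead, medium, frequency))
  2 * pi * bead$radius^3 * EPS0 * medium$rel_permittivity * re_k *
    grad_e2(field_model, x)
}

#' Stokes drift velocity of a bead under a force
#'
#' `v = F / (6 pi eta r)`: at low Reynolds number the bead drifts at the
#' velocity where viscous drag balances the applied force, so the drift
#' velocity is proportional to (and carries the sign of) the DEP force.
#'
#' @param force Force in N; vectorized.
#' @param bead A [functionalized_bead()].
#' @param medium A [dielectric_medium()].
#' @return Velocity in m/s.
#' @export
drift_velocity_from_force <- function(force, bead, medium) {
  force / (6 * pi * medium$viscosity * bead$radius)
}

#' Frequency response of a bead at a point
#'
#' Convenience table of the DEP response at one position: the complex
#' Clausius-Mossotti factor, the time-averaged force, and the Stokes drift
#' velocity per frequency.
#'
#' @inheritParams dep_force
#' @param frequency Vector of frequencies in Hz.
#' @return A data frame with columns `frequency`, `cm_real`, `cm_imag`,
#'   `force` (N) and `velocity` (m/s).
#' @export
dep_response <- function(bead, medium, field_model, x = 0, frequency) {
  k <- clausius_mossotti(bead, medium, frequency)
  f <- dep_force(bead, medium, field_model, x, frequency)
  data.frame(
    frequency = frequency,
    cm_real = Re(k),
    cm_imag = Im(k),
    force = f,
    velocity = drift_velocity_from_force(f, bead, medium)
  )
}

#' Built-in bead tables for the ssDNA variants
#'
#' Labeled parameter sets emulating the sequence variants assayed by the
#' sweep protocol: four 10-mers differing in the last nucleotide
#' (5'-TGTTGTGCGN-3', N = A/C/G/T) and three differing in the second-to-last
#' nucleotide (5'-TGTTGTGCNC-3', N = A/T/C; the guanine variant is excluded
#' because hairpin-driven bead clustering makes it unmeasurable). Each label
#' maps to a surface conductance chosen so that every variant's crossover
#' frequency lies strictly between 50 and 250 kHz and the negative-DEP
#' magnitudes over 0.5-2 MHz are ordered and non-crossing.
#'
#' @param position `"last"` or `"second_to_last"`: which nucleotide position
#'   the variant set differs in.
#' @return A named list of [functionalized_bead()] objects, one per variant,
#'   in lexicographic label order.
#' @examples
#' names(nucleotide_bead_table("last"))
#' @export
nucleotide_bead_table <- function(position = c("last", "second_to_last")) {
  position <- match.arg(position)
  ks <- switch(position,
    last = c(A = 1.8760e-9, C = 1.8795e-9, G = 1.8830e-9, T = 1.8865e-9),
    second_to_last = c(A = 1.8775e-9, C = 1.8845e-9, T = 1.8810e-9)
  )
  ks <- ks[order(names(ks))]
  seqs <- switch(position,
    last = paste0("TGTTGTGCG", names(ks)),
    second_to_last = paste0("TGTTGTGC", names(ks), "C")
  )
  beads <- mapply(function(k, lab) {
    functionalized_bead(surface_conductance = k, label = lab)
  }, ks, names(ks), SIMPLIFY = FALSE)
  for (i in seq_along(beads)) attr(beads[[i]], "sequence") <- seqs[i]
  beads
}
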