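#' Calibration library of labeled DEP spectra
#'
#' A set of reference spectra, one per nucleotide variant, all on a common
#' frequency grid, used as the calibration curves against which a measured
#' spectrum is matched. Entries are stored in lexicographic label order so
#' downstream tie-breaks are deterministic.
#'
#' @param spectra List of `dep_spectrum` objects (>= 2) with distinct labels
#'   and identical frequency grids.
#' @return An object of class `calibration_library`.
#' @export
calibration_library <- function(spectra) {
  stopifnot(length(spectra) >= 2)
  labels <- vapply(spectra, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate labels in calibration library", call. = FALSE)
  }
  grid <- spectra[[1]]$frequencies_hz
  same <- vapply(spectra, function(s) {
    length(s$frequencies_hz) == length(grid) &&
      all(s$frequencies_hz == grid)
  }, logical(1))
  if (!all(same)) {
    stop("all library entries must share one frequency grid", call. = FALSE)
  }
  names(spectra) <- labels
  structure(list(entries = spectra[order(labels)],
                 frequencies_hz = grid),
            class = "calibration_library")
}

#' @export
print.calibration_library <- function(x, ...) {
  cat("<calibration_library>", length(x$entries), "entries (",
      paste(names(x$entries), collapse = ", "), ") on",
      length(x$frequencies_hz), "frequencies\n")
  invisible(x)
}

#' Call the nucleotide variant of a measured spectrum
#'
#' Nearest-curve classification: the distance from the query to each library
#' entry is the root-mean-square difference of the mean velocities across the
#' common frequency grid, and the call is the entry with the smallest
#' distance (ties broken by lexicographic label order and flagged). The call
#' is flagged `ambiguous` when more than one library entry's mean +/- 1 sd
#' band overlaps the query's band at every frequency - i.e. when no frequency
#' separates the query from at least one non-best entry - or when the minimum
#' distance is tied. `n_separating_frequencies` reports, minimized over the
#' non-best entries, how many frequencies separate the query from that entry:
#' 0 means some alternative variant is never excluded by the error bars.
#'
#' @param query A `dep_spectrum` on the library grid.
#' @param library A [calibration_library()].
#' @return An object of class `nucleotide_call`: list with `best_label`,
#'   `distances` (named, um/s), `ambiguous`, `n_separating_frequencies`.
#' @export
call_nucleotide <- function(query, library) {
  grid <- library$frequencies_hz
  if (length(query$frequencies_hz) != length(grid) ||
      any(query$frequencies_hz != grid)) {
    stop("query frequency grid does not match the calibration library",
         call. = FALSE)
  }
  distances <- vapply(library$entries, function(entry) {
    sqrt(mean((query$mean_velocity_um_s - entry$mean_velocity_um_s)^2))
  }, numeric(1))
  best <- names(distances)[which.min(distances)]  # names sorted at build
  tie <- sum(distances == min(distances)) > 1
  n_sep <- vapply(library$entries, function(entry) {
    length(ci_overlap(query, entry)$separating_frequencies_hz)
  }, integer(1))
  n_sep_others <- n_sep[names(n_sep) != best]
  indistinct <- sum(n_sep == 0)  # entries the error bars never exclude
  structure(
    list(best_label = best,
         distances = distances,
         ambiguous = tie || indistinct > 1,
         n_separating_frequencies = min(n_sep_others)),
    class = "nucleotide_call"
  )
}

#' @export
print.nucleotide_call <- function(x, ...) {
  cat("<nucleotide_call>", x$best_label,
      if (x$ambiguous) "(AMBIGUOUS)" else "", "\n  distances (um/s):",
      paste(names(x$distances), signif(x$distances, 4), sep = "=",
            collapse = "  "),
      "\n  separating frequencies vs nearest alternative:",
      x$n_separating_frequencies, "\n")
  invisible(x)
}

#' Pairwise separability of a calibration library
#'
#' For every pair of library entries, lists the frequencies at which their
#' mean +/- 1 sd error bars do not overlap. The library is `separable` when
#' every pair has at least one such frequency - the condition under which a
#' single-frequency measurement could in principle distinguish any two
#' variants, and the criterion by which non-overlapping calibration curves
#' support variant identification.
#'
#' @param library A [calibration_library()].
#' @return List with `pairs` (data frame: `label_a`, `label_b`,
#'   `n_separating`, and a list-column `separating_frequencies_hz`) and
#'   logical `separable`.
#' @export
library_separability <- function(library) {
  labels <- names(library$entries)
  combos <- utils::combn(labels, 2)
  sep_freqs <- vector("list", ncol(combos))
  n_sep <- integer(ncol(combos))
  for (j in seq_len(ncol(combos))) {
    ov <- ci_overlap(library$entries[[combos[1, j]]],
                     library$entries[[combos[2, j]]])
    sep_freqs[[j]] <- ov$separating_frequencies_hz
    n_sep[j] <- length(ov$separating_frequencies_hz)
  }
  pairs <- data.frame(label_a = combos[1, ], label_b = combos[2, ],
                      n_separating = n_sep, stringsAsFactors = FALSE)
  pairs$separating_frequencies_hz <- sep_freqs
  list(pairs = pairs, separable = all(n_sep >= 1))
}

#' Write / read a calibration library directory
#'
#' On disk a library is a directory of spectrum CSVs plus an `index.json`
#' mapping labels to files.
#'
#' @param library A [calibration_library()].
#' @param dir Directory path.
#' @return `write_calibration_library`: invisibly `dir`;
#'   `read_calibration_library`: a `calibration_library`.
#' @export
write_calibration_library <- function(library, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (label in names(library$entries)) {
    f <- paste0("spectrum_", label, ".csv")
    write_spectrum_csv(library$entries[[label]], file.path(dir, f))
    files[label] <- f
  }
  jsonlite::write_json(as.list(files), file.path(dir, "index.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_calibration_library
#' @export
read_calibration_library <- function(dir) {
  index_path <- file.path(dir, "index.json")
  if (!file.exists(index_path)) {
    stop("no index.json in library directory ", dir, call. = FALSE)
  }
  index <- jsonlite::read_json(index_path, simplifyVector = TRUE)
  spectra <- lapply(file.path(dir, unlist(index)), read_spectrum_csv)
  calibration_library(spectra)
}
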