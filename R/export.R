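## Plain-text exports: optimization traces and scan tables as CSV, run
## records as JSON, trajectories as multi-frame XYZ.

#' Write an optimization trace as CSV
#'
#' Columns: cycle, E (Hartree), E_eff (Hartree), d (Angstrom), grad_max
#' (Hartree/Bohr).
#'
#' @param result An `"ego_result"`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_trace_csv <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' Write an EGO result summary as JSON
#'
#' @param result An `"ego_result"`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_result_json <- function(result, path) {
  jsonlite::write_json(list(
    force_au = result$pull$f,
    anchors = c(result$pull$atom_i, result$pull$atom_j),
    converged = result$converged,
    cycles = result$cycles,
    final_energy = utils::tail(result$trace$E, 1),
    final_energy_effective = utils::tail(result$trace$E_eff, 1),
    final_anchor_distance = utils::tail(result$trace$d, 1),
    rupture_events = result$rupture_events
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the trajectory of an EGO result as multi-frame XYZ
#'
#' @param result An `"ego_result"` with stored frames.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_result_trajectory <- function(result, path) {
  if (is.null(result$frames) || !length(result$frames))
    stop("no frames stored")
  frames <- lapply(result$frames, function(x) {
    m <- result$mol; m$coords <- x; m
  })
  write_trajectory(frames, path,
                   comments = sprintf("cycle %d", seq_along(frames)))
  invisible(path)
}

#' Write a stretch-relax scan summary as CSV
#'
#' @param scan A `"scan_result"`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(scan$summary, path, row.names = FALSE)
  invisible(path)
}

#' Write per-force scan records as JSON
#'
#' One object per ladder force with labels, lengths and energies (the
#' heavyweight ego results are summarized, not serialized).
#'
#' @param scan A `"scan_result"`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_scan_json <- function(scan, path) {
  recs <- lapply(scan$records, function(r) {
    if (!isTRUE(r$ok)) return(list(f = r$f, ok = FALSE, error = r$error))
    list(f = r$f, ok = TRUE, converged = r$converged,
         ruptured = r$ruptured,
         labels_relaxed = r$labels_relaxed,
         length_bins_relaxed = r$length_bins_relaxed,
         unit_lengths_relaxed = r$unit_lengths_relaxed,
         L_stretched = r$L_stretched, L_relaxed = r$L_relaxed,
         E_stretched = r$E_stretched, E_relaxed = r$E_relaxed)
  })
  jsonlite::write_json(list(
    reference_labels = scan$reference_labels,
    rupture_force = scan$rupture_force,
    transition_forces = scan$transition_forces,
    records = recs
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
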