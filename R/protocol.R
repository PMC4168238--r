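## Experiment driver: stretch-relax scans over a force ladder, adaptive
## search for the minimal force causing a permanent conformational
## transition, and per-unit transition labelling.  The protocol mirrors
## simulated AFM pulling: every force starts from the same pre-relaxed
## reference structure (not a quasi-static continuation), the stressed
## structure is then relaxed at zero force, and a transition counts as
## permanent when the relaxed conformer label differs from the start.

#' Define a force ladder
#'
#' @param f_min,f_max Ladder bounds in au (Hartree/Bohr),
#'   `0 <= f_min < f_max`.  Defaults are the standard pulling range for
#'   pyranose rings, 0.02-0.08 au.
#' @param step Ladder increment in au (default 0.005 au).
#' @param refine_resolution Bracket width at which the bisection refinement
#'   of [find_minimal_transition_force()] stops (au); must be in
#'   `(0, step]`.
#' @return List of class `"force_ladder"`.
#' @export
force_ladder <- function(f_min = 0.02, f_max = 0.08, step = 0.005,
                         refine_resolution = step / 4) {
  stopifnot(f_min >= 0, f_min <= f_max, step > 0,
            refine_resolution > 0, refine_resolution <= step)
  structure(list(f_min = f_min, f_max = f_max, step = step,
                 refine_resolution = refine_resolution,
                 forces = seq(f_min, f_max, by = step)),
            class = "force_ladder")
}

scan_labels <- function(mol, topo) {
  vapply(topo$units, function(u) {
    st <- puckering_coordinates(mol, u$ring[c("O5", "C1", "C2", "C3",
                                              "C4", "C5")])
    if (st$planar) "planar" else classify_canonical(st)$name
  }, "")
}

#' Run a stretch-relax scan over a force ladder
#'
#' The molecule is first relaxed at zero force; every ladder force is then
#' applied to the anchor oxygens starting from that same reference,
#' followed by relaxation and per-unit conformer labelling.  Backend
#' failures at single forces are recorded as flagged records and the scan
#' continues.
#'
#' @param mol A [molecule()].
#' @param topo A `saccharide_topology` (supplies the anchor atoms).
#' @param model An `"energy_model"`.
#' @param ladder A [force_ladder()].
#' @param opts An [ego_options()].
#' @return Object of class `"scan_result"`: `records` (list; per force:
#'   `f`, `stretched`/`relaxed` ego results, `labels_*`, `unit_lengths_*`,
#'   `L_*`, `E_*`, `ok`), `summary` (data frame), `reference` (relaxed
#'   start), `reference_labels`, `transition_forces`, `regions` (data
#'   frame partitioning the scanned range below rupture), `rupture_force`
#'   (NA if none).
#' @export
run_stretch_relax_scan <- function(mol, topo, model, ladder = force_ladder(),
                                   opts = ego_options()) {
  validate_topology(mol, topo)
  anchors <- topo$anchors
  pull0 <- pull_spec(anchors[["O4a"]], anchors[["O1a"]], 0)
  ref <- optimize_enforced(mol, model, pull0, opts)
  ref_labels <- scan_labels(ref$mol, topo)

  records <- lapply(ladder$forces, function(f) {
    rec <- list(f = f, ok = FALSE)
    out <- tryCatch({
      s <- optimize_enforced(ref$mol, model,
                             pull_spec(anchors[["O4a"]], anchors[["O1a"]], f),
                             opts)
      r <- optimize_enforced(s$mol, model, pull0, opts)
      lens_s <- measure_unit_lengths(s$mol, topo)
      lens_r <- measure_unit_lengths(r$mol, topo)
      list(f = f, ok = TRUE,
           stretched = s, relaxed = r,
           labels_stretched = scan_labels(s$mol, topo),
           labels_relaxed = scan_labels(r$mol, topo),
           length_bins_relaxed = label_by_length(lens_r$unit_lengths),
           unit_lengths_stretched = lens_s$unit_lengths,
           unit_lengths_relaxed = lens_r$unit_lengths,
           L_stretched = lens_s$L, L_relaxed = lens_r$L,
           E_stretched = utils::tail(s$trace$E, 1),
           E_relaxed = utils::tail(r$trace$E, 1),
           converged = s$converged && r$converged,
           ruptured = nrow(s$rupture_events) > 0)
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
    out
  })
  if (!any(vapply(records, function(r) isTRUE(r$ok), TRUE)))
    stop("every ladder force failed; first error: ",
         records[[1]]$error %||% "unknown")

  ok <- vapply(records, function(r) isTRUE(r$ok), TRUE)
  summary <- do.call(rbind, lapply(records[ok], function(r) {
    data.frame(f = r$f, L_stretched = r$L_stretched,
               L_relaxed = r$L_relaxed, E_stretched = r$E_stretched,
               E_relaxed = r$E_relaxed,
               labels_relaxed = paste(r$labels_relaxed, collapse = "|"),
               converged = r$converged, ruptured = r$ruptured)
  }))

  rupt <- summary$f[summary$ruptured]
  rupture_force <- if (length(rupt)) min(rupt) else NA_real_
  below <- summary[is.na(rupture_force) | summary$f < rupture_force, ,
                   drop = FALSE]
  regions <- NULL
  transition_forces <- numeric(0)
  if (nrow(below)) {
    lab <- below$labels_relaxed
    run_id <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
    regions <- do.call(rbind, lapply(split(seq_along(lab), run_id),
                                     function(ix) {
      data.frame(f_lo = below$f[ix[1]], f_hi = below$f[ix[length(ix)]],
                 labels = lab[ix[1]])
    }))
    rownames(regions) <- NULL
    if (nrow(regions) > 1) transition_forces <- regions$f_lo[-1]
  }
  structure(list(records = records, summary = summary,
                 reference = ref, reference_labels = ref_labels,
                 transition_forces = transition_forces,
                 regions = regions, rupture_force = rupture_force,
                 ladder = ladder, topo = topo),
            class = "scan_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d forces in [%.4f, %.4f] au\n",
              length(x$records), x$ladder$f_min, x$ladder$f_max))
  cat("  start labels:", paste(x$reference_labels, collapse = " "), "\n")
  if (!is.null(x$regions)) {
    for (r in seq_len(nrow(x$regions)))
      cat(sprintf("  region %d: f in [%.4f, %.4f] -> %s\n", r,
                  x$regions$f_lo[r], x$regions$f_hi[r], x$regions$labels[r]))
  }
  if (!is.na(x$rupture_force))
    cat(sprintf("  rupture from f = %.4f au\n", x$rupture_force))
  invisible(x)
}

#' Minimal force causing a permanent conformational transition
#'
#' Walks the ladder upward until the relaxed conformer labels first differ
#' from the reference, then bisects the bracketing interval down to the
#' ladder's `refine_resolution`.  This reproduces adaptive fine-step
#' scanning without a hard-coded fine grid.
#'
#' @inheritParams run_stretch_relax_scan
#' @param transition_test Optional predicate `function(relaxed_mol)`
#'   returning `TRUE` when a permanent transition has occurred; the
#'   default compares per-unit relaxed canonical labels with the
#'   reference.  (A custom predicate also allows non-saccharide systems,
#'   e.g. analytic two-state models, in which case `topo` may be a plain
#'   list with an `anchors` element.)
#' @return List of class `"transition_force"`: `force` (bracket midpoint,
#'   or `NA`), `bracket` (length-2), `status` (`"ok"`, `"absent"` -- no
#'   transition up to `f_max` -- or `"unbracketed"` -- the lowest ladder
#'   force already transitions), `n_evaluations`.
#' @export
find_minimal_transition_force <- function(mol, topo, model,
                                          ladder = force_ladder(),
                                          opts = ego_options(),
                                          transition_test = NULL) {
  if (is.null(transition_test)) validate_topology(mol, topo)
  anchors <- topo$anchors
  pull0 <- pull_spec(anchors[["O4a"]], anchors[["O1a"]], 0)
  ref <- optimize_enforced(mol, model, pull0, opts)
  ref_labels <- if (is.null(transition_test)) scan_labels(ref$mol, topo)
  n_eval <- 0L
  transitions <- function(f) {
    n_eval <<- n_eval + 1L
    s <- optimize_enforced(ref$mol, model,
                           pull_spec(anchors[["O4a"]], anchors[["O1a"]], f),
                           opts)
    r <- optimize_enforced(s$mol, model, pull0, opts)
    if (!is.null(transition_test)) transition_test(r$mol)
    else any(scan_labels(r$mol, topo) != ref_labels)
  }
  lo <- NA_real_; hi <- NA_real_
  for (f in ladder$forces) {
    if (transitions(f)) { hi <- f; break }
    lo <- f
  }
  if (is.na(hi))
    return(structure(list(force = NA_real_, bracket = c(lo, NA_real_),
                          status = "absent", n_evaluations = n_eval),
                     class = "transition_force"))
  if (is.na(lo))
    return(structure(list(force = hi, bracket = c(ladder$f_min, hi),
                          status = "unbracketed", n_evaluations = n_eval),
                     class = "transition_force"))
  while (hi - lo > ladder$refine_resolution) {
    mid <- (lo + hi) / 2
    if (transitions(mid)) hi <- mid else lo <- mid
  }
  structure(list(force = (lo + hi) / 2, bracket = c(lo, hi),
                 status = "ok", n_evaluations = n_eval),
            class = "transition_force")
}

#' @export
print.transition_force <- function(x, ...) {
  cat(sprintf("<transition_force> %s: f* = %s au, bracket [%s, %s]\n",
              x$status, format(x$force, digits = 6),
              format(x$bracket[1], digits = 6),
              format(x$bracket[2], digits = 6)))
  invisible(x)
}

#' Per-unit transition descriptors of a stretch-relax record
#'
#' Compares each unit's relaxed canonical label against the starting
#' labels and attaches the positional class of the unit: the terminal
#' unit carrying the free O4 anchor, the terminal unit carrying the free
#' O1 anchor, or internal.  (A monomer is its own O4-anchor terminal.)
#'
#' @param record One element of `scan_result$records` (must have `ok`).
#' @param topo The `saccharide_topology`.
#' @param reference_labels Character vector of starting labels (one per
#'   unit).
#' @return Data frame: `unit`, `position`
#'   (terminal-O4a/terminal-O1a/internal), `from`, `to`, `transition`
#'   (e.g. `"4C1->1C4"` or `"none"`), `provisional` (TRUE when the
#'   relaxed optimization had not converged).
#' @export
label_transitions <- function(record, topo, reference_labels) {
  if (!isTRUE(record$ok)) stop("record is flagged as failed")
  nu <- length(topo$units)
  stopifnot(length(reference_labels) == nu)
  position <- rep("internal", nu)
  position[1] <- "terminal-O4a"
  position[nu] <- if (nu == 1) "terminal-O4a" else "terminal-O1a"
  to <- record$labels_relaxed
  data.frame(unit = seq_len(nu), position = position,
             from = reference_labels, to = to,
             transition = ifelse(to == reference_labels, "none",
                                 paste0(reference_labels, "->", to)),
             provisional = !isTRUE(record$converged))
}
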