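## Force-extension and optimization-history analysis: building curves
## from scan results, plateau detection (extension jumps at nearly
## constant force, the signature of a conformational transition), energy
## landmarks of an optimization trace, and per-cycle structural series.

#' Build a force-extension curve from a scan
#'
#' Pairs each ladder force with the stretched anchor-to-anchor length L.
#' Records that failed or did not converge are excluded and listed.
#'
#' @param scan A `"scan_result"`.
#' @return Object of class `"force_extension_curve"`: data frame `points`
#'   (`f`, `L`) sorted by strictly increasing force, plus `excluded`
#'   (forces of unusable records).
#' @export
build_force_extension_curve <- function(scan) {
  usable <- vapply(scan$records, function(r)
    isTRUE(r$ok) && isTRUE(r$converged), TRUE)
  excluded <- vapply(scan$records[!usable], function(r) r$f, 0)
  pts <- do.call(rbind, lapply(scan$records[usable], function(r)
    data.frame(f = r$f, L = r$L_stretched)))
  if (is.null(pts) || nrow(pts) < 2)
    stop("fewer than 2 usable records; cannot build a curve")
  pts <- pts[order(pts$f), ]
  rownames(pts) <- NULL
  structure(list(points = pts, excluded = excluded),
            class = "force_extension_curve")
}

#' @export
print.force_extension_curve <- function(x, ...) {
  cat(sprintf("<force_extension_curve> %d points, f in [%.4f, %.4f] au, L in [%.2f, %.2f] A\n",
              nrow(x$points), min(x$points$f), max(x$points$f),
              min(x$points$L), max(x$points$L)))
  if (length(x$excluded))
    cat("  excluded forces:", paste(format(x$excluded), collapse = ", "), "\n")
  invisible(x)
}

#' Detect plateaus of a force-extension curve
#'
#' A plateau is a consecutive span over which the extension jumps by at
#' least `jump_threshold` per ladder step while the force advances by at
#' most `max_steps` ladder steps; its onset force is the force at which
#' the jumped extension is first attained.  Scaling all extensions by a
#' constant scales the reported jumps and leaves onset forces unchanged.
#'
#' @param curve A `"force_extension_curve"` (>= 4 points).
#' @param jump_threshold Minimum extension jump per ladder step counted
#'   as plateau-like (Angstrom, default 0.3).
#' @param max_steps Maximum force advance of one plateau, in ladder steps
#'   (default 2).
#' @return Object of class `"plateau_set"`: data frame with `f_onset`,
#'   `delta_L`, `span_from`, `span_to` (point indices); zero rows when
#'   the curve is featureless.
#' @export
detect_plateaus <- function(curve, jump_threshold = 0.3, max_steps = 2) {
  pts <- curve$points
  if (nrow(pts) < 4) stop("need at least 4 curve points")
  dL <- diff(pts$L)
  df <- diff(pts$f)
  step_est <- stats::median(df)
  big <- dL >= jump_threshold
  out <- list()
  i <- 1
  while (i <= length(big)) {
    if (big[i]) {
      j <- i
      while (j + 1 <= length(big) && big[j + 1] &&
             pts$f[j + 2] - pts$f[i] <= max_steps * step_est + 1e-12)
        j <- j + 1
      out[[length(out) + 1L]] <- data.frame(
        f_onset = pts$f[i + 1], delta_L = sum(dL[i:j]),
        span_from = i, span_to = j + 1)
      i <- j + 1
    } else i <- i + 1
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(f_onset = numeric(0), delta_L = numeric(0),
               span_from = integer(0), span_to = integer(0))
  structure(list(plateaus = tab, jump_threshold = jump_threshold),
            class = "plateau_set")
}

#' @export
print.plateau_set <- function(x, ...) {
  if (!nrow(x$plateaus)) {
    cat("<plateau_set> none detected\n")
  } else {
    cat(sprintf("<plateau_set> %d plateau(s):\n", nrow(x$plateaus)))
    for (k in seq_len(nrow(x$plateaus)))
      cat(sprintf("  onset f = %.4f au, delta L = %.2f A\n",
                  x$plateaus$f_onset[k], x$plateaus$delta_L[k]))
  }
  invisible(x)
}

#' Energy landmarks of an optimization history
#'
#' Local maxima and minima of the backbone energy along the optimization
#' cycles after centred moving-average smoothing; on a forced
#' optimization these landmarks mark the barrier crossings of the
#' enforced reaction path.  Barrier heights are E(max) minus the
#' preceding minimum (or the starting energy).
#'
#' @param trace An `ego_result` trace data frame (columns `cycle`, `E`),
#'   length >= 5.
#' @param smoothing_window Odd window length; 1 = raw extrema.
#' @return Object of class `"history_landmarks"`: `maxima`, `minima`
#'   (cycle numbers, alternating), `barriers` (heights in Hartree, one
#'   per maximum), `first_barrier_highest` (logical, NA if < 2 barriers).
#' @export
find_history_landmarks <- function(trace, smoothing_window = 1) {
  stopifnot(nrow(trace) >= 5, smoothing_window >= 1,
            smoothing_window %% 2 == 1)
  E <- trace$E
  if (smoothing_window > 1) {
    k <- smoothing_window %/% 2
    E <- vapply(seq_along(E), function(i) {
      lo <- max(1, i - k); hi <- min(length(E), i + k)
      mean(trace$E[lo:hi])
    }, 0)
  }
  # collapse exact ties so extrema alternate strictly
  keep <- c(TRUE, diff(E) != 0)
  idx <- which(keep)
  Ek <- E[keep]
  n <- length(Ek)
  kinds <- integer(0); at <- integer(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (Ek[i] > Ek[i - 1] && Ek[i] > Ek[i + 1]) {
        kinds <- c(kinds, 1L); at <- c(at, idx[i])
      } else if (Ek[i] < Ek[i - 1] && Ek[i] < Ek[i + 1]) {
        kinds <- c(kinds, -1L); at <- c(at, idx[i])
      }
    }
  }
  maxima <- trace$cycle[at[kinds == 1L]]
  minima <- trace$cycle[at[kinds == -1L]]
  barriers <- vapply(at[kinds == 1L], function(im) {
    prev_min <- at[kinds == -1L & at < im]
    base <- if (length(prev_min)) E[max(prev_min)] else E[1]
    E[im] - base
  }, 0)
  structure(list(maxima = maxima, minima = minima, barriers = barriers,
                 first_barrier_highest = if (length(barriers) >= 2)
                   barriers[1] > max(barriers[-1]) else NA),
            class = "history_landmarks")
}

#' @export
print.history_landmarks <- function(x, ...) {
  cat(sprintf("<history_landmarks> maxima at cycle(s) %s; minima at %s\n",
              paste(x$maxima, collapse = ", "),
              paste(x$minima, collapse = ", ")))
  if (length(x$barriers))
    cat("  barriers (Ha):", paste(format(x$barriers, digits = 4),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' Per-cycle structural series of an optimization
#'
#' Extracts, for every stored trajectory frame: the anchor-to-anchor
#' length L, the glycosidic dihedrals of a chosen linkage, and one ring
#' dihedral of the O4-terminal unit (O4a-C4-C3-C2), the observables that
#' expose the two-phase course of enforced stretching (chain elongation
#' and unit rotation first, ring flips second).
#'
#' @param result An `"ego_result"` with stored frames.
#' @param topo The `saccharide_topology`.
#' @param linkage Which glycosidic linkage to report (default: the last);
#'   ignored for a monomer.
#' @return Data frame: `cycle`, `L`, `phi`, `psi` (NA for a monomer),
#'   `ring_dihedral`.
#' @export
structural_trace <- function(result, topo, linkage = NULL) {
  if (is.null(result$frames) || !length(result$frames))
    stop("no trajectory frames stored; rerun with store_trajectory = TRUE")
  mol <- result$mol
  anchors <- topo$anchors
  nl <- nrow(topo$linkages)
  if (is.null(linkage)) linkage <- if (nl) nl else 0L
  if (linkage > nl) stop("linkage ", linkage, " does not exist")
  u1 <- topo$units[[1]]
  ring_quad <- c(anchors[["O4a"]], u1$ring[["C4"]], u1$ring[["C3"]],
                 u1$ring[["C2"]])
  if (any(ring_quad > n_atoms(mol)))
    stop("ring dihedral atoms missing from the molecule")
  lk <- if (linkage > 0) topo$linkages[linkage, ] else NULL
  rows <- lapply(seq_along(result$frames), function(k) {
    x <- result$frames[[k]]
    m <- mol; m$coords <- x
    phi <- psi <- NA_real_
    if (!is.null(lk)) {
      gd <- glycosidic_dihedrals(m, topo)
      phi <- gd$phi[linkage]; psi <- gd$psi[linkage]
    }
    data.frame(cycle = k,
               L = vnorm(x[anchors[["O4a"]], ] - x[anchors[["O1a"]], ]),
               phi = phi, psi = psi,
               ring_dihedral = dihedral_points(x[ring_quad[1], ],
                                               x[ring_quad[2], ],
                                               x[ring_quad[3], ],
                                               x[ring_quad[4], ]))
  })
  do.call(rbind, rows)
}
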