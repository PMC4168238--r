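## Ring conformational analysis for six-membered (pyranose) rings:
## endocyclic torsions, Cremer-Pople puckering coordinates (Q, theta, phi),
## nearest-canonical-conformer classification over the 38-form itinerary,
## least-squares decomposition of torsion patterns, and the coarse
## characteristic-length bins used for oligomer unit labelling.

ring_atom_labels <- c("O", "1", "2", "3", "4", "5")

#' Endocyclic torsion angles of a six-membered ring
#'
#' The six ring dihedrals for consecutive atom quadruples around the cycle,
#' starting at the ring oxygen O5 and following the sequence
#' O5-C1-C2-C3-C4-C5 (IUPAC sign convention).  Torsion k is about the bond
#' between ring atoms k+1 and k+2 (cyclically).
#'
#' @param mol A [molecule()].
#' @param ring Integer vector of 6 distinct atom indices in ring order
#'   (O5, C1, C2, C3, C4, C5).
#' @return Numeric vector of 6 torsions in degrees, wrapped to (-180, 180].
#' @export
endocyclic_torsions <- function(mol, ring) {
  ring <- as.integer(ring)
  if (length(ring) != 6 || anyDuplicated(ring))
    stop("ring must be 6 distinct atom indices in cycle order")
  x <- mol$coords
  vapply(0:5, function(k) {
    q <- ring[((k + 0:3) %% 6) + 1]
    dihedral_points(x[q[1], ], x[q[2], ], x[q[3], ], x[q[4], ])
  }, 0)
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Standard puckering analysis of the six ring atoms relative to their
#' mean plane: total amplitude Q, phase angles theta (0..180 deg, chairs at
#' the poles) and phi (0..360 deg), and the component amplitudes q2, q3
#' with `q2^2 + q3^2 = Q^2`.  Atom 1 of the sequence is the ring oxygen.
#'
#' @inheritParams endocyclic_torsions
#' @param planarity_floor Amplitude (Angstrom) below which the ring is
#'   reported planar with undefined phase.
#' @return An object of class `"pucker_state"`: list with `Q`, `theta`,
#'   `phi`, `q2`, `q3`, `z` (out-of-plane displacements) and `planar`.
#' @export
puckering_coordinates <- function(mol, ring, planarity_floor = 1e-4) {
  ring <- as.integer(ring)
  if (length(ring) != 6 || anyDuplicated(ring))
    stop("ring must be 6 distinct atom indices in cycle order")
  r <- mol$coords[ring, , drop = FALSE]
  r <- sweep(r, 2, colMeans(r))
  j <- 0:5
  Rp <- colSums(r * sin(2 * pi * j / 6))
  Rpp <- colSums(r * cos(2 * pi * j / 6))
  nrm <- pracma_cross(Rp, Rpp)
  if (vnorm(nrm) < 1e-12) stop("degenerate ring geometry: no mean plane")
  nrm <- nrm / vnorm(nrm)
  z <- drop(r %*% nrm)
  st <- pucker_from_z(z)
  st$planar <- st$Q < planarity_floor
  st$z <- z
  class(st) <- "pucker_state"
  st
}

# (Q, theta, phi) from the six out-of-plane displacements.
pucker_from_z <- function(z) {
  j <- 0:5
  q2c <- sqrt(1 / 3) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(1 / 3) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  phi <- rad2deg(atan2(q2s, q2c)) %% 360
  theta <- rad2deg(atan2(q2, q3))          # in [0, 180] since q2 >= 0
  list(Q = Q, theta = theta, phi = phi, q2 = q2, q3 = q3)
}

# Inverse: displacement pattern for given (Q, theta, phi); the generating
# convention matched by pucker_from_z (round-trip exact).
pucker_to_z <- function(Q, theta, phi) {
  j <- 0:5
  q2 <- Q * sin(deg2rad(theta))
  q3 <- Q * cos(deg2rad(theta))
  sqrt(1 / 3) * q2 * cos(deg2rad(phi) + 4 * pi * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
}

#' @export
print.pucker_state <- function(x, ...) {
  if (isTRUE(x$planar)) {
    cat(sprintf("<pucker_state> planar (Q = %.4f A)\n", x$Q))
  } else {
    cat(sprintf("<pucker_state> Q = %.4f A, theta = %.2f deg, phi = %.2f deg\n",
                x$Q, x$theta, x$phi))
  }
  invisible(x)
}

## ---- canonical conformer table ------------------------------------------

# The 38 canonical forms: 2 chairs, 6 boats, 6 skews (twist-boats),
# 12 envelopes, 12 half-chairs.  Ideal (theta, phi) positions are derived
# once from the defining out-of-plane displacement patterns (which atoms
# lie above/below the reference plane), so the table is exactly consistent
# with pucker_from_z and the O5-first atom ordering.
canonical_cache <- new.env(parent = emptyenv())

#' Table of canonical pyranose ring conformers
#'
#' @return Data frame with columns `name`, `class` (chair, boat, skew,
#'   envelope, half-chair) and the ideal `theta`, `phi` in degrees.
#' @export
canonical_conformers <- function() {
  if (!is.null(canonical_cache$table)) return(canonical_cache$table)
  lab <- ring_atom_labels
  rows <- list()
  add <- function(name, class, z) {
    st <- pucker_from_z(z)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, class = class,
      theta = round(st$theta, 6), phi = round(st$phi, 6) %% 360)
  }
  # chairs: alternating pattern; C4 above / C1 below is 4C1 (theta = 0)
  add("4C1", "chair", c(1, -1, 1, -1, 1, -1))
  add("1C4", "chair", -c(1, -1, 1, -1, 1, -1))
  # boats and skews: pure theta = 90 cosine patterns every 30 deg in phi
  boat_names <- c("O,3B", "B1,4", "2,5B", "BO,3", "1,4B", "B2,5")
  skew_names <- c("3S1", "5S1", "2SO", "1S3", "1S5", "OS2")
  for (k in 0:5) {
    add(boat_names[k + 1], "boat", cos(deg2rad(60 * k) + 4 * pi * (0:5) / 6))
    add(skew_names[k + 1], "skew",
        cos(deg2rad(60 * k + 30) + 4 * pi * (0:5) / 6))
  }
  # envelopes: one atom out of the plane of the other five
  for (k in 1:6) {
    z <- numeric(6); z[k] <- 1
    add(paste0(lab[k], "E"), "envelope", z)
    add(paste0("E", lab[k]), "envelope", -z)
  }
  # half-chairs: adjacent pair on opposite sides
  for (k in 1:6) {
    k2 <- (k %% 6) + 1
    z <- numeric(6); z[k] <- 1; z[k2] <- -1
    add(paste0(lab[k], "H", lab[k2]), "half-chair", z)
    add(paste0(lab[k2], "H", lab[k]), "half-chair", -z)
  }
  tab <- do.call(rbind, rows)
  tab$phi[tab$class == "chair"] <- 0   # phase undefined at the poles
  canonical_cache$table <- tab
  tab
}

#' Classify a pucker state as its nearest canonical conformer
#'
#' Nearest of the 38 canonical forms on the (theta, phi) sphere by
#' great-circle distance.  Exact ties are broken deterministically toward
#' the candidate with lower ideal theta, then lower ideal phi.
#'
#' @param state A `"pucker_state"` from [puckering_coordinates()], or a
#'   list with `theta` and `phi` in degrees.
#' @param planarity_floor Minimum amplitude Q (Angstrom) for a defined
#'   phase; planar states are an error.
#' @return List of class `"conformer_label"`: `name`, `class`, ideal
#'   `theta`/`phi`, and `distance` (great-circle, degrees).
#' @export
classify_canonical <- function(state, planarity_floor = 0.05) {
  if (!is.null(state$Q) && (isTRUE(state$planar) || state$Q < planarity_floor))
    stop("ring is planar (Q below the planarity floor); no conformer label")
  tab <- canonical_conformers()
  d <- great_circle_deg(state$theta, state$phi, tab$theta, tab$phi)
  eps <- 1e-9
  cand <- which(d <= min(d) + eps)
  if (length(cand) > 1) {
    cand <- cand[order(tab$theta[cand], tab$phi[cand])]
  }
  k <- cand[1]
  structure(list(name = tab$name[k], class = tab$class[k],
                 theta = tab$theta[k], phi = tab$phi[k],
                 distance = d[k]),
            class = "conformer_label")
}

great_circle_deg <- function(t1, p1, t2, p2) {
  ct <- cos(deg2rad(t1)) * cos(deg2rad(t2)) +
    sin(deg2rad(t1)) * sin(deg2rad(t2)) * cos(deg2rad(p1 - p2))
  rad2deg(acos(pmax(-1, pmin(1, ct))))
}

#' @export
print.conformer_label <- function(x, ...) {
  cat(sprintf("<conformer_label> %s (%s), %.2f deg from ideal\n",
              x$name, x$class, x$distance))
  invisible(x)
}

## ---- torsion-space decomposition ----------------------------------------

# Ideal endocyclic torsion vectors of the canonical conformers, measured on
# rings generated at the canonical (theta, phi) with Q = 0.57 A.
canonical_torsion_basis <- function(Q = 0.57) {
  key <- sprintf("torsions_%.4f", Q)
  if (!is.null(canonical_cache[[key]])) return(canonical_cache[[key]])
  tab <- canonical_conformers()
  basis <- t(vapply(seq_len(nrow(tab)), function(k) {
    ring <- build_ring_from_pucker(Q = Q, theta = tab$theta[k],
                                   phi = tab$phi[k])
    endocyclic_torsions(ring, 1:6)
  }, numeric(6)))
  rownames(basis) <- tab$name
  canonical_cache[[key]] <- basis
  basis
}

#' Decompose endocyclic torsions over an ideal conformer basis
#'
#' Expresses an observed 6-vector of endocyclic torsions as the
#' least-squares linear combination of the ideal torsion patterns of a
#' chosen conformer basis (default: inverted chair 1C4, boat 1,4B and skew
#' OS2, which span the three pucker degrees of freedom).  Also reports the
#' closest canonical form in torsion space (highest cosine similarity over
#' all 38 ideal torsion vectors), an independent route to the
#' classification done by [classify_canonical()] on the pucker sphere.
#'
#' @param torsions Numeric vector of 6 endocyclic torsions in degrees.
#' @param basis_names Character vector of canonical names forming the basis.
#' @param Q Amplitude at which ideal basis rings are generated (Angstrom).
#' @return List: `coefficients` (named), `residual` (RMS of the fit, deg),
#'   `closest` (canonical name nearest in torsion space) and `similarity`
#'   (its cosine similarity).
#' @export
decompose_torsions <- function(torsions, basis_names = c("1C4", "1,4B", "OS2"),
                               Q = 0.57) {
  if (length(torsions) != 6 || any(!is.finite(torsions)))
    stop("torsions must be 6 finite angles in degrees")
  all_basis <- canonical_torsion_basis(Q)
  missing <- setdiff(basis_names, rownames(all_basis))
  if (length(missing)) stop("unknown conformer(s): ",
                            paste(missing, collapse = ", "))
  B <- t(all_basis[basis_names, , drop = FALSE])
  fit <- stats::lm.fit(B, torsions)
  coef <- fit$coefficients
  names(coef) <- basis_names
  sims <- apply(all_basis, 1, function(v) {
    s <- sqrt(sum(v^2)) * sqrt(sum(torsions^2))
    if (s < 1e-12) 0 else sum(v * torsions) / s
  })
  k <- which.max(sims)
  list(coefficients = coef,
       residual = sqrt(mean(fit$residuals^2)),
       closest = rownames(all_basis)[k],
       similarity = unname(sims[k]))
}

## ---- characteristic-length bins -----------------------------------------

# Characteristic relaxed unit lengths (anchor/glycosidic O-O distances, A)
# of the four conformer families seen after stretch-relax cycles.
.length_bin_centers <- c(c = 4.5, b1 = 4.3, b2 = 5.1, ic = 5.5)

#' Coarse conformer label from a characteristic unit length
#'
#' Bins a per-unit O-O distance to the nearest characteristic center:
#' chair (c, 4.5 A), twist-boat type 1 (b1, 4.3 A), twist-boat type 2
#' (b2, 5.1 A) or inverted chair (ic, 5.5 A), within a capture radius;
#' otherwise `"unassigned"`.  Exact ties go to the lower-energy conformer
#' family, chairs before twist-boats: c, ic, b1, b2.
#'
#' @param distance Numeric vector of O-O distances in Angstrom (> 0).
#' @param tolerance Capture radius around each center (default 0.25 A).
#' @return Character vector of labels.
#' @export
label_by_length <- function(distance, tolerance = 0.25) {
  stopifnot(all(distance > 0))
  priority <- c("c", "ic", "b1", "b2")
  centers <- .length_bin_centers[priority]
  vapply(distance, function(d) {
    dev <- abs(d - centers)
    if (min(dev) > tolerance) return("unassigned")
    names(centers)[which(dev <= min(dev) + 1e-12)][1]
  }, "")
}

#' Full pucker report for each saccharide unit
#'
#' Convenience wrapper: puckering coordinates, canonical label and length
#' bin for every unit of an oligomer.
#'
#' @param mol A [molecule()].
#' @param topo A `saccharide_topology`.
#' @return Data frame, one row per unit: `unit`, `Q`, `theta`, `phi`,
#'   `label`, `class`, `unit_length`, `length_bin`.
#' @export
ring_report <- function(mol, topo) {
  lens <- measure_unit_lengths(mol, topo)
  rows <- lapply(seq_along(topo$units), function(k) {
    ring <- topo$units[[k]]$ring[c("O5", "C1", "C2", "C3", "C4", "C5")]
    st <- puckering_coordinates(mol, ring)
    lb <- if (st$planar) list(name = "planar", class = "planar")
          else classify_canonical(st)
    data.frame(unit = k, Q = st$Q, theta = st$theta, phi = st$phi,
               label = lb$name, class = lb$class,
               unit_length = lens$unit_lengths[k],
               length_bin = label_by_length(lens$unit_lengths[k]))
  })
  do.call(rbind, rows)
}
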