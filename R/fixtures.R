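## Synthetic structure generators: ideal pyranose rings at arbitrary
## Cremer-Pople pucker, alpha-D-galacturonic-acid monomers with axial
## anchor oxygens, and (1->4)-linked oligomers up to (and beyond) the
## hexamer.  All geometry is built from standard bond lengths and
## tetrahedral/trigonal substituent placement; no external data needed.

# Standard bond lengths (Angstrom) used by every builder.
.std_bonds <- c(CC = 1.52, CO_ring = 1.43, CO_H = 1.42, C_dbl_O = 1.21,
                OH = 0.97, CH = 1.10)

#' Build a six-membered ring at a prescribed pucker
#'
#' Inverse Cremer-Pople construction: out-of-plane displacements are set
#' from (Q, theta, phi) and the in-plane polygon is the (unique convex)
#' cyclic hexagon whose 3D edge lengths equal the requested bond lengths.
#' [puckering_coordinates()] of the result recovers (Q, theta, phi)
#' exactly (to numerical precision), making this the round-trip oracle for
#' the pucker analysis.
#'
#' @param Q Total puckering amplitude in Angstrom (>= 0), or `NULL`
#'   (default) for the amplitude that minimizes endocyclic angle strain at
#'   the requested phase (about 0.61 A at the chair poles, 0.70 A on the
#'   boat/skew equator, in line with observed six-ring amplitudes).
#' @param theta,phi Phase angles in degrees (ignored where undefined, e.g.
#'   phi at the poles).
#' @param conformer Optional canonical conformer name (e.g. `"1C4"`,
#'   `"5S1"`); overrides `theta`/`phi` with the ideal values.
#' @param bond_cc,bond_co C-C and C-O(ring) bond lengths in Angstrom.
#' @return A [molecule()] of 6 atoms in ring order O5, C1..C5 with ring
#'   bonds.
#' @export
build_ring_from_pucker <- function(Q = NULL, theta = 0, phi = 0,
                                   conformer = NULL,
                                   bond_cc = .std_bonds[["CC"]],
                                   bond_co = .std_bonds[["CO_ring"]]) {
  if (!is.null(conformer)) {
    tab <- canonical_conformers()
    k <- match(conformer, tab$name)
    if (is.na(k)) stop("unknown canonical conformer: ", conformer)
    theta <- tab$theta[k]; phi <- tab$phi[k]
  }
  if (is.null(Q)) Q <- strain_optimal_amplitude(theta, phi, bond_cc, bond_co)
  if (Q < 0) stop("Q must be >= 0")
  z <- pucker_to_z(Q, theta, phi)
  # edge j joins ring atom j to j+1; edges 1 and 6 are C-O
  L <- c(bond_co, bond_cc, bond_cc, bond_cc, bond_cc, bond_co)
  dz <- z[c(2:6, 1)] - z
  t2 <- L^2 - dz^2
  if (any(t2 <= 0))
    stop("infeasible ring geometry: Q too large for the bond lengths")
  tl <- sqrt(t2)
  u <- cyclic_polygon_angles(tl)
  # clockwise winding so the mean-plane normal is +z
  ang <- cumsum(c(0, -u))[1:6]
  Rc <- tl[1] / (2 * sin(u[1] / 2))
  xy <- cbind(Rc * cos(ang), Rc * sin(ang))
  xy <- sweep(xy, 2, colMeans(xy))
  coords <- cbind(xy, z - mean(z))
  ring_bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = 1)
  molecule(c("O", "C", "C", "C", "C", "C"), coords, bonds = ring_bonds,
           labels = stats::setNames(c("O5", "C1", "C2", "C3", "C4", "C5"),
                                    as.character(1:6)))
}

# Amplitude minimizing the summed squared deviation of the six endocyclic
# bond angles from tetrahedral, at fixed phase and bond lengths.
strain_optimal_amplitude <- function(theta, phi, bond_cc, bond_co) {
  strain <- function(Q) {
    r <- try(build_ring_from_pucker(Q = Q, theta = theta, phi = phi,
                                    bond_cc = bond_cc, bond_co = bond_co),
             silent = TRUE)
    if (inherits(r, "try-error")) return(1e6)
    ang <- vapply(0:5, function(k)
      atom_angle(r, ((k - 1) %% 6) + 1, (k %% 6) + 1, ((k + 1) %% 6) + 1), 0)
    sum((ang - rad2deg(acos(-1 / 3)))^2)
  }
  stats::optimize(strain, c(0.2, 0.9), tol = 1e-8)$minimum
}

# Central angles of the convex cyclic polygon with side lengths tl:
# solve sum(2*asin(tl/(2R))) == 2*pi for the circumradius R.
cyclic_polygon_angles <- function(tl) {
  f <- function(R) sum(2 * asin(pmin(1, tl / (2 * R)))) - 2 * pi
  lo <- max(tl) / 2 * (1 + 1e-12)
  hi <- sum(tl)                       # generous upper bound, f(hi) < 0
  if (f(lo) < 0)
    stop("infeasible ring geometry: edges cannot close into a hexagon")
  R <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  2 * asin(tl / (2 * R))
}

## ---- local frames and placement helpers ---------------------------------

# The two tetrahedral exocyclic unit vectors at ring atom `c` with ring
# neighbours A (previous) and B (next).  Branch sign s = +1/-1 selects the
# component along unit(u x v); this sign is a conformation-independent
# stereo-descriptor.
exocyclic_pair <- function(A, c, B, target = acos(-1 / 3)) {
  u <- (A - c) / vnorm(A - c)
  v <- (B - c) / vnorm(B - c)
  w <- sum(u * v)
  a <- cos(target) / (1 + w)
  c2 <- 1 - a^2 * (2 + 2 * w)
  if (c2 < 0) stop("local geometry too distorted for tetrahedral placement")
  nloc <- pracma_cross(u, v)
  nloc <- nloc / vnorm(nloc)
  list(plus = a * (u + v) + sqrt(c2) * nloc,
       minus = a * (u + v) - sqrt(c2) * nloc)
}

# NeRF-style internal-coordinate placement: position of atom D given three
# reference atoms A-B-C, the C-D distance, the B-C-D angle and the
# A-B-C-D dihedral (degrees).
place_atom <- function(A, B, C, r, angle, dihedral) {
  bc <- (C - B) / vnorm(C - B)
  n <- pracma_cross(B - A, bc)
  n <- n / vnorm(n)
  m <- pracma_cross(n, bc)
  ang <- deg2rad(180 - angle)
  dih <- deg2rad(dihedral)
  d <- r * c(cos(ang), sin(ang) * cos(dih), -sin(ang) * sin(dih))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Deterministic unit vector perpendicular to w, biased toward `ref`.
perp_unit <- function(w, ref) {
  p <- ref - sum(ref * w) / sum(w * w) * w
  if (vnorm(p) < 1e-8) {
    ref <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- ref - sum(ref * w) / sum(w * w) * w
  }
  p / vnorm(p)
}

rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / vnorm(axis)
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * tcrossprod(a)
}

## ---- galacturonic monomer -----------------------------------------------

# Atom layout of the 23-atom monomer (C6H10O7).
.mono_index <- c(O5 = 1, C1 = 2, C2 = 3, C3 = 4, C4 = 5, C5 = 6,
                 O1 = 7, O2 = 8, O3 = 9, O4 = 10, C6 = 11, O6A = 12,
                 O6B = 13, H1 = 14, H2 = 15, H3 = 16, H4 = 17, H5 = 18,
                 HO1 = 19, HO2 = 20, HO3 = 21, HO4 = 22, HO6 = 23)

#' Build an alpha-D-galacturonic acid monomer at a chosen ring conformer
#'
#' 23-atom C6H10O7 unit: pyranose ring (O5, C1..C5), hydroxyls at
#' C1/C2/C3/C4 and a carboxyl group at C5.  In the reference chair (4C1)
#' the C1 and C4 oxygens are placed axially (the alpha-anomeric and galacto
#' configuration that makes the glycosidic and aglycone bonds mechanical
#' levers); the branch choice at every stereocentre is recorded in the
#' reference chair and re-applied at the requested conformer, so ring
#' inversion converts axial substituents to equatorial exactly as in the
#' physical molecule.
#'
#' @param conformer Canonical conformer name (default `"4C1"`).
#' @param Q Ring puckering amplitude in Angstrom.
#' @param anchors_axial If `TRUE` (default) O1 and O4 are axial in the
#'   reference chair; `FALSE` swaps them with their ring hydrogens.
#' @param ionized If `TRUE` build the carboxylate anion (drop the carboxyl
#'   proton, formal charge -1).
#' @return List with `mol` (the [molecule()]) and `topo` (the
#'   [saccharide_topology()], anchors `O4a` = O4, `O1a` = O1).
#' @export
build_galacturonic_monomer <- function(conformer = "4C1", Q = NULL,
                                       anchors_axial = TRUE,
                                       ionized = FALSE) {
  ring <- build_ring_from_pucker(Q = Q, conformer = conformer)
  ref <- if (identical(conformer, "4C1")) ring else
    build_ring_from_pucker(Q = Q, conformer = "4C1")
  # stereo branch signs recorded in the reference chair --------------------
  # axial/equatorial per substituent in 4C1: O1 ax, O2 eq, O3 eq, O4 ax,
  # C6 (carboxyl at C5) eq
  subst_axial <- c(C1 = TRUE, C2 = FALSE, C3 = FALSE, C4 = TRUE, C5 = FALSE)
  if (!anchors_axial) subst_axial[c("C1", "C4")] <- FALSE
  signs <- vapply(names(subst_axial), function(at) {
    k <- .mono_index[[at]]
    prev <- if (k == 2) 1L else k - 1L
    nxt <- if (k == 6) 1L else k + 1L
    pr <- exocyclic_pair(ref$coords[prev, ], ref$coords[k, ],
                         ref$coords[nxt, ])
    # mean-plane normal of the builder frame is +z
    ax_is_plus <- abs(pr$plus[3]) >= abs(pr$minus[3])
    if (subst_axial[[at]] == ax_is_plus) 1 else -1
  }, 0)

  coords <- matrix(NA_real_, 23, 3)
  coords[1:6, ] <- ring$coords
  centroid <- colMeans(ring$coords)
  branch <- function(at, s) {
    k <- .mono_index[[at]]
    prev <- if (k == 2) 1L else k - 1L
    nxt <- if (k == 6) 1L else k + 1L
    pr <- exocyclic_pair(ring$coords[prev, ], ring$coords[k, ],
                         ring$coords[nxt, ])
    if (s > 0) pr$plus else pr$minus
  }
  place_OH <- function(O, C) {
    w <- O - C
    p <- perp_unit(w, O - centroid)
    O + .std_bonds[["OH"]] *
      (cos(deg2rad(107.5)) * (-w / vnorm(w)) + sin(deg2rad(107.5)) * p)
  }
  ix <- .mono_index
  for (at in c("C1", "C2", "C3", "C4")) {
    k <- ix[[at]]
    On <- ix[[sub("C", "O", at)]]
    Hn <- ix[[sub("C", "H", at)]]
    e_sub <- branch(at, signs[[at]])
    e_h <- branch(at, -signs[[at]])
    coords[On, ] <- coords[k, ] + .std_bonds[["CO_H"]] * e_sub
    coords[Hn, ] <- coords[k, ] + .std_bonds[["CH"]] * e_h
    coords[ix[[paste0("HO", sub("C", "", at))]], ] <-
      place_OH(coords[On, ], coords[k, ])
  }
  # carboxyl at C5
  e_c6 <- branch("C5", signs[["C5"]])
  e_h5 <- branch("C5", -signs[["C5"]])
  coords[ix[["C6"]], ] <- coords[ix[["C5"]], ] + .std_bonds[["CC"]] * e_c6
  coords[ix[["H5"]], ] <- coords[ix[["C5"]], ] + .std_bonds[["CH"]] * e_h5
  uC <- (coords[ix[["C5"]], ] - coords[ix[["C6"]], ])
  uC <- uC / vnorm(uC)
  pC <- perp_unit(uC, coords[ix[["C6"]], ] - centroid)
  coords[ix[["O6A"]], ] <- coords[ix[["C6"]], ] + .std_bonds[["C_dbl_O"]] *
    (cos(deg2rad(120)) * uC + sin(deg2rad(120)) * pC)
  coords[ix[["O6B"]], ] <- coords[ix[["C6"]], ] + .std_bonds[["CO_H"]] *
    (cos(deg2rad(120)) * uC - sin(deg2rad(120)) * pC)
  coords[ix[["HO6"]], ] <- place_OH(coords[ix[["O6B"]], ],
                                    coords[ix[["C6"]], ])

  elements <- c("O", "C", "C", "C", "C", "C", "O", "O", "O", "O", "C",
                "O", "O", "H", "H", "H", "H", "H", "H", "H", "H", "H", "H")
  bonds <- rbind(
    data.frame(i = 1:6, j = c(2:6, 1), order = 1),               # ring
    data.frame(i = c(ix[["C1"]], ix[["C2"]], ix[["C3"]], ix[["C4"]]),
               j = c(ix[["O1"]], ix[["O2"]], ix[["O3"]], ix[["O4"]]),
               order = 1),
    data.frame(i = ix[["C5"]], j = ix[["C6"]], order = 1),
    data.frame(i = ix[["C6"]], j = c(ix[["O6A"]], ix[["O6B"]]),
               order = c(2, 1)),
    data.frame(i = c(ix[["C1"]], ix[["C2"]], ix[["C3"]], ix[["C4"]],
                     ix[["C5"]]),
               j = c(ix[["H1"]], ix[["H2"]], ix[["H3"]], ix[["H4"]],
                     ix[["H5"]]), order = 1),
    data.frame(i = c(ix[["O1"]], ix[["O2"]], ix[["O3"]], ix[["O4"]],
                     ix[["O6B"]]),
               j = c(ix[["HO1"]], ix[["HO2"]], ix[["HO3"]], ix[["HO4"]],
                     ix[["HO6"]]), order = 1))
  labels <- stats::setNames(names(ix), as.character(unname(ix)))
  mol <- molecule(elements, coords, bonds = bonds, labels = labels)
  if (ionized) {
    mol <- delete_atoms(mol, ix[["HO6"]])
    mol$formal_charge <- -1L
  }
  topo <- monomer_topology(offset = 0L, ionized = ionized)
  topo <- saccharide_topology(topo$units, topo$linkages, topo$anchors,
                              mol = mol)
  list(mol = mol, topo = topo)
}

# Topology of one monomer block at an index offset (before any deletions).
monomer_topology <- function(offset = 0L, ionized = FALSE) {
  ix <- .mono_index
  unit <- list(ring = stats::setNames(
    as.integer(ix[c("O5", "C1", "C2", "C3", "C4", "C5")] + offset),
    c("O5", "C1", "C2", "C3", "C4", "C5")),
    O1 = as.integer(ix[["O1"]] + offset),
    O4 = as.integer(ix[["O4"]] + offset),
    carboxyl = as.integer(c(ix[["O6A"]], ix[["O6B"]]) + offset))
  list(units = list(unit), linkages = NULL,
       anchors = c(O4a = as.integer(ix[["O4"]] + offset),
                   O1a = as.integer(ix[["O1"]] + offset)))
}

#' Delete atoms from a molecule
#'
#' Removes atoms and every bond touching them; remaining indices are
#' shifted down.  The returned molecule carries an `index_map` attribute
#' mapping old indices to new (NA for deleted atoms).
#'
#' @param mol A [molecule()].
#' @param idx Integer indices of atoms to delete.
#' @return The reduced molecule.
#' @export
delete_atoms <- function(mol, idx) {
  n <- n_atoms(mol)
  keep <- setdiff(seq_len(n), idx)
  map <- rep(NA_integer_, n)
  map[keep] <- seq_along(keep)
  b <- mol$bonds
  b <- b[!(b$i %in% idx) & !(b$j %in% idx), , drop = FALSE]
  b$i <- map[b$i]; b$j <- map[b$j]
  labels <- mol$labels
  if (!is.null(labels)) {
    old <- as.integer(names(labels))
    ok <- !is.na(map[old])
    labels <- stats::setNames(labels[ok], as.character(map[old[ok]]))
  }
  out <- molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE],
                  bonds = b, formal_charge = mol$formal_charge,
                  labels = labels)
  attr(out, "index_map") <- map
  out
}

## ---- oligomer assembly ---------------------------------------------------

#' Build a (1->4)-linked alpha-D-galacturonic acid oligomer
#'
#' Chains `n_units` monomers through glycosidic bonds C1(i)-Og-C4(i+1):
#' unit i's anomeric oxygen becomes the glycosidic oxygen, unit i+1 loses
#' its O4 hydroxyl (condensation: 23n - 3(n-1) atoms).  Units are ordered
#' from the free-O4 (`O4a`) terminus.  Glycosidic dihedrals phi
#' (H1-C1-Og-C4') and psi (C1-Og-C4'-H4') are set per linkage.
#'
#' @param n_units Number of saccharide units (>= 1).
#' @param conformers Canonical conformer per unit (recycled).
#' @param phi,psi Glycosidic dihedrals in degrees per linkage (recycled);
#'   defaults give an extended, clash-free chain.
#' @param Q Ring puckering amplitude (Angstrom).
#' @param ionized Logical per unit (recycled): carboxylate anion units.
#' @param min_separation Clash threshold between non-bonded atoms
#'   (Angstrom); on a clash the linkage dihedrals are nudged and the build
#'   retried, else an error names the offending pair.
#' @return List with `mol`, `topo`, and `clash_adjusted` (logical).
#' @export
build_oligomer <- function(n_units, conformers = "4C1", phi = -35, psi = -25,
                           Q = NULL, ionized = FALSE, min_separation = 1.0) {
  stopifnot(n_units >= 1)
  conformers <- rep_len(conformers, n_units)
  phi <- rep_len(phi, max(1, n_units - 1))
  psi <- rep_len(psi, max(1, n_units - 1))
  ionized <- rep_len(ionized, n_units)
  offsets <- c(0, 20, -20, 40, -40)
  for (adj in offsets) {
    res <- try(assemble_oligomer(n_units, conformers, phi + adj, psi + adj,
                                 Q, ionized, min_separation), silent = TRUE)
    if (!inherits(res, "try-error")) {
      res$clash_adjusted <- adj != 0
      if (res$clash_adjusted)
        message("glycosidic dihedrals adjusted by ", adj,
                " deg to avoid a steric clash")
      return(res)
    }
    last_err <- attr(res, "condition")
    if (!grepl("steric clash", conditionMessage(last_err))) stop(last_err)
  }
  stop(conditionMessage(last_err))
}

assemble_oligomer <- function(n_units, conformers, phi, psi, Q, ionized,
                              min_separation) {
  ix <- .mono_index
  first <- build_galacturonic_monomer(conformers[1], Q = Q)
  mol <- first$mol
  # per-unit index vectors into the growing molecule (full 23-atom maps)
  unit_map <- list(stats::setNames(as.integer(ix), names(ix)))
  link_rows <- list()
  if (n_units > 1) {
    for (i in 2:n_units) {
      prevm <- unit_map[[i - 1]]
      nxt <- build_galacturonic_monomer(conformers[i], Q = Q)$mol
      # target position of the new unit's C4 from the established
      # H1-C1-O1 frame of the previous unit and the phi dihedral
      A <- mol$coords[prevm[["H1"]], ]
      B <- mol$coords[prevm[["C1"]], ]
      Cg <- mol$coords[prevm[["O1"]], ]
      C4p <- place_atom(A, B, Cg, .std_bonds[["CO_H"]], 117, phi[i - 1])
      # rigid-align the new unit: O4 -> Og position, C4 -> C4p
      v_from <- nxt$coords[ix[["O4"]], ] - nxt$coords[ix[["C4"]], ]
      v_to <- Cg - C4p
      R1 <- rotation_between(v_from, v_to)
      xyz <- nxt$coords %*% t(R1)
      xyz <- sweep(xyz, 2, xyz[ix[["C4"]], ] - C4p, "-")
      # spin about the Og-C4' axis to set psi = C1-Og-C4'-H4'; the
      # rotation sense relative to the dihedral sign is detected from the
      # first attempt and corrected exactly
      spin <- function(xyz, delta) {
        R2 <- rotation_about_axis(xyz[ix[["C4"]], ] - Cg, deg2rad(delta))
        sweep(sweep(xyz, 2, Cg) %*% t(R2), 2, Cg, "+")
      }
      meas <- function(xyz)
        dihedral_points(B, Cg, xyz[ix[["C4"]], ], xyz[ix[["H4"]], ])
      cur <- meas(xyz)
      delta <- wrap180(psi[i - 1] - cur)
      xyz2 <- spin(xyz, delta)
      if (abs(delta) > 1e-9 && abs(wrap180(meas(xyz2) - psi[i - 1])) > 1e-6)
        xyz2 <- spin(xyz, -delta)
      xyz <- xyz2
      nxt$coords <- xyz
      # condensation: the new unit loses O4 and its hydroxyl proton; the
      # previous unit loses the proton on its (now glycosidic) O1
      nxt2 <- delete_atoms(nxt, c(ix[["O4"]], ix[["HO4"]]))
      nmap <- attr(nxt2, "index_map")
      mol2 <- delete_atoms(mol, prevm[["HO1"]])
      pmap <- attr(mol2, "index_map")
      unit_map <- lapply(unit_map, function(m) {
        m2 <- pmap[m]; names(m2) <- names(m); m2
      })
      off <- n_atoms(mol2)
      newmap <- nmap[ix] + off
      names(newmap) <- names(ix)
      newmap[["O4"]] <- unit_map[[i - 1]][["O1"]]   # shared glycosidic O
      unit_map[[i]] <- newmap
      # merge
      labels2 <- c(mol2$labels,
                   stats::setNames(nxt2$labels,
                                   as.character(as.integer(names(nxt2$labels))
                                                + off)))
      bonds <- rbind(mol2$bonds,
                     data.frame(i = nxt2$bonds$i + off,
                                j = nxt2$bonds$j + off,
                                order = nxt2$bonds$order),
                     data.frame(i = unit_map[[i - 1]][["O1"]],
                                j = newmap[["C4"]], order = 1))
      mol <- molecule(c(mol2$elements, nxt2$elements),
                      rbind(mol2$coords, nxt2$coords),
                      bonds = bonds,
                      formal_charge = mol2$formal_charge +
                        nxt2$formal_charge,
                      labels = labels2)
      link_rows[[i - 1]] <- data.frame(C1 = unit_map[[i - 1]][["C1"]],
                                       Og = unit_map[[i - 1]][["O1"]],
                                       C4next = newmap[["C4"]])
    }
  }
  # ionization after assembly so deletions do not disturb the linking
  for (i in which(ionized)) {
    h <- unit_map[[i]][["HO6"]]
    mol <- delete_atoms(mol, h)
    map <- attr(mol, "index_map")
    unit_map <- lapply(unit_map, function(m) {
      m2 <- map[m]; names(m2) <- names(m); m2
    })
    mol$formal_charge <- mol$formal_charge - 1L
    for (k in seq_along(link_rows))
      link_rows[[k]][] <- lapply(link_rows[[k]], function(v) map[v])
  }
  check_clashes(mol, min_separation)
  units <- lapply(unit_map, function(m) {
    list(ring = m[c("O5", "C1", "C2", "C3", "C4", "C5")],
         O1 = unname(m[["O1"]]), O4 = unname(m[["O4"]]),
         carboxyl = unname(m[c("O6A", "O6B")]))
  })
  anchors <- c(O4a = unname(unit_map[[1]][["O4"]]),
               O1a = unname(unit_map[[n_units]][["O1"]]))
  linkages <- if (length(link_rows)) do.call(rbind, link_rows) else NULL
  topo <- saccharide_topology(units, linkages, anchors, mol = mol)
  list(mol = mol, topo = topo)
}

rotation_between <- function(a, b) {
  a <- a / vnorm(a); b <- b / vnorm(b)
  v <- pracma_cross(a, b)
  s <- vnorm(v); c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    p <- perp_unit(a, c(1, 0, 0))
    return(rotation_about_axis(p, pi))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

# Error when two atoms more than two bonds apart come closer than `thresh`.
check_clashes <- function(mol, thresh) {
  n <- n_atoms(mol)
  if (n < 4) return(invisible(TRUE))
  d <- as.matrix(stats::dist(mol$coords))
  adj <- matrix(FALSE, n, n)
  adj[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
  adj <- adj | t(adj)
  two <- (adj %*% adj) > 0                 # within two bonds
  excl <- adj | two | diag(TRUE, n)
  bad <- which(d < thresh & !excl & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("steric clash: atoms %d and %d are %.2f A apart",
                 bad[1, 1], bad[1, 2], d[bad[1, 1], bad[1, 2]]))
  invisible(TRUE)
}

#' Randomly perturb coordinates
#'
#' Adds an independent uniform displacement in [-amplitude, amplitude] to
#' every Cartesian coordinate.  The global RNG state is saved and
#' restored; the same seed always yields the same perturbation.
#'
#' @param mol A [molecule()].
#' @param amplitude Maximum displacement per coordinate (Angstrom, >= 0).
#' @param seed Integer seed.
#' @return The perturbed molecule.
#' @export
perturb_molecule <- function(mol, amplitude, seed = 1L) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(mol)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- n_atoms(mol)
  mol$coords <- mol$coords + matrix(stats::runif(3 * n, -amplitude,
                                                 amplitude), n, 3)
  mol
}
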