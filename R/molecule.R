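## Structure data model: the universal molecule record plus geometric
## primitives (distances, angles, torsions) shared by every other module.

# Covalent radii (Angstrom, Cordero-style consensus values) used for bond
# inference when a file format carries no connectivity.
.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

.atomic_masses <- c(
  H = 1.00782503, B = 11.009305, C = 12.0, N = 14.003074, O = 15.994915,
  F = 18.998403, Na = 22.989770, Mg = 23.985042, Si = 27.976927,
  P = 30.973762, S = 31.972071, Cl = 34.968853, K = 38.963707,
  Ca = 39.962591, Br = 78.918338, I = 126.904473
)

#' Construct a molecule
#'
#' The universal structure record: element symbols, Cartesian coordinates in
#' Angstrom, an explicit bond list, and a formal charge.  Optional `labels`
#' tag atom indices with roles (e.g. `"O4a"`, `"O1a"` for anchor oxygens).
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix, one row per atom, three columns (Angstrom).
#' @param bonds Data frame or matrix with columns `i`, `j` (1-based atom
#'   indices) and optionally `order`; may be `NULL` for no bonds.
#' @param formal_charge Integer total formal charge.
#' @param labels Optional named character vector: names are atom indices
#'   (as strings), values are role tags.
#' @return An object of class `"molecule"`.
#' @export
molecule <- function(elements, coords, bonds = NULL, formal_charge = 0L,
                     labels = NULL) {
  elements <- as.character(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3)
    stop("coords must have three columns (x, y, z in Angstrom)")
  n <- length(elements)
  if (nrow(coords) != n)
    stop(sprintf("element count (%d) and coordinate rows (%d) differ",
                 n, nrow(coords)))
  unknown <- setdiff(unique(elements), names(.covalent_radii))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  bonds <- normalize_bonds(bonds, n)
  mol <- structure(list(
    elements = elements,
    coords = coords,
    bonds = bonds,
    formal_charge = as.integer(formal_charge),
    labels = labels
  ), class = "molecule")
  mol
}

# Canonical bond table: i < j, unique unordered pairs, valid indices.
normalize_bonds <- function(bonds, n) {
  if (is.null(bonds) || NROW(bonds) == 0)
    return(data.frame(i = integer(0), j = integer(0), order = numeric(0)))
  bonds <- as.data.frame(bonds)
  if (!all(c("i", "j") %in% names(bonds)))
    names(bonds)[1:2] <- c("i", "j")
  if (is.null(bonds$order)) bonds$order <- 1
  i <- pmin(bonds$i, bonds$j); j <- pmax(bonds$i, bonds$j)
  if (any(i == bonds$j & j == bonds$i & i == j) || any(bonds$i == bonds$j))
    stop("bond connects an atom to itself")
  if (any(i < 1) || any(j > n))
    stop("bond index out of range 1..", n)
  out <- data.frame(i = as.integer(i), j = as.integer(j),
                    order = as.numeric(bonds$order))
  if (anyDuplicated(out[, c("i", "j")]))
    stop("duplicate bonds present")
  out[order(out$i, out$j), , drop = FALSE]
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, %d bonds, formal charge %+d\n",
              n_atoms(x), nrow(x$bonds), x$formal_charge))
  tab <- table(x$elements)
  cat("  composition:",
      paste0(names(tab), ifelse(tab > 1, tab, ""), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Infer bonds from a covalent-radius distance cutoff
#'
#' Two atoms are bonded when their distance is below `scale` times the sum
#' of their covalent radii.  Used for formats (plain XYZ, PDB without
#' CONECT) that carry no connectivity.
#'
#' @param mol A `molecule`.
#' @param scale Cutoff multiplier on the radius sum (default 1.3).
#' @return The molecule with its `bonds` table replaced by inferred bonds.
#' @export
infer_bonds <- function(mol, scale = 1.3) {
  n <- n_atoms(mol)
  if (n < 2) { mol$bonds <- normalize_bonds(NULL, n); return(mol) }
  r <- .covalent_radii[mol$elements]
  d <- as.matrix(stats::dist(mol$coords))
  cut <- outer(r, r, "+") * scale
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  mol$bonds <- normalize_bonds(
    data.frame(i = hit[, 1], j = hit[, 2], order = 1), n)
  mol
}

## ---- geometric primitives ------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

#' Distance between two atoms
#' @param mol A `molecule`.
#' @param i,j Atom indices.
#' @return Distance in Angstrom.
#' @export
atom_distance <- function(mol, i, j) vnorm(mol$coords[i, ] - mol$coords[j, ])

#' Torsion angle of four points
#'
#' Signed dihedral in degrees, IUPAC sign convention (positive for a
#' clockwise rotation of the far bond when sighting down the central bond),
#' wrapped to (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate torsion: three consecutive atoms are collinear")
  m1 <- pracma_cross(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  wrap180(rad2deg(ang))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle between four atoms of a molecule
#' @inheritParams atom_distance
#' @param k,l Further atom indices.
#' @return Signed dihedral in degrees in (-180, 180].
#' @export
atom_dihedral <- function(mol, i, j, k, l) {
  x <- mol$coords
  dihedral_points(x[i, ], x[j, ], x[k, ], x[l, ])
}

#' Bond angle between three atoms
#' @inheritParams atom_dihedral
#' @return Angle in degrees in [0, 180].
#' @export
atom_angle <- function(mol, i, j, k) {
  u <- mol$coords[i, ] - mol$coords[j, ]
  v <- mol$coords[k, ] - mol$coords[j, ]
  rad2deg(acos(max(-1, min(1, sum(u * v) / (vnorm(u) * vnorm(v))))))
}

## ---- saccharide topology -------------------------------------------------

#' Construct a saccharide topology
#'
#' Index map locating, for each saccharide unit, the six ring atoms
#' (O5, C1..C5), the exocyclic oxygens on the C1 and C4 sides, and the
#' carboxyl oxygens; plus the glycosidic linkages and the two terminal
#' anchor oxygens the pulling forces act on.  Units are ordered from the
#' free-O4 (`O4a`) end: unit i's C1 is joined through a glycosidic oxygen
#' to unit i+1's C4.
#'
#' @param units List, one entry per saccharide unit, each a list with a
#'   named integer vector `ring` (names `O5, C1, C2, C3, C4, C5`), scalars
#'   `O1` and `O4` (exocyclic oxygen indices on the C1/C4 sides), and
#'   optionally `carboxyl` (indices of the two carboxyl oxygens).
#' @param linkages Data frame with columns `C1`, `Og`, `C4next` (atom
#'   indices), one row per glycosidic linkage; zero rows for a monomer.
#' @param anchors Named integer vector `c(O4a = ..., O1a = ...)`: terminal
#'   anchor oxygens (never ring atoms).
#' @param mol Optional `molecule` to validate the indices against.
#' @return An object of class `"saccharide_topology"`.
#' @export
saccharide_topology <- function(units, linkages = NULL, anchors, mol = NULL) {
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  for (u in units) {
    if (!all(ring_names %in% names(u$ring)))
      stop("each unit needs ring indices named ", paste(ring_names, collapse = ", "))
    if (length(unique(u$ring[ring_names])) != 6)
      stop("ring atom indices must be six distinct atoms")
  }
  if (is.null(linkages))
    linkages <- data.frame(C1 = integer(0), Og = integer(0), C4next = integer(0))
  if (!all(c("O4a", "O1a") %in% names(anchors)))
    stop("anchors must be named O4a and O1a")
  topo <- structure(list(units = units,
                         linkages = as.data.frame(linkages),
                         anchors = c(O4a = as.integer(anchors[["O4a"]]),
                                     O1a = as.integer(anchors[["O1a"]]))),
                    class = "saccharide_topology")
  if (!is.null(mol)) validate_topology(mol, topo)
  topo
}

#' Validate a topology against a molecule
#'
#' Checks index ranges, that linkage atoms are bonded, and that the anchors
#' are oxygens outside every ring.
#'
#' @param mol A `molecule`.
#' @param topo A `saccharide_topology`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_topology <- function(mol, topo) {
  n <- n_atoms(mol)
  idx <- unlist(lapply(topo$units, function(u) u$ring))
  idx <- c(idx, topo$anchors, unlist(topo$linkages))
  if (any(idx < 1 | idx > n)) stop("topology index out of atom range")
  bkey <- paste(mol$bonds$i, mol$bonds$j)
  bonded <- function(a, b) paste(min(a, b), max(a, b)) %in% bkey
  if (nrow(topo$linkages)) {
    for (r in seq_len(nrow(topo$linkages))) {
      lk <- topo$linkages[r, ]
      if (!bonded(lk$C1, lk$Og) || !bonded(lk$Og, lk$C4next))
        stop("glycosidic linkage atoms are not bonded in the molecule")
    }
  }
  ring_atoms <- unlist(lapply(topo$units, function(u) u$ring))
  for (a in topo$anchors) {
    if (a %in% ring_atoms) stop("anchor oxygen is a ring atom")
    if (mol$elements[a] != "O") stop("anchor atom is not oxygen")
  }
  invisible(TRUE)
}

#' @export
print.saccharide_topology <- function(x, ...) {
  cat(sprintf("<saccharide_topology> %d unit(s), %d glycosidic linkage(s)\n",
              length(x$units), nrow(x$linkages)))
  cat(sprintf("  anchors: O4a = atom %d, O1a = atom %d\n",
              x$anchors[["O4a"]], x$anchors[["O1a"]]))
  invisible(x)
}

#' Characteristic per-unit oxygen-oxygen lengths
#'
#' For each saccharide unit the distance between its two flanking
#' distinctive oxygens in chain order (terminal anchor or glycosidic
#' oxygen), plus the total anchor-to-anchor molecule length `L`.  For a
#' monomer the single unit length equals `L`.
#'
#' @param mol A `molecule`.
#' @param topo A `saccharide_topology` consistent with `mol`.
#' @return List with `unit_lengths` (numeric, one per unit, Angstrom),
#'   `flanks` (two-column matrix of the oxygen indices used) and `L`
#'   (anchor-to-anchor distance, Angstrom).
#' @export
measure_unit_lengths <- function(mol, topo) {
  validate_topology(mol, topo)
  nu <- length(topo$units)
  left <- c(topo$anchors[["O4a"]],
            if (nu > 1) topo$linkages$Og else integer(0))
  right <- c(if (nu > 1) topo$linkages$Og else integer(0),
             topo$anchors[["O1a"]])
  if (length(left) != nu || length(right) != nu)
    stop("linkage count inconsistent with unit count")
  ul <- vapply(seq_len(nu),
               function(k) atom_distance(mol, left[k], right[k]), 0)
  list(unit_lengths = ul,
       flanks = cbind(left = left, right = right),
       L = atom_distance(mol, topo$anchors[["O4a"]], topo$anchors[["O1a"]]))
}

#' Glycosidic dihedral angles of every linkage
#'
#' By default phi is measured as H1-C1-Og-C4' and psi as C1-Og-C4'-H4'
#' (the hydrogen-referenced convention); explicit atom quadruples can be
#' supplied to override either angle.  The quadruples actually used are
#' returned alongside the angles, wrapped to (-180, 180].
#'
#' @param mol A `molecule`.
#' @param topo A `saccharide_topology`.
#' @param quadruples Optional list with elements `phi` and/or `psi`, each a
#'   list (one per linkage) of 4 atom indices measured verbatim.
#' @return Data frame with one row per linkage: `linkage`, `phi`, `psi`,
#'   and the atom quadruples as list columns.
#' @export
glycosidic_dihedrals <- function(mol, topo, quadruples = NULL) {
  nl <- nrow(topo$linkages)
  if (nl == 0)
    return(data.frame(linkage = integer(0), phi = numeric(0), psi = numeric(0)))
  find_h <- function(c_idx) {
    nb <- c(mol$bonds$j[mol$bonds$i == c_idx], mol$bonds$i[mol$bonds$j == c_idx])
    h <- nb[mol$elements[nb] == "H"]
    if (!length(h)) stop("no hydrogen bonded to atom ", c_idx,
                         " for the default dihedral convention")
    h[1]
  }
  phi_q <- vector("list", nl); psi_q <- vector("list", nl)
  phi <- psi <- numeric(nl)
  for (k in seq_len(nl)) {
    lk <- topo$linkages[k, ]
    pq <- if (!is.null(quadruples$phi)) quadruples$phi[[k]] else
      c(find_h(lk$C1), lk$C1, lk$Og, lk$C4next)
    sq <- if (!is.null(quadruples$psi)) quadruples$psi[[k]] else
      c(lk$C1, lk$Og, lk$C4next, find_h(lk$C4next))
    phi[k] <- do.call(dihedral_points, lapply(pq, function(i) mol$coords[i, ]))
    psi[k] <- do.call(dihedral_points, lapply(sq, function(i) mol$coords[i, ]))
    phi_q[[k]] <- pq; psi_q[[k]] <- sq
  }
  out <- data.frame(linkage = seq_len(nl), phi = phi, psi = psi)
  out$phi_atoms <- phi_q
  out$psi_atoms <- psi_q
  out
}
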