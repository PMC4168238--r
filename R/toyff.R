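## Built-in toy molecular-mechanics backend.  Morse bonds (harmonic
## curvature k at r0, finite dissociation energy D, hence a finite
## maximum transmissible tension), cosine-harmonic angles (bounded
## torque), 3-fold cosine torsions, a two-term cosine profile on
## endocyclic ring torsions, and a soft quadratic nonbonded repulsion.
## The finite bond/angle force capacity is what lets a pulled ring become
## mechanically unstable and flip instead of stretching forever.  The ring profile
## is tuned so an isolated pyranose-like six-ring has a chair global
## minimum, a twist-boat local-minimum band, and an inverted-chair
## minimum, with inversion passing through the twist-boat band -- the
## qualitative topography the stretch-relax protocol probes.  No claim of
## thermochemical accuracy; energies are Hartree, gradients Hartree/Bohr.

#' Default parameters of the toy energy model
#'
#' Reads the versioned parameter file shipped with the package and applies
#' optional overrides (named sublists are merged shallowly).
#'
#' @param overrides Named list, e.g. `list(ring_profile = list(k2 = 0.006))`.
#' @param version Parameter file version to load.
#' @return List of class `"toy_ff_params"`.
#' @export
toy_ff_params <- function(overrides = NULL, version = 1) {
  path <- system.file("extdata",
                      sprintf("toyff_params_v%d.json", version),
                      package = "egopull")
  if (path == "")
    stop("no toy force-field parameter file for version ", version)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (is.list(overrides[[nm]]) && is.list(p[[nm]]))
        p[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      else p[[nm]] <- overrides[[nm]]
    }
  }
  stopifnot(all(unlist(p$bond$k) > 0), p$angle$k > 0)
  class(p) <- "toy_ff_params"
  p
}

bond_type_key <- function(e1, e2, order) {
  rank <- c(C = 1, O = 2, H = 3)   # canonical order: CC, CO, CH, OH
  ifelse(order >= 2 & ((e1 == "C" & e2 == "O") | (e1 == "O" & e2 == "C")),
         "CO2",
         vapply(seq_along(e1), function(k) {
           pair <- c(e1[k], e2[k])
           r <- rank[pair]
           if (anyNA(r)) paste0(sort(pair), collapse = "")
           else paste0(pair[order(r)], collapse = "")
         }, ""))
}

#' Build the toy energy model for a molecule
#'
#' Assembles bonded terms from the molecule's bond list (angles around
#' every centre, torsions around every central bond), marks endocyclic
#' ring torsions (which receive the extra ring profile) from the topology,
#' and excludes pairs within three bonds from the nonbonded repulsion.
#'
#' @param mol A [molecule()] with bonds.
#' @param topo Optional `saccharide_topology`; when given, the six ring
#'   bonds of every unit get the ring torsion profile.  Without it, ring
#'   bonds are detected as bonds lying on any 6-cycle of ring atoms found
#'   in `mol$labels`, or none.
#' @param params A `"toy_ff_params"` list (default [toy_ff_params()]).
#' @return An object of class `"energy_model"`: list with
#'   `evaluate(coords)` returning `list(energy, gradient)` (Hartree,
#'   Hartree/Bohr), plus the term tables and `reference_lengths` (per-bond
#'   equilibrium lengths used as rupture reference).
#' @export
toy_ff_build <- function(mol, topo = NULL, params = toy_ff_params()) {
  if (nrow(mol$bonds) == 0) stop("molecule has no bonds")
  n <- n_atoms(mol)
  el <- mol$elements
  b <- mol$bonds

  key <- bond_type_key(el[b$i], el[b$j], b$order)
  missing <- setdiff(unique(key), names(params$bond$k))
  if (length(missing))
    stop("no bond parameters for type(s): ", paste(missing, collapse = ", "))
  bond_tab <- data.frame(i = b$i, j = b$j,
                         k = unlist(params$bond$k[key]),
                         r0 = unlist(params$bond$r0[key]),
                         D = unlist(params$bond$D[key]))
  bond_tab$a <- sqrt(bond_tab$k / (2 * bond_tab$D))

  nb_list <- neighbors_list(b, n)
  sp2 <- rep(FALSE, n)
  sp2[unique(c(b$i[b$order >= 2], b$j[b$order >= 2]))] <- TRUE

  ang <- list(); k <- 0L
  for (cen in seq_len(n)) {
    nbs <- nb_list[[cen]]
    if (length(nbs) < 2) next
    cmb <- utils::combn(nbs, 2)
    th0 <- if (el[cen] == "O") params$angle$theta0_O
           else if (sp2[cen]) params$angle$theta0_sp2
           else params$angle$theta0_sp3
    for (c2 in seq_len(ncol(cmb))) {
      k <- k + 1L
      ang[[k]] <- c(cmb[1, c2], cen, cmb[2, c2], th0)
    }
  }
  angle_tab <- if (k) as.data.frame(do.call(rbind, ang)) else
    data.frame(V1 = integer(0), V2 = integer(0), V3 = integer(0),
               V4 = numeric(0))
  names(angle_tab) <- c("i", "j", "k", "theta0")

  ring_bond_keys <- character(0)
  if (!is.null(topo)) {
    for (u in topo$units) {
      r <- u$ring
      ring_bond_keys <- c(ring_bond_keys,
                          paste(pmin(r, r[c(2:6, 1)]),
                                pmax(r, r[c(2:6, 1)])))
    }
  }
  tor <- list(); k <- 0L
  for (bb in seq_len(nrow(b))) {
    aj <- b$i[bb]; ak <- b$j[bb]
    is_ring <- paste(min(aj, ak), max(aj, ak)) %in% ring_bond_keys
    for (ai in setdiff(nb_list[[aj]], ak))
      for (al in setdiff(nb_list[[ak]], aj)) {
        if (ai == al) next
        k <- k + 1L
        tor[[k]] <- c(ai, aj, ak, al, as.numeric(is_ring))
      }
  }
  torsion_tab <- if (k) as.data.frame(do.call(rbind, tor)) else
    data.frame(i = integer(0), j = integer(0), k = integer(0),
               l = integer(0), ring = numeric(0))
  names(torsion_tab) <- c("i", "j", "k", "l", "ring")
  # the ring profile is per ring bond; spread it over that bond's
  # quadruples so its strength is independent of substitution count
  if (nrow(torsion_tab)) {
    keyb <- paste(torsion_tab$j, torsion_tab$k)
    cnt <- table(keyb[torsion_tab$ring > 0])
    torsion_tab$ring_w <- ifelse(torsion_tab$ring > 0,
                                 1 / as.numeric(cnt[keyb]), 0)
  } else torsion_tab$ring_w <- numeric(0)

  excl <- pairs_within_bonds(b, n, 3)
  sig_class <- ifelse(el == "H", "H", "X")
  np <- params$nonbonded

  model <- list(
    evaluate = NULL,
    bond_tab = bond_tab, angle_tab = angle_tab, torsion_tab = torsion_tab,
    params = params, n_atoms = n,
    reference_lengths = bond_tab$r0
  )

  bohr <- ego_constants[["bohr_A"]]
  model$evaluate <- function(coords) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop("coordinate count mismatch")
    g <- matrix(0, n, 3)   # Hartree / Angstrom, converted on return
    e <- 0

    ## bonds (Morse: V = D (1 - exp(-a (r - r0)))^2, V''(r0) = k)
    dv <- coords[bond_tab$i, , drop = FALSE] - coords[bond_tab$j, , drop = FALSE]
    dl <- sqrt(rowSums(dv^2))
    ex <- exp(-bond_tab$a * (dl - bond_tab$r0))
    e <- e + sum(bond_tab$D * (1 - ex)^2)
    f <- 2 * bond_tab$D * bond_tab$a * (1 - ex) * ex / dl
    g <- acc_rows(g, bond_tab$i, dv * f)
    g <- acc_rows(g, bond_tab$j, -dv * f)

    ## angles
    if (nrow(angle_tab)) {
      u <- coords[angle_tab$i, , drop = FALSE] - coords[angle_tab$j, , drop = FALSE]
      v <- coords[angle_tab$k, , drop = FALSE] - coords[angle_tab$j, , drop = FALSE]
      lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
      uh <- u / lu; vh <- v / lv
      ct <- pmax(-1, pmin(1, rowSums(uh * vh)))
      ct0 <- cos(deg2rad(angle_tab$theta0))
      # cosine-harmonic: V = kc (cos th - cos th0)^2 with curvature k at
      # th0; torque is bounded and vanishes at the linear limit
      kc <- params$angle$k / (2 * sin(deg2rad(angle_tab$theta0))^2)
      e <- e + sum(kc * (ct - ct0)^2)
      pref <- 2 * kc * (ct - ct0)      # dV/d(cos th)
      gi <- (vh - ct * uh) / lu * pref
      gk <- (uh - ct * vh) / lv * pref
      g <- acc_rows(g, angle_tab$i, gi)
      g <- acc_rows(g, angle_tab$k, gk)
      g <- acc_rows(g, angle_tab$j, -(gi + gk))
    }

    ## torsions
    if (nrow(torsion_tab)) {
      tt <- torsion_tab
      b1 <- coords[tt$j, , drop = FALSE] - coords[tt$i, , drop = FALSE]
      b2 <- coords[tt$k, , drop = FALSE] - coords[tt$j, , drop = FALSE]
      b3 <- coords[tt$l, , drop = FALSE] - coords[tt$k, , drop = FALSE]
      n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
      lb2 <- sqrt(rowSums(b2^2))
      m1 <- rowcross(n1, b2 / lb2)
      phi <- atan2(rowSums(m1 * n2), rowSums(n1 * n2))
      k3 <- params$torsion$k3
      kr2 <- params$ring_profile$k2 * tt$ring_w
      kr3 <- params$ring_profile$k3 * tt$ring_w
      e <- e + sum(k3 * (1 + cos(3 * phi)) +
                     kr2 * (1 + cos(2 * phi)) +
                     kr3 * (1 + cos(3 * phi)))
      dEdphi <- -3 * (k3 + kr3) * sin(3 * phi) - 2 * kr2 * sin(2 * phi)
      s1 <- rowSums(n1^2); s2 <- rowSums(n2^2)
      gi <- n1 * (lb2 / s1)
      gl <- -n2 * (lb2 / s2)
      c12 <- rowSums(b1 * b2) / lb2^2
      c32 <- rowSums(b3 * b2) / lb2^2
      gj <- -gi * (1 + c12) + gl * c32
      gk <- gi * c12 - gl * (1 + c32)
      g <- acc_rows(g, tt$i, gi * dEdphi)
      g <- acc_rows(g, tt$j, gj * dEdphi)
      g <- acc_rows(g, tt$k, gk * dEdphi)
      g <- acc_rows(g, tt$l, gl * dEdphi)
    }

    ## nonbonded soft repulsion
    d <- as.matrix(stats::dist(coords))
    sig <- matrix(np$sigma_XX, n, n)
    hh <- sig_class == "H"
    sig[hh, ] <- np$sigma_XH; sig[, hh] <- np$sigma_XH
    sig[hh, hh] <- np$sigma_HH
    act <- which(upper.tri(d) & d < sig & !excl, arr.ind = TRUE)
    if (nrow(act)) {
      rr <- d[act]; ss <- sig[act]
      e <- e + sum(np$eps * (1 - rr / ss)^2)
      dEdr <- -2 * np$eps * (1 - rr / ss) / ss
      dv <- coords[act[, 1], , drop = FALSE] - coords[act[, 2], , drop = FALSE]
      gv <- dv * (dEdr / rr)
      g <- acc_rows(g, act[, 1], gv)
      g <- acc_rows(g, act[, 2], -gv)
    }

    list(energy = e, gradient = g * bohr)   # Hartree/Bohr
  }
  class(model) <- "energy_model"
  model
}

# scatter-add rows of `val` into `g` at (possibly repeated) indices
acc_rows <- function(g, idx, val) {
  s <- rowsum(val, idx)
  at <- as.integer(rownames(s))
  g[at, ] <- g[at, , drop = FALSE] + s
  g
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

neighbors_list <- function(b, n) {
  out <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    out[[b$i[k]]] <- c(out[[b$i[k]]], b$j[k])
    out[[b$j[k]]] <- c(out[[b$j[k]]], b$i[k])
  }
  out
}

# logical matrix: TRUE for pairs within `depth` bonds (or identical)
pairs_within_bonds <- function(b, n, depth) {
  adj <- matrix(FALSE, n, n)
  adj[cbind(b$i, b$j)] <- TRUE
  adj <- adj | t(adj)
  reach <- adj | diag(TRUE, n)
  cur <- adj
  for (d in seq_len(depth - 1)) {
    cur <- (cur %*% adj) > 0
    reach <- reach | cur
  }
  reach
}

#' Build a bespoke harmonic-spring model
#'
#' Minimal analytic backend (bonds only) used as a closed-form oracle:
#' a dimer with one spring has its minimum at `r0` and, under a pulling
#' force f, at `r0 + f/k` exactly.
#'
#' @param bonds Data frame with columns `i`, `j`, `k` (Hartree/A^2) and
#'   `r0` (Angstrom).
#' @param n Number of atoms.
#' @return An `"energy_model"`.
#' @export
spring_model <- function(bonds, n) {
  bonds <- as.data.frame(bonds)
  bohr <- ego_constants[["bohr_A"]]
  model <- list(bond_tab = bonds, n_atoms = n,
                reference_lengths = bonds$r0)
  model$evaluate <- function(coords) {
    coords <- as.matrix(coords)
    dv <- coords[bonds$i, , drop = FALSE] - coords[bonds$j, , drop = FALSE]
    dl <- sqrt(rowSums(dv^2))
    e <- sum(0.5 * bonds$k * (dl - bonds$r0)^2)
    f <- bonds$k * (dl - bonds$r0) / dl
    g <- matrix(0, n, 3)
    g <- acc_rows(g, bonds$i, dv * f)
    g <- acc_rows(g, bonds$j, -dv * f)
    list(energy = e, gradient = g * bohr)
  }
  class(model) <- "energy_model"
  model
}

#' Check a model gradient against central finite differences
#'
#' Central differences of the energy at the given coordinates, compared
#' component-wise with the analytic gradient.
#'
#' @param model An `"energy_model"`.
#' @param coords Coordinate matrix (Angstrom).
#' @param step Finite-difference step in Angstrom (> 0).
#' @param tol Pass threshold on the maximum absolute deviation
#'   (Hartree/Bohr).
#' @return List: `max_deviation`, `pass`, `step`, `tol`.
#' @export
check_gradient_fd <- function(model, coords, step = 1e-4, tol = 1e-6) {
  stopifnot(step > 0)
  coords <- as.matrix(coords)
  ev <- model$evaluate(coords)
  if (!is.finite(ev$energy)) stop("non-finite energy at probe coordinates")
  bohr <- ego_constants[["bohr_A"]]
  num <- matrix(0, nrow(coords), 3)
  for (a in seq_len(nrow(coords))) for (c3 in 1:3) {
    xp <- coords; xp[a, c3] <- xp[a, c3] + step
    xm <- coords; xm[a, c3] <- xm[a, c3] - step
    ep <- model$evaluate(xp)$energy
    em <- model$evaluate(xm)$energy
    if (!is.finite(ep) || !is.finite(em))
      stop("non-finite energy at displaced probe")
    num[a, c3] <- (ep - em) / (2 * step) * bohr   # Hartree/Bohr
  }
  dev <- max(abs(num - ev$gradient))
  list(max_deviation = dev, pass = dev <= tol, step = step, tol = tol)
}
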