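## Enforced Geometry Optimization: minimization of the force-modified
## energy E_eff(x) = E(x) - f * d(x), where d is the distance between the
## two anchor atoms and f the constant pulling force (Hartree/Bohr).
## Quasi-Newton (BFGS) descent with a backtracking line search in
## Cartesian coordinates, per-cycle trace, bond-rupture logging, and
## numerical vibrational analysis of stationary points.

#' Specify a constant pulling force pair
#'
#' @param atom_i,atom_j Indices of the two anchor atoms (distinct).
#' @param f Force magnitude in au (Hartree/Bohr), >= 0.  The pair pulls
#'   the anchors apart along their connecting line.
#' @return List of class `"pull_spec"`.
#' @export
pull_spec <- function(atom_i, atom_j, f) {
  stopifnot(atom_i != atom_j, f >= 0)
  structure(list(atom_i = as.integer(atom_i), atom_j = as.integer(atom_j),
                 f = as.numeric(f)), class = "pull_spec")
}

#' Options for the EGO optimizer
#'
#' Convergence follows the usual compliance criteria of quantum-chemistry
#' optimizers: maximum and RMS effective-gradient components, energy
#' change and maximum atomic displacement between accepted cycles must all
#' fall below their thresholds.
#'
#' @param max_cycles Maximum accepted optimization cycles (>= 1).
#' @param tol_grad_max Threshold on the largest absolute component of the
#'   effective gradient (Hartree/Bohr).
#' @param tol_grad_rms Threshold on the RMS effective gradient
#'   (Hartree/Bohr).
#' @param tol_energy_change Threshold on |delta E_eff| (Hartree).
#' @param tol_displacement Threshold on the largest atom displacement per
#'   cycle (Angstrom).
#' @param rupture_factor A bonded pair exceeding this multiple of its
#'   reference length triggers a rupture event.
#' @param max_step Largest allowed atom displacement per cycle (Angstrom);
#'   step-control for the line search.
#' @param store_trajectory Keep per-cycle coordinate frames.
#' @return List of class `"ego_options"`.
#' @export
ego_options <- function(max_cycles = 2000L, tol_grad_max = 4.5e-4,
                        tol_grad_rms = 3e-4, tol_energy_change = 1e-6,
                        tol_displacement = 1.8e-3, rupture_factor = 2.0,
                        max_step = 0.3, store_trajectory = TRUE) {
  stopifnot(max_cycles >= 1, tol_grad_max > 0, tol_grad_rms > 0,
            tol_energy_change > 0, tol_displacement > 0, rupture_factor > 1,
            max_step > 0)
  structure(as.list(environment()), class = "ego_options")
}

#' External force vectors of a pulling pair
#'
#' +f on atom i and -f on atom j along the unit vector from j to i
#' (pulling the two apart); zero on every other atom.  The pair is equal,
#' opposite and collinear, so it exerts no net force and no net torque.
#'
#' @param coords Coordinate matrix (Angstrom).
#' @param pull A [pull_spec()].
#' @return Matrix of per-atom force vectors (Hartree/Bohr).
#' @export
external_force_vectors <- function(coords, pull) {
  coords <- as.matrix(coords)
  F <- matrix(0, nrow(coords), 3)
  if (pull$f == 0) return(F)
  u <- coords[pull$atom_i, ] - coords[pull$atom_j, ]
  du <- vnorm(u)
  if (du < 1e-6) stop("anchor atoms are coincident")
  u <- u / du
  F[pull$atom_i, ] <- pull$f * u
  F[pull$atom_j, ] <- -pull$f * u
  F
}

#' Gradient of the force-modified energy
#'
#' The gradient of `E_eff(x) = E(x) - f * d(x)` is the model gradient
#' minus the external force vectors (all Hartree/Bohr).
#'
#' @param model_gradient Per-atom model gradient matrix (Hartree/Bohr).
#' @param coords Coordinate matrix (Angstrom).
#' @param pull A [pull_spec()].
#' @return Modified gradient matrix (Hartree/Bohr).
#' @export
effective_gradient <- function(model_gradient, coords, pull) {
  model_gradient <- as.matrix(model_gradient)
  if (!all(dim(model_gradient) == dim(as.matrix(coords))))
    stop("gradient and coordinate shapes differ")
  model_gradient - external_force_vectors(coords, pull)
}

# effective energy in Hartree: pull distance converted to Bohr
effective_energy <- function(energy, coords, pull) {
  if (pull$f == 0) return(energy)
  d <- vnorm(coords[pull$atom_i, ] - coords[pull$atom_j, ])
  energy - pull$f * d / ego_constants[["bohr_A"]]
}

#' Enforced geometry optimization
#'
#' Minimizes the force-modified energy by BFGS with a backtracking
#' (Armijo) line search; every accepted cycle is recorded in the trace
#' (backbone energy E, effective energy E_eff, anchor distance d, max
#' effective-gradient component).  Bonded pairs stretching past
#' `rupture_factor` times their reference length are logged as rupture
#' events; the optimization continues.
#'
#' @param mol A [molecule()] (starting structure).
#' @param model An `"energy_model"`.
#' @param pull A [pull_spec()]; use `f = 0` for plain minimization.
#' @param opts An [ego_options()].
#' @return Object of class `"ego_result"`: `mol` (final structure),
#'   `trace` (data frame: cycle, E, E_eff, d, grad_max), `converged`,
#'   `rupture_events` (data frame: i, j, cycle, length), `frames`
#'   (list of coordinate matrices if stored), `pull`, `cycles`.
#' @export
optimize_enforced <- function(mol, model, pull, opts = ego_options()) {
  x <- mol$coords
  n <- nrow(x)
  bohr <- ego_constants[["bohr_A"]]
  ref_len <- model$reference_lengths
  bond_i <- model$bond_tab$i; bond_j <- model$bond_tab$j

  eval_eff <- function(x) {
    ev <- model$evaluate(x)
    if (!is.finite(ev$energy)) return(NULL)
    geff <- effective_gradient(ev$gradient, x, pull)
    list(E = ev$energy, E_eff = effective_energy(ev$energy, x, pull),
         g = geff)
  }
  cur <- eval_eff(x)
  if (is.null(cur))
    stop("non-finite energy at the starting structure")

  trace <- vector("list", opts$max_cycles + 1L)
  frames <- if (opts$store_trajectory) vector("list", opts$max_cycles + 1L)
  ruptured <- character(0)
  rupture_events <- list()
  d_of <- function(x) vnorm(x[pull$atom_i, ] - x[pull$atom_j, ])
  record <- function(cyc, x, cur) {
    trace[[cyc + 1L]] <<- data.frame(
      cycle = cyc + 1L, E = cur$E, E_eff = cur$E_eff, d = d_of(x),
      grad_max = max(abs(cur$g)))
    if (opts$store_trajectory) frames[[cyc + 1L]] <<- x
    if (length(bond_i)) {
      bl <- sqrt(rowSums((x[bond_i, , drop = FALSE] -
                            x[bond_j, , drop = FALSE])^2))
      broke <- which(bl > opts$rupture_factor * ref_len)
      for (b in broke) {
        key <- paste(bond_i[b], bond_j[b])
        if (!key %in% ruptured) {
          ruptured <<- c(ruptured, key)
          rupture_events[[length(rupture_events) + 1L]] <<- data.frame(
            i = bond_i[b], j = bond_j[b], cycle = cyc + 1L, length = bl[b])
        }
      }
    }
  }
  record(0L, x, cur)

  # BFGS in flattened Angstrom coordinates; gradients converted to
  # Hartree/Angstrom for consistent descent geometry
  gA <- function(cur) as.numeric(cur$g) / bohr
  H <- diag(3 * n)                      # inverse-Hessian approximation
  g_prev <- gA(cur); x_prev <- as.numeric(x)
  converged <- FALSE
  cycles <- 0L
  aborted <- FALSE
  for (cyc in seq_len(opts$max_cycles)) {
    p <- -as.numeric(H %*% g_prev)
    if (sum(p * g_prev) >= 0) {         # not a descent direction: reset
      H <- diag(3 * n)
      p <- -g_prev
    }
    # step control: cap the largest atom displacement
    pm <- matrix(p, n, 3)
    pmax_atom <- max(sqrt(rowSums(pm^2)))
    alpha0 <- if (pmax_atom > opts$max_step) opts$max_step / pmax_atom else 1
    alpha <- alpha0
    accepted <- NULL
    slope <- sum(p * g_prev)
    for (ls in 1:30) {
      x_try <- matrix(x_prev + alpha * p, n, 3)
      trial <- eval_eff(x_try)
      if (is.null(trial)) { aborted <- TRUE; break }
      if (trial$E_eff <= cur$E_eff + 1e-4 * alpha * slope) {
        accepted <- trial; break
      }
      alpha <- alpha / 2
    }
    if (aborted || is.null(accepted)) break
    x_new <- x_prev + alpha * p
    s <- x_new - x_prev
    y <- gA(accepted) - g_prev
    sy <- sum(s * y)
    if (sy > 1e-12) {
      rho <- 1 / sy
      Hy <- H %*% y
      H <- H - rho * (outer(s, as.numeric(Hy)) + outer(as.numeric(Hy), s)) +
        rho^2 * sum(y * Hy) * outer(s, s) + rho * outer(s, s)
    }
    cycles <- cyc
    disp_max <- max(sqrt(rowSums(matrix(s, n, 3)^2)))
    dE <- abs(accepted$E_eff - cur$E_eff)
    cur <- accepted
    x <- matrix(x_new, n, 3)
    record(cyc, x, cur)
    g_prev <- gA(cur); x_prev <- x_new
    if (max(abs(cur$g)) <= opts$tol_grad_max &&
        sqrt(mean(cur$g^2)) <= opts$tol_grad_rms &&
        dE <= opts$tol_energy_change &&
        disp_max <= opts$tol_displacement) {
      converged <- TRUE
      break
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
  out_mol <- mol
  out_mol$coords <- x
  res <- structure(list(
    mol = out_mol,
    trace = trace,
    converged = converged,
    aborted = aborted,
    rupture_events = if (length(rupture_events))
      do.call(rbind, rupture_events)
    else data.frame(i = integer(0), j = integer(0), cycle = integer(0),
                    length = numeric(0)),
    frames = if (opts$store_trajectory)
      frames[!vapply(frames, is.null, TRUE)],
    pull = pull, cycles = cycles), class = "ego_result")
  if (aborted)
    stop(structure(class = c("ego_nonfinite", "error", "condition"),
                   list(message = "non-finite energy during optimization",
                        call = sys.call(-1), result = res)))
  res
}

#' @export
print.ego_result <- function(x, ...) {
  cat(sprintf(
    "<ego_result> f = %.4f au, %d cycles, %s, E = %.6f Ha, d = %.3f A\n",
    x$pull$f, x$cycles, if (x$converged) "converged" else "NOT converged",
    utils::tail(x$trace$E, 1), utils::tail(x$trace$d, 1)))
  if (nrow(x$rupture_events))
    cat(sprintf("  %d rupture event(s), first at cycle %d\n",
                nrow(x$rupture_events), x$rupture_events$cycle[1]))
  invisible(x)
}

#' Relax a structure (zero-force re-optimization)
#'
#' Re-optimizes with the external force removed; used after every
#' enforced optimization to test whether a conformational change is
#' permanent.
#'
#' @inheritParams optimize_enforced
#' @param pull Optional [pull_spec()] naming the anchors (its `f` is
#'   ignored); defaults to atoms 1 and 2 purely for distance bookkeeping.
#' @return An `"ego_result"`.
#' @export
relax <- function(mol, model, opts = ego_options(), pull = NULL) {
  anchors <- if (is.null(pull)) c(1L, 2L) else c(pull$atom_i, pull$atom_j)
  optimize_enforced(mol, model, pull_spec(anchors[1], anchors[2], 0), opts)
}

#' Vibrational stability analysis
#'
#' Numerical mass-weighted Hessian (central differences of the analytic
#' gradient), projection of the rigid-body translations/rotations, and
#' harmonic frequencies of the remaining modes.  Negative eigenvalues are
#' reported as negative frequencies (imaginary modes).
#'
#' @param mol A [molecule()] at a converged stationary point.
#' @param model An `"energy_model"`.
#' @param step Hessian displacement step (Angstrom).
#' @param grad_tol Largest allowed gradient component (Hartree/Bohr) for
#'   the structure to count as stationary.
#' @param zero_tol Mass-weighted eigenvalues below this magnitude count as
#'   rigid-body modes (atomic units).
#' @return List of class `"stability_report"`: `nu_min` (cm^-1, lowest
#'   nontrivial), `n_negative`, `frequencies` (all nontrivial, cm^-1),
#'   `n_rigid_modes`.
#' @export
vibrational_stability <- function(mol, model, step = 1e-3,
                                  grad_tol = 1e-3, zero_tol = 1e-8) {
  x <- mol$coords
  n <- nrow(x)
  ev <- model$evaluate(x)
  if (max(abs(ev$gradient)) > grad_tol)
    stop(sprintf(
      "not at a stationary point: max gradient %.2e au exceeds %.2e",
      max(abs(ev$gradient)), grad_tol))
  bohr <- ego_constants[["bohr_A"]]
  step_bohr <- step / bohr
  H <- matrix(0, 3 * n, 3 * n)
  for (a in seq_len(n)) for (c3 in 1:3) {
    xp <- x; xp[a, c3] <- xp[a, c3] + step
    xm <- x; xm[a, c3] <- xm[a, c3] - step
    col <- (as.numeric(t(model$evaluate(xp)$gradient)) -
              as.numeric(t(model$evaluate(xm)$gradient))) / (2 * step_bohr)
    H[, (a - 1) * 3 + c3] <- col
  }
  H <- (H + t(H)) / 2
  m_amu <- .atomic_masses[mol$elements]
  m_me <- rep(m_amu, each = 3) * ego_constants[["amu_me"]]
  Hmw <- H / sqrt(outer(m_me, m_me))
  # rigid-body basis (mass-weighted translations and rotations about the
  # centre of mass)
  com <- colSums(x * m_amu) / sum(m_amu)
  xc <- sweep(x, 2, com)
  B <- matrix(0, 3 * n, 6)
  sq <- sqrt(rep(m_amu, each = 3))
  idx <- function(mat) as.numeric(t(mat))
  B[, 1] <- idx(cbind(1, 0, 0)[rep(1, n), ]) * sq
  B[, 2] <- idx(cbind(0, 1, 0)[rep(1, n), ]) * sq
  B[, 3] <- idx(cbind(0, 0, 1)[rep(1, n), ]) * sq
  B[, 4] <- idx(cbind(0, -xc[, 3], xc[, 2])) * sq
  B[, 5] <- idx(cbind(xc[, 3], 0, -xc[, 1])) * sq
  B[, 6] <- idx(cbind(-xc[, 2], xc[, 1], 0)) * sq
  qrB <- qr(B)
  n_rigid <- qrB$rank                     # 5 for linear molecules
  Qfull <- qr.Q(qrB, complete = TRUE)
  P <- Qfull[, (n_rigid + 1):(3 * n), drop = FALSE]
  Hp <- t(P) %*% Hmw %*% P
  lam <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  freq <- ifelse(lam >= 0, sqrt(pmax(lam, 0)), -sqrt(-lam)) *
    ego_constants[["hartree_cm1"]]
  freq <- sort(freq)
  structure(list(nu_min = freq[1],
                 n_negative = sum(lam < -zero_tol),
                 frequencies = freq,
                 n_rigid_modes = n_rigid),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report> nu_min = %.2f cm^-1, %d negative mode(s), %d rigid modes\n",
    x$nu_min, x$n_negative, x$n_rigid_modes))
  invisible(x)
}
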