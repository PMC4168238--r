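# Shared fixtures, built once per test run.

# chair monomer + toy model + zero-force reference (used across files)
mono <- build_galacturonic_monomer("4C1")
mono_model <- toy_ff_build(mono$mol, mono$topo)
mono_pull <- function(f) pull_spec(mono$topo$anchors[["O4a"]],
                                   mono$topo$anchors[["O1a"]], f)
mono_ref <- relax(mono$mol, mono_model, ego_options(), mono_pull(0))

# spring dimer: one harmonic bond, closed-form behaviour
spring_k <- 0.5
spring_r0 <- 1.5
spring <- spring_model(data.frame(i = 1, j = 2, k = spring_k, r0 = spring_r0),
                       n = 2)
spring_mol <- molecule(c("O", "O"),
                       matrix(c(0, 0, 0, 1.2, 0.3, 0), 2, 3, byrow = TRUE),
                       bonds = data.frame(i = 1, j = 2, order = 1))

# quartic double-well in the interatomic distance: V = A ((r-c)^2 - w^2)^2.
# Wells at r = c -/+ w; the lower-well barrier vanishes at the analytic
# tipping force f* = bohr * 8 A w^3 / (3 sqrt(3)) (au).
double_well_model <- function(A = 2.0, c0 = 2.0, w = 0.4) {
  bohr <- ego_constants[["bohr_A"]]
  m <- list(bond_tab = data.frame(i = 1, j = 2),
            reference_lengths = c0 - w, n_atoms = 2)
  m$evaluate <- function(coords) {
    dv <- coords[1, ] - coords[2, ]
    r <- sqrt(sum(dv^2))
    s <- r - c0
    e <- A * (s^2 - w^2)^2
    dEdr <- 4 * A * s * (s^2 - w^2)
    g <- rbind(dv / r * dEdr, -dv / r * dEdr)
    list(energy = e, gradient = g * bohr)
  }
  class(m) <- "energy_model"
  m
}
double_well_fstar <- function(A = 2.0, w = 0.4)
  ego_constants[["bohr_A"]] * 8 * A * w^3 / (3 * sqrt(3))

expect_coords_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a - b)), tol)
}

random_rotation <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  egopull:::rotation_about_axis(ax, stats::runif(1, 0, 2 * pi))
}
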