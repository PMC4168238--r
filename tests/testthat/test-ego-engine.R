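# EGO engine: force vectors, effective gradient, optimizer, relaxation,
# rupture and vibrational analysis.

test_that("external force pairs are equal, opposite, collinear", {
  x <- rbind(c(0, 0, 0), c(3, 0, 0), c(1, 1, 0))
  F0 <- external_force_vectors(x, pull_spec(1, 2, 0))
  expect_true(all(F0 == 0))
  F <- external_force_vectors(x, pull_spec(1, 2, 0.05))
  expect_equal(F[1, ], c(-0.05, 0, 0))
  expect_equal(F[2, ], c(0.05, 0, 0))
  expect_equal(F[3, ], c(0, 0, 0))
  # net force and net torque about an arbitrary point vanish
  x2 <- matrix(rnorm(9), 3, 3)
  F2 <- external_force_vectors(x2, pull_spec(1, 3, 0.07))
  expect_lt(max(abs(colSums(F2))), 1e-10)
  origin <- c(2, -5, 1)
  tq <- Reduce(`+`, lapply(1:3, function(a)
    egopull:::pracma_cross(x2[a, ] - origin, F2[a, ])))
  expect_lt(max(abs(tq)), 1e-10)
  xc <- rbind(c(0, 0, 0), c(1e-8, 0, 0))
  expect_error(external_force_vectors(xc, pull_spec(1, 2, 0.1)),
               "coincident")
})

test_that("effective gradient is the gradient of E - f*d", {
  x <- mono$mol$coords
  g <- mono_model$evaluate(x)$gradient
  expect_identical(effective_gradient(g, x, mono_pull(0)), g)
  # doubling f doubles the external term exactly
  g1 <- effective_gradient(g, x, mono_pull(0.03)) - g
  g2 <- effective_gradient(g, x, mono_pull(0.06)) - g
  expect_equal(g2, 2 * g1, tolerance = 1e-14)
  # matches central differences of E_eff to 1e-6 on random probes
  pull <- mono_pull(0.04)
  bohr <- ego_constants[["bohr_A"]]
  E_eff <- function(x) egopull:::effective_energy(
    mono_model$evaluate(x)$energy, x, pull)
  set.seed(21)
  h <- 1e-4
  for (probe in 1:20) {
    a <- sample(23, 1); c3 <- sample(3, 1)
    xp <- x; xp[a, c3] <- xp[a, c3] + h
    xm <- x; xm[a, c3] <- xm[a, c3] - h
    num <- (E_eff(xp) - E_eff(xm)) / (2 * h) * bohr
    ana <- effective_gradient(mono_model$evaluate(x)$gradient, x,
                              pull)[a, c3]
    expect_lt(abs(num - ana), 1e-6)
  }
})

test_that("spring dimer under pull converges to the analytic minimum", {
  f <- 0.05
  res <- optimize_enforced(spring_mol, spring, pull_spec(1, 2, f),
                           ego_options())
  d_expect <- spring_r0 + f / (spring_k * ego_constants[["bohr_A"]])
  expect_true(res$converged)
  expect_equal(utils::tail(res$trace$d, 1), d_expect, tolerance = 1e-6)
  # relax returns to r0
  back <- relax(res$mol, spring, ego_options(), pull_spec(1, 2, 0))
  expect_equal(utils::tail(back$trace$d, 1), spring_r0, tolerance = 1e-6)
})

test_that("zero-force optimization only ever lowers the energy", {
  start <- perturb_molecule(mono$mol, 0.05, seed = 9)
  res <- relax(start, mono_model, ego_options(), mono_pull(0))
  expect_lte(utils::tail(res$trace$E, 1), res$trace$E[1])
  # E_eff non-increasing along every accepted cycle
  expect_true(all(diff(res$trace$E_eff) <= 1e-12))
})

test_that("relaxing an already-relaxed structure is a no-op", {
  again <- relax(mono_ref$mol, mono_model, ego_options(), mono_pull(0))
  expect_lt(abs(utils::tail(again$trace$E, 1) -
                  utils::tail(mono_ref$trace$E, 1)), 1e-6)
  expect_identical(ring_report(again$mol, mono$topo)$label, "4C1")
})

test_that("optimization is deterministic", {
  r1 <- optimize_enforced(mono_ref$mol, mono_model, mono_pull(0.03),
                          ego_options())
  r2 <- optimize_enforced(mono_ref$mol, mono_model, mono_pull(0.03),
                          ego_options())
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$mol$coords, r2$mol$coords)
})

test_that("converged E_eff matches a dense grid search (small systems)", {
  # 1 dof: quartic double-well under sub-threshold pull
  dw <- double_well_model()
  mol2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                   bonds = data.frame(i = 1, j = 2, order = 1))
  f <- 0.05
  res <- optimize_enforced(mol2, dw, pull_spec(1, 2, f), ego_options())
  bohr <- ego_constants[["bohr_A"]]
  grid <- seq(1.2, 2.0, by = 1e-4)   # the basin the start occupies
  A <- 2.0; c0 <- 2.0; w <- 0.4
  Egrid <- A * ((grid - c0)^2 - w^2)^2 - f * grid / bohr
  expect_lt(abs(utils::tail(res$trace$E_eff, 1) - min(Egrid)), 1e-4)

  # 2 dof: two springs in series pulled at the ends
  chain <- molecule(c("C", "C", "C"),
                    rbind(c(0, 0, 0), c(1.4, 0.4, 0), c(2.6, -0.2, 0)),
                    bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1))
  two <- spring_model(data.frame(i = c(1, 2), j = c(2, 3),
                                 k = c(0.4, 0.6), r0 = c(1.5, 1.3)), 3)
  res2 <- optimize_enforced(chain, two, pull_spec(1, 3, 0.04), ego_options())
  r1g <- seq(1.5, 2.0, by = 2e-4); r2g <- seq(1.3, 1.8, by = 2e-4)
  Eg <- outer(r1g, r2g, function(a, b)
    0.5 * 0.4 * (a - 1.5)^2 + 0.5 * 0.6 * (b - 1.3)^2 -
      0.04 * (a + b) / bohr)
  expect_lt(abs(utils::tail(res2$trace$E_eff, 1) - min(Eg)), 1e-4)
})

test_that("forces far above the ladder maximum rupture anchor bonds", {
  huge <- tryCatch(
    optimize_enforced(mono_ref$mol, mono_model, mono_pull(0.15),
                      ego_options(max_cycles = 400)),
    ego_nonfinite = function(e) e$result)
  expect_gt(nrow(huge$rupture_events), 0)
  lbl <- mono$mol$labels
  broken <- paste0(lbl[as.character(huge$rupture_events$i)], "-",
                   lbl[as.character(huge$rupture_events$j)])
  expect_true(any(broken %in% c("C1-O1", "C4-O4", "O1-C1", "O4-C4")))
})

test_that("vibrational analysis: spring frequency is exact, chair is stable", {
  res <- relax(spring_mol, spring, ego_options(), pull_spec(1, 2, 0))
  st <- vibrational_stability(res$mol, spring)
  mu <- egopull:::.atomic_masses[["O"]] / 2 * ego_constants[["amu_me"]]
  nu_expect <- sqrt(spring_k * ego_constants[["bohr_A"]]^2 / mu) *
    ego_constants[["hartree_cm1"]]
  expect_equal(st$nu_min, nu_expect, tolerance = 1e-3)
  expect_equal(st$n_rigid_modes, 5)    # linear molecule
  expect_equal(st$n_negative, 0)

  st2 <- vibrational_stability(mono_ref$mol, mono_model)
  expect_equal(st2$n_rigid_modes, 6)
  expect_equal(st2$n_negative, 0)

  off <- perturb_molecule(mono_ref$mol, 0.2, seed = 4)
  expect_error(vibrational_stability(off, mono_model), "stationary")
})
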