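# Stretch-relax protocol: ladders, scans, minimal-force search, labels.
# Toy-backend thresholds used here were established by a brute-force
# pre-scan of the shipped v1 parameters: the monomer chair survives
# pulls up to ~0.055 au and relaxes to the inverted chair above ~0.0575.

test_that("force ladder validates its fields", {
  lad <- force_ladder(0.02, 0.08, 0.005)
  expect_length(lad$forces, 13)
  expect_error(force_ladder(0.08, 0.02), "f_min")
  expect_error(force_ladder(0.02, 0.08, step = -1))
  expect_error(force_ladder(0.02, 0.08, 0.005, refine_resolution = 0.01),
               "refine")
})

test_that("a degenerate ladder produces a single record", {
  lad <- force_ladder(0.03, 0.03 + 1e-12, step = 0.005)
  sc <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  expect_length(sc$records, 1)
  expect_identical(sc$records[[1]]$labels_relaxed, "4C1")
})

test_that("sub-threshold ladder: no permanent change, one region", {
  lad <- force_ladder(0.02, 0.05, 0.015)
  sc <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  expect_true(all(sc$summary$labels_relaxed == "4C1"))
  expect_equal(nrow(sc$regions), 1)
  expect_length(sc$transition_forces, 0)
  expect_true(is.na(sc$rupture_force))
  # stretched length is non-decreasing in force below rupture
  expect_true(all(diff(sc$summary$L_stretched) > -1e-3))
})

test_that("ladder crossing the threshold yields an inverted-chair region", {
  lad <- force_ladder(0.04, 0.07, 0.01)
  sc <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  expect_gte(nrow(sc$regions), 2)
  expect_identical(sc$regions$labels[nrow(sc$regions)], "1C4")
  expect_length(sc$transition_forces, nrow(sc$regions) - 1)
  # regions partition the scanned range
  expect_equal(sc$regions$f_lo[1], 0.04)
  expect_equal(sc$regions$f_hi[nrow(sc$regions)], 0.07)
})

test_that("scan results are deterministic", {
  lad <- force_ladder(0.05, 0.06, 0.01)
  s1 <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  s2 <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  expect_identical(s1$summary, s2$summary)
})

test_that("minimal transition force: analytic two-state system", {
  dw <- double_well_model()
  mol2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                   bonds = data.frame(i = 1, j = 2, order = 1))
  fstar <- double_well_fstar()            # ~0.1043 au, closed form
  lad <- force_ladder(0.06, 0.14, 0.02, refine_resolution = 5e-4)
  # conservative step control so descent resolves the vanishing barrier
  res <- find_minimal_transition_force(
    mol2, list(anchors = c(O4a = 1L, O1a = 2L)), dw, lad,
    opts = ego_options(max_step = 0.05),
    transition_test = function(m) sqrt(sum((m$coords[1, ] -
                                              m$coords[2, ])^2)) > 2.0)
  expect_identical(res$status, "ok")
  expect_lt(abs(res$force - fstar), 5e-4 + 1e-9)
  expect_lte(res$bracket[2] - res$bracket[1], 5e-4 + 1e-12)
  # bracket property: the analytic threshold lies inside the bracket
  expect_gte(fstar, res$bracket[1] - 1e-9)
  expect_lte(fstar, res$bracket[2] + 1e-9)
})

test_that("minimal force search reports absent and unbracketed cases", {
  dw <- double_well_model()
  mol2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                   bonds = data.frame(i = 1, j = 2, order = 1))
  crossed <- function(m) sqrt(sum((m$coords[1, ] - m$coords[2, ])^2)) > 2.0
  below <- find_minimal_transition_force(
    mol2, list(anchors = c(O4a = 1L, O1a = 2L)), dw,
    force_ladder(0.01, 0.05, 0.02), opts = ego_options(max_step = 0.05),
    transition_test = crossed)
  expect_identical(below$status, "absent")
  expect_true(is.na(below$force))
  above <- find_minimal_transition_force(
    mol2, list(anchors = c(O4a = 1L, O1a = 2L)), dw,
    force_ladder(0.12, 0.14, 0.01), opts = ego_options(max_step = 0.05),
    transition_test = crossed)
  expect_identical(above$status, "unbracketed")
  expect_equal(above$bracket[1], 0.12)
})

test_that("refine_resolution equal to the step returns the grid answer", {
  dw <- double_well_model()
  mol2 <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
                   bonds = data.frame(i = 1, j = 2, order = 1))
  lad <- force_ladder(0.06, 0.14, 0.02, refine_resolution = 0.02)
  res <- find_minimal_transition_force(
    mol2, list(anchors = c(O4a = 1L, O1a = 2L)), dw, lad,
    opts = ego_options(max_step = 0.05),
    transition_test = function(m) sqrt(sum((m$coords[1, ] -
                                              m$coords[2, ])^2)) > 2.0)
  expect_identical(res$status, "ok")
  expect_equal(res$bracket, c(0.10, 0.12))
})

test_that("transition labels carry position classes and unit counts", {
  lad <- force_ladder(0.05, 0.06, 0.01)
  sc <- run_stretch_relax_scan(mono$mol, mono$topo, mono_model, lad)
  lt <- label_transitions(sc$records[[1]], mono$topo, sc$reference_labels)
  expect_identical(lt$transition, "none")
  expect_identical(lt$position, "terminal-O4a")
  lt2 <- label_transitions(sc$records[[2]], mono$topo, sc$reference_labels)
  expect_identical(lt2$transition, "4C1->1C4")
  expect_false(lt2$provisional)

  hex <- build_oligomer(6)
  fake <- list(ok = TRUE, labels_relaxed = rep("4C1", 6), converged = TRUE)
  lth <- label_transitions(fake, hex$topo, rep("4C1", 6))
  expect_equal(nrow(lth), 6)
  expect_identical(lth$position,
                   c("terminal-O4a", rep("internal", 4), "terminal-O1a"))
})
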