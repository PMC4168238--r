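# Ring pucker analysis: torsions, Cremer-Pople coordinates, canonical
# classification, torsion decomposition, length bins.

test_that("endocyclic torsions: planar ring zero, chair alternating", {
  flat <- build_ring_from_pucker(Q = 0)
  expect_lt(max(abs(endocyclic_torsions(flat, 1:6))), 1e-9)
  chair <- build_ring_from_pucker(conformer = "4C1")
  tor <- endocyclic_torsions(chair, 1:6)
  expect_true(all(abs(diff(sign(tor))) == 2))        # alternating signs
  # equal magnitudes hold exactly for the equilateral (all-carbon) ring
  eq <- build_ring_from_pucker(Q = 0.6, theta = 0, bond_co = 1.52)
  tor_eq <- endocyclic_torsions(eq, 1:6)
  expect_lt(diff(range(abs(tor_eq))), 1e-6)
})

test_that("rotating the ring start atom permutes torsions cyclically", {
  ring <- build_ring_from_pucker(Q = 0.55, theta = 70, phi = 200)
  t0 <- endocyclic_torsions(ring, 1:6)
  t2 <- endocyclic_torsions(ring, c(3:6, 1:2))
  expect_equal(t2, t0[c(3:6, 1:2)], tolerance = 1e-9)
})

test_that("degenerate collinear geometry errors", {
  m <- molecule(rep("C", 6),
                cbind(seq(0, 5) * 1.5, 0, 0))
  expect_error(endocyclic_torsions(m, 1:6), "collinear")
})

test_that("pucker coordinates round-trip the generator over a grid", {
  for (theta in c(0, 30, 54.7, 90, 125.3, 150, 180)) {
    for (phi in c(0, 60, 137, 240, 330)) {
      for (Q in c(0.45, 0.57, 0.7)) {
        ring <- build_ring_from_pucker(Q = Q, theta = theta, phi = phi)
        st <- puckering_coordinates(ring, 1:6)
        expect_equal(st$Q, Q, tolerance = 1e-6)
        expect_equal(st$theta, theta, tolerance = 1e-6)
        if (theta > 1e-9 && theta < 180 - 1e-9)
          expect_lt(min(abs(st$phi - phi), 360 - abs(st$phi - phi)), 1e-6)
        expect_lt(abs(st$q2^2 + st$q3^2 - st$Q^2), 1e-9)
      }
    }
  }
})

test_that("planar rings are flagged and refuse a conformer label", {
  flat <- build_ring_from_pucker(Q = 0)
  st <- puckering_coordinates(flat, 1:6)
  expect_true(st$planar)
  expect_lt(st$Q, 1e-6)
  expect_error(classify_canonical(st), "planar")
})

test_that("canonical classification hits poles, skews, and breaks ties", {
  expect_identical(classify_canonical(list(theta = 2, phi = 123))$name,
                   "4C1")
  expect_identical(classify_canonical(list(theta = 178, phi = 5))$name,
                   "1C4")
  tab <- canonical_conformers()
  for (nm in c("5S1", "2SO", "OS2", "1,4B")) {
    ideal <- tab[tab$name == nm, ]
    expect_identical(classify_canonical(list(theta = ideal$theta,
                                             phi = ideal$phi))$name, nm)
  }
  # (90, 105) is equidistant from 5S1 (phi 90) and 2,5B (phi 120):
  # deterministic tie-break to the lower ideal phi
  tie <- classify_canonical(list(theta = 90, phi = 105))
  expect_identical(tie$name, "5S1")
  # the 38-conformer table is complete and well-formed
  expect_equal(nrow(tab), 38)
  expect_equal(sum(tab$class == "chair"), 2)
  expect_equal(sum(tab$class == "boat"), 6)
  expect_equal(sum(tab$class == "skew"), 6)
  expect_equal(sum(tab$class == "envelope"), 12)
  expect_equal(sum(tab$class == "half-chair"), 12)
})

test_that("classification is invariant under rigid motion", {
  ring <- build_ring_from_pucker(Q = 0.6, theta = 100, phi = 95)
  st0 <- puckering_coordinates(ring, 1:6)
  R <- random_rotation(31)
  moved <- ring
  moved$coords <- sweep(ring$coords %*% t(R), 2, c(1, 2, 3), "+")
  st1 <- puckering_coordinates(moved, 1:6)
  expect_equal(st1$theta, st0$theta, tolerance = 1e-9)
  expect_equal(st1$phi, st0$phi, tolerance = 1e-9)
  expect_identical(classify_canonical(st1)$name, classify_canonical(st0)$name)
})

test_that("torsion decomposition recovers pure and blended basis vectors", {
  basis <- egopull:::canonical_torsion_basis()
  v_1c4 <- basis["1C4", ]
  d <- decompose_torsions(v_1c4)
  expect_equal(unname(d$coefficients["1C4"]), 1, tolerance = 1e-9)
  expect_lt(max(abs(d$coefficients[c("1,4B", "OS2")])), 1e-9)
  expect_identical(d$closest, "1C4")
  blend <- 0.5 * basis["1C4", ] + 0.5 * basis["1,4B", ]
  d2 <- decompose_torsions(blend)
  expect_equal(unname(d2$coefficients["1C4"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(d2$coefficients["1,4B"]), 0.5, tolerance = 1e-9)
  expect_error(decompose_torsions(c(1, 2, NA, 4, 5, 6)), "finite")
})

test_that("torsion-space and pucker-sphere classification agree", {
  # exact agreement on every ideal conformer
  tab <- canonical_conformers()
  for (k in seq_len(nrow(tab))) {
    ring <- build_ring_from_pucker(Q = 0.6, theta = tab$theta[k],
                                   phi = tab$phi[k])
    expect_identical(
      classify_canonical(puckering_coordinates(ring, 1:6))$name,
      tab$name[k])
    expect_identical(decompose_torsions(endocyclic_torsions(ring, 1:6))$closest,
                     tab$name[k])
  }
  # on 1,000 random rings: full agreement away from label boundaries
  # (margin > 8 deg on the pucker sphere), high agreement overall
  set.seed(42)
  n <- 1000
  agree <- 0; margin_checked <- 0; margin_agree <- 0
  for (k in seq_len(n)) {
    Q <- runif(1, 0.4, 0.7)
    theta <- acos(runif(1, -1, 1)) * 180 / pi
    phi <- runif(1, 0, 360)
    ring <- build_ring_from_pucker(Q = Q, theta = theta, phi = phi)
    st <- puckering_coordinates(ring, 1:6)
    c1 <- classify_canonical(st)$name
    c2 <- decompose_torsions(endocyclic_torsions(ring, 1:6))$closest
    if (c1 == c2) agree <- agree + 1
    d <- sort(egopull:::great_circle_deg(st$theta, st$phi, tab$theta,
                                         tab$phi))
    if (d[2] - d[1] > 8) {
      margin_checked <- margin_checked + 1
      if (c1 == c2) margin_agree <- margin_agree + 1
    }
  }
  expect_identical(margin_agree, margin_checked)
  expect_gt(margin_checked, 300)
  expect_gt(agree / n, 0.8)
})

test_that("length bins reproduce the characteristic centers and ties", {
  expect_identical(label_by_length(4.5), "c")
  expect_identical(label_by_length(5.5), "ic")
  expect_identical(label_by_length(5.1), "b2")
  expect_identical(label_by_length(4.3), "b1")
  expect_identical(label_by_length(4.4), "c")       # tie -> lower energy
  expect_identical(label_by_length(6.5), "unassigned")
  expect_identical(label_by_length(c(4.52, 5.48)), c("c", "ic"))
  expect_error(label_by_length(-1))
})
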