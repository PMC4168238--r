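# Force-extension curves, plateau detection, history landmarks and
# structural traces.

# minimal scan-shaped object from explicit (f, L) pairs
fake_scan <- function(f, L, converged = TRUE) {
  structure(list(records = Map(function(fi, Li, ci)
    list(f = fi, ok = TRUE, converged = ci, L_stretched = Li),
    f, L, rep_len(converged, length(f)))), class = "scan_result")
}

test_that("curve building keeps order and excludes unusable records", {
  sc <- fake_scan(c(0.03, 0.01, 0.02), c(5.3, 5.1, 5.2))
  cv <- build_force_extension_curve(sc)
  expect_equal(cv$points$f, c(0.01, 0.02, 0.03))
  expect_equal(cv$points$L, c(5.1, 5.2, 5.3))
  sc2 <- fake_scan(c(0.01, 0.02, 0.03), c(5.1, 5.2, 5.3),
                   converged = c(TRUE, FALSE, TRUE))
  cv2 <- build_force_extension_curve(sc2)
  expect_equal(cv2$excluded, 0.02)
  expect_equal(nrow(cv2$points), 2)
  expect_error(build_force_extension_curve(fake_scan(0.01, 5)), "fewer")
})

test_that("spring dimer curve is the analytic line with slope 1/k", {
  fs <- seq(0.01, 0.05, by = 0.01)
  Ls <- vapply(fs, function(f) {
    r <- optimize_enforced(spring_mol, spring, pull_spec(1, 2, f),
                           ego_options())
    utils::tail(r$trace$d, 1)
  }, 0)
  cv <- build_force_extension_curve(fake_scan(fs, Ls))
  slope <- coef(lm(L ~ f, cv$points))[["f"]]
  expect_equal(slope, 1 / (spring_k * ego_constants[["bohr_A"]]),
               tolerance = 0.01)
})

test_that("plateau detector: linear empty, steps found in order", {
  lin <- build_force_extension_curve(
    fake_scan(seq(0.02, 0.08, 0.005), 5 + seq(0.02, 0.08, 0.005) * 10))
  expect_equal(nrow(detect_plateaus(lin)$plateaus), 0)

  f <- seq(0.02, 0.08, 0.005)
  L <- 5 + (f - 0.02) * 2          # gentle slope
  L[f >= 0.05] <- L[f >= 0.05] + 1.0   # one 1.0 A jump at 0.05
  one <- detect_plateaus(build_force_extension_curve(fake_scan(f, L)))
  expect_equal(nrow(one$plateaus), 1)
  expect_equal(one$plateaus$f_onset, 0.05)
  expect_equal(one$plateaus$delta_L, 1.0 + 0.005 * 2,
               tolerance = 1e-9)   # jump plus the base slope of the step

  L2 <- 5 + (f - 0.02) * 2
  L2[f >= 0.04] <- L2[f >= 0.04] + 0.8
  L2[f >= 0.065] <- L2[f >= 0.065] + 1.2
  two <- detect_plateaus(build_force_extension_curve(fake_scan(f, L2)))
  expect_equal(nrow(two$plateaus), 2)
  expect_equal(two$plateaus$f_onset, c(0.04, 0.065))
  expect_equal(two$plateaus$delta_L, c(0.81, 1.21), tolerance = 1e-9)
})

test_that("plateau detection is scale-equivariant in extension", {
  f <- seq(0.02, 0.08, 0.005)
  L <- 5 + (f - 0.02) * 2
  L[f >= 0.05] <- L[f >= 0.05] + 1.0
  base <- detect_plateaus(build_force_extension_curve(fake_scan(f, L)))
  scaled <- detect_plateaus(build_force_extension_curve(fake_scan(f, 3 * L)),
                            jump_threshold = 0.3 * 3)
  expect_equal(scaled$plateaus$f_onset, base$plateaus$f_onset)
  expect_equal(scaled$plateaus$delta_L, 3 * base$plateaus$delta_L,
               tolerance = 1e-9)
})

test_that("history landmarks: monotone none, constructed barriers found", {
  mono_trace <- data.frame(cycle = 1:10, E = seq(1, 0.1, length.out = 10))
  lm0 <- find_history_landmarks(mono_trace)
  expect_length(lm0$maxima, 0)
  expect_length(lm0$minima, 0)

  # two barriers, first higher (0.5 then 0.2)
  E <- c(0, 0.2, 0.5, 0.3, 0.1, 0.25, 0.3, 0.2, 0.05, 0.0)
  tr <- data.frame(cycle = 1:10, E = E)
  lm <- find_history_landmarks(tr)
  expect_equal(lm$maxima, c(3, 7))
  expect_equal(lm$minima, 5)
  expect_equal(lm$barriers, c(0.5, 0.2), tolerance = 1e-12)
  expect_true(lm$first_barrier_highest)
  # alternation between extrema
  merged <- sort(c(lm$maxima, lm$minima))
  expect_equal(merged, c(3, 5, 7))

  # smoothing_window = 1 equals raw detection
  expect_identical(find_history_landmarks(tr, smoothing_window = 1)$maxima,
                   lm$maxima)
  expect_error(find_history_landmarks(tr, smoothing_window = 2))
})

test_that("structural trace reproduces the trace distances exactly", {
  s <- optimize_enforced(mono_ref$mol, mono_model, mono_pull(0.04),
                         ego_options())
  st <- structural_trace(s, mono$topo)
  expect_equal(nrow(st), nrow(s$trace))
  expect_lt(max(abs(st$L - s$trace$d)), 1e-9)
  expect_true(all(is.na(st$phi)))      # monomer: no glycosidic linkage
  # constant-geometry dummy trajectory gives constant series
  dummy <- s
  dummy$frames <- rep(list(s$frames[[1]]), 5)
  std <- structural_trace(dummy, mono$topo)
  expect_equal(length(unique(round(std$ring_dihedral, 9))), 1)
  expect_equal(length(unique(round(std$L, 9))), 1)
  no_frames <- s; no_frames$frames <- NULL
  expect_error(structural_trace(no_frames, mono$topo), "frames")
})

test_that("elongation saturates before the ring flips (two-phase course)", {
  s <- optimize_enforced(mono_ref$mol, mono_model, mono_pull(0.065),
                         ego_options(max_cycles = 4000))
  expect_true(s$converged)
  st <- structural_trace(s, mono$topo)
  dL <- st$L - st$L[1]
  cyc_L90 <- which(dL >= 0.9 * utils::tail(dL, 1))[1]
  jumps <- abs(diff(st$ring_dihedral))
  cyc_flip <- which(jumps > 20)[1]
  expect_false(is.na(cyc_flip))        # the ring does flip at this force
  expect_lt(cyc_L90, cyc_flip)         # ...but only after elongation
})
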