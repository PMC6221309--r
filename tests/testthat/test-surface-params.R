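# Analytic oracles and invariance properties of the four texture
# parameters and their supporting constructs.

test_that("Sa matches the analytic value for constant and sinusoidal surfaces", {
  flat <- height_map(matrix(5, 32, 32), dx = 1)
  expect_equal(compute_sa(flat), 0)

  hm <- sinusoid_hm()
  expect_equal(compute_sa(hm), 2 / pi, tolerance = 0.01)

  # translation invariance
  shifted <- height_map(hm$heights + 10, dx = hm$dx)
  expect_equal(compute_sa(shifted), compute_sa(hm))

  # linear scaling of heights
  doubled <- height_map(2 * hm$heights, dx = hm$dx)
  expect_equal(compute_sa(doubled), 2 * compute_sa(hm), tolerance = 1e-12)
})

test_that("ACF is normalized, symmetric, and analytic for a sinusoid", {
  hm <- smooth_noise_hm(64, seed = 2)
  ac <- compute_acf(hm)
  c0 <- which(ac$lag_x == 0)
  r0 <- which(ac$lag_y == 0)
  expect_equal(ac$acf[r0, c0], 1)
  # symmetry under lag negation (even grid: drop the unpaired edge lag)
  core <- ac$acf[2:64, 2:64]
  expect_equal(core, core[63:1, 63:1], tolerance = 1e-10)

  # sinusoid: ACF along x is cos(2 pi tau / lambda); at tau = lambda/4 -> 0
  hs <- sinusoid_hm(n = 256, lambda = 100)
  acs <- compute_acf(hs)
  tau <- acs$lag_x
  along_x <- acs$acf[which(acs$lag_y == 0), ]
  sel <- abs(tau) < 200
  expect_equal(along_x[sel], cos(2 * pi * tau[sel] / 100), tolerance = 1e-6)

  # white noise: off-origin ACF is O(1/sqrt(N))
  hw <- white_noise_hm(128, seed = 3)
  acw <- compute_acf(hw)
  off <- acw$acf
  off[which(acw$lag_y == 0), which(acw$lag_x == 0)] <- 0
  expect_lt(max(abs(off)), 5 / sqrt(128 * 128))

  expect_error(compute_acf(height_map(matrix(1, 8, 8), dx = 1)),
               "zero height variance")
})

test_that("Sal matches analytic values and is scale/rotation invariant", {
  # uncorrelated surface: Sal is one sample spacing
  hw <- white_noise_hm(256, dx = 1.5625, seed = 1)
  expect_equal(compute_sal(hw), 1.5625, tolerance = 1e-12)

  # sinusoid: invert the cosine ACF at the 0.2 threshold
  hs <- sinusoid_hm(n = 512, lambda = 100)
  expect_equal(compute_sal(hs), 100 / (2 * pi) * acos(0.2), tolerance = 0.02)

  hm <- smooth_noise_hm(64, seed = 7)
  # height scaling leaves Sal unchanged; 180 degree rotation too
  scaled <- height_map(3 * hm$heights, dx = hm$dx)
  expect_equal(compute_sal(scaled), compute_sal(hm))
  rot <- height_map(hm$heights[64:1, 64:1], dx = hm$dx)
  expect_equal(compute_sal(rot), compute_sal(hm), tolerance = 1e-10)
  # isotropic sampling: 90 degree rotation with dx = dy
  rot90 <- height_map(t(hm$heights)[64:1, ], dx = hm$dx)
  expect_equal(compute_sal(rot90), compute_sal(hm), tolerance = 1e-10)
})

test_that("material ratio curve has correct endpoints and shape", {
  hm <- smooth_noise_hm(64, seed = 11)
  curve <- compute_material_ratio_curve(hm)
  n <- sum(hm$mask)
  expect_equal(curve$ratios[1], 100 / n)              # only the max itself
  expect_equal(curve$ratios[length(curve$ratios)], 100)
  expect_true(all(diff(curve$ratios) >= 0))

  # uniform height distribution (ramp): the curve is a straight line
  hr <- ramp_hm()
  cr <- compute_material_ratio_curve(hr)
  linear <- 100 * (max(cr$heights) - cr$heights) /
    (max(cr$heights) - min(cr$heights))
  expect_lt(max(abs(cr$ratios - linear)), 100 / 256 + 1e-9)

  # adding a constant shifts the height axis only
  hs <- height_map(hm$heights + 7, dx = hm$dx)
  cs <- compute_material_ratio_curve(hs)
  expect_equal(cs$heights, curve$heights + 7)
  expect_equal(cs$ratios, curve$ratios)
})

test_that("Smr1 oracles: ramp near zero, plateau-and-pit small, translation invariant", {
  hr <- ramp_hm()
  expect_lt(compute_smr1(hr), 0.2)

  # 95 % of the area on a plateau, 5 % in deep pits
  set.seed(9)
  z <- matrix(0, 64, 64)
  pit <- sample(64 * 64, round(0.05 * 64 * 64))
  z[pit] <- -10
  hp <- height_map(z, dx = 1)
  expect_lt(compute_smr1(hp), 5)

  hm <- smooth_noise_hm(64, seed = 12)
  shifted <- height_map(hm$heights + 3, dx = hm$dx)
  expect_equal(compute_smr1(shifted), compute_smr1(hm))

  expect_error(compute_smr1(height_map(matrix(1, 8, 8), dx = 1)),
               "constant surface")
})

test_that("peak detection finds the right peaks and prunes small ripple", {
  # one paraboloid bump on a flat noisy base -> exactly one peak at apex
  hp <- paraboloid_hm()
  pk <- find_significant_peaks(hp)
  expect_length(pk$rows, 1)
  expect_equal(c(pk$rows, pk$cols), c(65, 65))

  # two equal bumps separated by a deep valley -> two peaks
  n <- 129
  xs <- (seq_len(n) - (n + 1) / 2) * 1.5625
  bump <- function(cx) 10 * exp(-((outer(xs, rep(0, n), `+`) - 0)^2 +
                                    (outer(rep(0, n), xs, `+`) - cx)^2) / 500)
  z2 <- bump(-60) + bump(60)
  h2 <- height_map(z2, dx = 1.5625)
  pk2 <- find_significant_peaks(h2)
  expect_length(pk2$rows, 2)

  # tiny ripple (amplitude < 5 % of Sz) on one large bump -> still 1 peak
  ripple <- 0.2 * sin(2 * pi * outer(xs, rep(1, n)) / 20)
  h3 <- height_map(hp$heights + ripple, dx = 1.5625)
  pk3 <- find_significant_peaks(h3)
  expect_length(pk3$rows, 1)
})

test_that("Spc matches the paraboloid curvature and scales linearly", {
  hp <- paraboloid_hm(R = 50)
  pk <- find_significant_peaks(hp)
  expect_equal(compute_spc(hp, pk), 1 / 50, tolerance = 0.02)

  # doubling heights doubles Spc
  h2 <- height_map(2 * hp$heights, dx = hp$dx)
  expect_equal(compute_spc(h2), 2 * compute_spc(hp), tolerance = 1e-10)

  expect_error(
    compute_spc(hp, structure(list(rows = integer(0), cols = integer(0)),
                              class = "peak_set")),
    "no significant peaks")
})

test_that("parameters use measured cells only: light masking barely moves Sa", {
  hm <- smooth_noise_hm(64, seed = 21)
  set.seed(22)
  drop <- sample(64 * 64, round(0.01 * 64 * 64))
  z <- hm$heights
  z[drop] <- NA
  hm2 <- height_map(z, dx = hm$dx)
  expect_lt(abs(compute_sa(hm2) - compute_sa(hm)) / compute_sa(hm), 0.01)
})

test_that("compute_all_params is consistent with the individual operations", {
  hm <- smooth_noise_hm(64, seed = 30)
  pars <- compute_all_params(hm)
  expect_named(pars, c("Sa", "Sal", "Spc", "Smr1"))
  expect_identical(unname(pars["Sa"]), compute_sa(hm))
  expect_identical(unname(pars["Sal"]), as.numeric(compute_sal(hm)))
  expect_identical(unname(pars["Smr1"]), compute_smr1(hm))
  expect_identical(unname(pars["Spc"]), compute_spc(hm))
  # all four parameters strictly positive on a simulated bone surface
  hb <- simulate_base_surface("GS", seed = 5, n_pix = 128)
  expect_true(all(compute_all_params(hb) > 0))
})
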