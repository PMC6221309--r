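# The metrological chain: QC, leveling, mirroring, outlier removal, hole
# filling, S-filter and form removal.

test_that("measured-fraction QC uses an inclusive bound", {
  full <- height_map(matrix(rnorm(16), 4, 4), dx = 1)
  expect_true(qc_measured_fraction(full)$accept)
  expect_equal(qc_measured_fraction(full)$fraction, 1)

  # 512 x 512 grid with 26214 NaNs -> fraction 0.9, rejected at 0.95
  set.seed(1)
  z <- matrix(rnorm(512 * 512), 512, 512)
  z[sample(length(z), 26214)] <- NA
  partial <- height_map(z, dx = 1)
  qc <- qc_measured_fraction(partial)
  expect_equal(qc$fraction, 1 - 26214 / 262144, tolerance = 1e-12)
  expect_false(qc$accept)

  # fraction exactly at the threshold is accepted
  z2 <- matrix(rnorm(400), 20, 20)
  z2[sample(400, 20)] <- NA
  expect_true(qc_measured_fraction(height_map(z2, dx = 1), 0.95)$accept)
})

test_that("least-squares leveling annihilates planes and is idempotent", {
  n <- 64
  xs <- (seq_len(n) - (n + 1) / 2) * 1.5
  plane <- 2 + 3 * outer(rep(1, n), xs) - outer(xs, rep(1, n))
  hm <- height_map(plane, dx = 1.5)
  lv <- level_lsq(hm)
  expect_lt(max(abs(lv$heights)), 1e-9)

  hr <- smooth_noise_hm(64, seed = 3)
  l1 <- level_lsq(hr)
  l2 <- level_lsq(l1)
  expect_equal(l2$heights, l1$heights, tolerance = 1e-10)

  # plane + sinusoid: leveling recovers the Sa of the sinusoid alone
  # (full periods, so the plane fit is unaffected by the oscillation)
  hs <- sinusoid_hm(n = 256, dx = 1, lambda = 64)
  tilt <- 0.5 - 0.03 * outer(rep(1, 256), seq_len(256)) +
    0.02 * outer(seq_len(256), rep(1, 256))
  mixed <- height_map(hs$heights + tilt, dx = 1)
  expect_equal(compute_sa(level_lsq(mixed)), compute_sa(level_lsq(hs)),
               tolerance = 1e-6)
})

test_that("mold mirroring is an involution that preserves roughness", {
  hm <- smooth_noise_hm(32, seed = 5)
  mm <- mirror_mold(hm)
  expect_identical(mirror_mold(mm)$heights, hm$heights)
  expect_equal(compute_sa(mm), compute_sa(hm))
  const <- height_map(matrix(3, 8, 8), dx = 1)
  expect_true(all(mirror_mold(const)$heights == -3))
})

test_that("outlier removal cuts spikes, keeps clean data, respects the hole cap", {
  hm <- smooth_noise_hm(64, seed = 6)
  sq <- osteotex:::compute_sq(hm)
  z <- hm$heights
  z[30, 30] <- z[30, 30] + 100 * sq
  spiked <- height_map(z, dx = hm$dx)
  out <- remove_outliers(spiked)
  expect_false(out$mask[30, 30])
  others <- out$mask
  others[30, 30] <- TRUE
  expect_true(all(others))
  expect_identical(out$heights[out$mask], spiked$heights[out$mask])

  # clean surface passes through unchanged
  clean <- remove_outliers(hm)
  expect_identical(clean$heights[clean$mask], hm$heights[clean$mask])
  expect_true(all(clean$mask))

  # a 300-cell hole is not fillable (cap is < 225 points)
  zh <- hm$heights
  zh[10:24, 10:29] <- NA              # 15 x 20 = 300 contiguous cells
  holed <- remove_outliers(height_map(zh, dx = hm$dx))
  expect_true(all(!holed$meta$fillable[10:24, 10:29]))
  # a small hole is fillable
  zh2 <- hm$heights
  zh2[40:42, 40:42] <- NA
  holed2 <- remove_outliers(height_map(zh2, dx = hm$dx))
  expect_true(all(holed2$meta$fillable[40:42, 40:42]))
})

test_that("hole filling is harmonic: reproduces planes, fills means, identity", {
  # single missing cell surrounded by constant h -> filled with h
  z <- matrix(7, 9, 9)
  z[5, 5] <- NA
  filled <- fill_nonmeasured(height_map(z, dx = 1))
  expect_equal(filled$heights[5, 5], 7, tolerance = 1e-5)
  expect_true(all(filled$mask))

  # interior hole on the plane z = x + 2y is restored exactly
  n <- 21
  plane <- outer(2 * seq_len(n), seq_len(n), `+`)
  zp <- plane
  zp[8:10, 8:10] <- NA
  fp <- fill_nonmeasured(height_map(zp, dx = 1))
  expect_equal(fp$heights[8:10, 8:10], plane[8:10, 8:10], tolerance = 1e-4)

  # nothing to fill -> identity
  hm <- smooth_noise_hm(32, seed = 8)
  expect_identical(fill_nonmeasured(hm)$heights, hm$heights)
})

test_that("S-filter transmission follows the Gaussian cutoff definition", {
  flat <- height_map(matrix(4, 64, 64), dx = 1.5625)
  expect_equal(sfilter_lowpass(flat, 5)$heights, flat$heights,
               tolerance = 1e-9)

  amp_after <- function(lambda, cutoff, n = 512) {
    hm <- sinusoid_hm(n = n, dx = 1.5625, lambda = lambda)
    filt <- sfilter_lowpass(hm, cutoff)
    x <- (seq_len(n) - 1) * 1.5625
    basis <- cbind(sin(2 * pi * x / lambda), cos(2 * pi * x / lambda))
    co <- stats::lm.fit(basis, filt$heights[1, ])$coefficients
    sqrt(sum(co^2))
  }
  # at the cutoff wavelength the amplitude is halved
  expect_equal(amp_after(25, 25), 0.5, tolerance = 0.01)
  # far above the cutoff the surface passes essentially unchanged
  expect_gt(amp_after(100, 5), 0.99)

  expect_error(sfilter_lowpass(smooth_noise_hm(16), 1), "cutoff")
})

test_that("degree-2 form removal annihilates quadratics and is idempotent", {
  n <- 64
  xs <- (seq_len(n) - (n + 1) / 2) * 1.5
  xg <- outer(rep(1, n), xs)
  yg <- outer(xs, rep(1, n))
  quad <- 1 + 0.5 * xg - 0.2 * yg + 0.01 * xg^2 - 0.02 * xg * yg + 0.03 * yg^2
  hq <- height_map(quad, dx = 1.5)
  res <- remove_form_poly2(hq)
  sz <- max(quad) - min(quad)
  expect_lt(max(abs(res$heights)), 1e-9 * sz)

  hm <- smooth_noise_hm(64, seed = 9)
  r1 <- remove_form_poly2(hm)
  r2 <- remove_form_poly2(r1)
  expect_equal(r2$heights, r1$heights, tolerance = 1e-9)

  # residuals orthogonal to all degree-<=2 monomials
  basis <- cbind(1, xg[hm$mask], yg[hm$mask], xg[hm$mask]^2,
                 (xg * yg)[hm$mask], yg[hm$mask]^2)
  ip <- crossprod(basis, r1$heights[hm$mask])
  szr <- max(r1$heights) - min(r1$heights)
  expect_lt(max(abs(ip)) / (sum(hm$mask) * szr), 1e-6)

  # sinusoid + quadratic bowl: residual equals the sinusoid minus its own
  # degree-2 projection (normal-equations oracle)
  hs <- sinusoid_hm(n = 64, dx = 1.5, lambda = 24)
  mix <- height_map(hs$heights + quad, dx = 1.5)
  rmix <- remove_form_poly2(mix)
  beta <- solve(crossprod(basis), crossprod(basis, hs$heights[hm$mask]))
  proj <- matrix(basis %*% beta, n, n)
  expect_equal(rmix$heights, hs$heights - proj, tolerance = 1e-8)
})

test_that("full pipeline: deterministic, refuses bad QC, bone and mold agree", {
  hm <- simulate_base_surface("GS", seed = 31, n_pix = 64)
  cfg <- preprocess_config(sfilter_cutoff_um = 5)
  p1 <- preprocess_pipeline(hm, cfg)
  p2 <- preprocess_pipeline(hm, cfg)
  expect_identical(p1$heights, p2$heights)
  expect_s3_class(p1$meta$stage_log, "data.frame")
  expect_true(all(c("level", "outliers", "fill", "sfilter", "form") %in%
                    p1$meta$stage_log$stage))

  # a perfect (bias- and jitter-free) mold preprocessed as a mold matches
  # the preprocessed bone cell for cell
  mold <- mold_of(hm, spc_bias = 0, jitter_px = 0)
  pm <- preprocess_pipeline(mold, preprocess_config(sfilter_cutoff_um = 5,
                                                    is_mold = TRUE))
  expect_equal(pm$heights, p1$heights, tolerance = 1e-9)

  # QC-rejected input is refused
  zbad <- hm$heights
  zbad[1:40, ] <- NA
  expect_error(preprocess_pipeline(height_map(zbad, dx = hm$dx), cfg),
               "QC rejected")

  # fill-in never lowers the measured fraction
  log <- p1$meta$stage_log
  expect_gte(log$measured_fraction[log$stage == "fill"],
             log$measured_fraction[log$stage == "outliers"])
})

test_that("form removal recovers texture under a quadratic bow", {
  hm <- simulate_base_surface("SF", seed = 13, n_pix = 128)
  n <- 128
  xs <- (seq_len(n) - (n + 1) / 2) * hm$dx
  bow <- 2e-4 * (outer(xs^2, rep(1, n)) + outer(rep(1, n), xs^2))
  bowed <- height_map(hm$heights + bow, dx = hm$dx)
  cfg <- preprocess_config(sfilter_cutoff_um = 5)
  ref <- preprocess_pipeline(hm, cfg)
  got <- preprocess_pipeline(bowed, cfg)
  expect_lt(abs(compute_sa(got) - compute_sa(ref)) / compute_sa(ref), 0.05)
})
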