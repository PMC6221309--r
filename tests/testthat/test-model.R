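# Likelihood, priors, sampler contract and posterior summaries.

small_table <- function(n_specimens = 10, seed = 5, n_lots = 3,
                        rescans = FALSE) {
  reg <- build_registry(registry_config(n_specimens = n_specimens,
                                        n_lots = n_lots, durations = 90))
  simulate_observation_table(reg, seed = seed,
                             rescan_final_molds = rescans)
}

# a minimal handcrafted fit object for the summary operations
fake_fit <- function(S = 200, seed = 1) {
  set.seed(seed)
  k <- 1; p <- 4; n_spec <- 3; n_lot <- 2; n <- 12
  B <- array(rnorm(k * p * S, 0, 0.1), dim = c(k, p, S))
  fit <- list(
    B = B,
    U_spec = array(0, dim = c(n_spec, p, S)),
    U_lot = array(0, dim = c(n_lot, p, S)),
    d_spec = matrix(1, S, p), d_lot = matrix(1, S, p),
    d_err = matrix(sqrt(2 * 3 / 5), S, p),
    omega_spec = array(diag(p), dim = c(p, p, S)),
    omega_lot = array(diag(p), dim = c(p, p, S)),
    omega_err = array(diag(p), dim = c(p, p, S)),
    nu = rep(5, S), chains = 2L, warmup = 0L, draws_per_chain = S / 2,
    Y = matrix(0, n, p), X = matrix(1, n, 1,
                                    dimnames = list(NULL, "(Intercept)")),
    zi = list(spec_idx = rep(1:3, each = 4), lot_idx = rep(1:2, 6),
              n_spec = 3, n_lot = 2),
    model_id = "M0", col_names = "(Intercept)",
    param_names = c("Sa", "Sal", "Spc", "Smr1"))
  class(fit) <- "texture_fit"
  fit
}

test_that("multivariate t log-density: Gaussian limit, symmetry, 1-D slice", {
  d <- c(0.3, 0.5, 0.2, 0.4)
  O <- diag(4)
  O[1, 2] <- O[2, 1] <- 0.4
  r <- c(0.2, -0.1, 0.05, 0.3)
  # nu -> infinity recovers the Gaussian
  Sigma <- diag(d) %*% O %*% diag(d)
  gauss <- -0.5 * determinant(2 * pi * Sigma)$modulus[1] -
    0.5 * drop(r %*% solve(Sigma, r))
  expect_equal(log_likelihood(r, rep(0, 4), d, O, 1e6), gauss,
               tolerance = 1e-3, ignore_attr = TRUE)
  # symmetry in the residual
  expect_equal(log_likelihood(r, rep(0, 4), d, O, 5),
               log_likelihood(-r, rep(0, 4), d, O, 5))
  # p = 1 slice matches the scaled univariate Student-t
  expect_equal(log_likelihood(0.7, 0, 0.3, matrix(1, 1, 1), 4),
               stats::dt(0.7 / 0.3, df = 4, log = TRUE) - log(0.3))
  expect_error(log_likelihood(r, rep(0, 4), d, O, 1.5), "nu")
})

test_that("log-prior terms match their closed forms and support", {
  par0 <- list(B = matrix(0, 1, 1), d_spec = 1, omega_spec = matrix(1),
               d_lot = 1, omega_lot = matrix(1), d_err = 1,
               omega_err = matrix(1), nu = 10)
  lp0 <- log_prior(par0)
  par1 <- par0
  par1$B <- matrix(1, 1, 1)
  # moving one B element from 0 to 1 changes the Gaussian(0,5) term only
  expect_equal(lp0 - log_prior(par1),
               dnorm(0, 0, 5, TRUE) - dnorm(1, 0, 5, TRUE))
  # truncation at nu = 2
  par2 <- par0
  par2$nu <- 1.5
  expect_identical(log_prior(par2), -Inf)
  # the identity maximizes the LKJ(1.5) density over correlation matrices
  O4 <- function(rho) {
    m <- matrix(rho, 4, 4)
    diag(m) <- 1
    m
  }
  pI <- par0
  pI$omega_err <- diag(4)
  pR <- par0
  pR$omega_err <- O4(0.5)
  expect_gt(log_prior(pI), log_prior(pR))
})

test_that("sampler contract: draw count, determinism, convergence report", {
  tab <- small_table()
  fit1 <- fit_mcmc(table = tab, model_id = "M1", chains = 2,
                   warmup = 100, draws = 100, seed = 3)
  expect_equal(n_draws(fit1), 200)
  expect_equal(dim(fit1$B), c(6, 4, 200))
  expect_true(is.finite(fit1$max_rhat))
  expect_true(all(c("d_spec", "omega_err", "nu") %in%
                    names(fit1$acceptance)))
  fit2 <- fit_mcmc(table = tab, model_id = "M1", chains = 2,
                   warmup = 100, draws = 100, seed = 3)
  expect_identical(fit1$B, fit2$B)
  expect_identical(fit1$nu, fit2$nu)
})

test_that("posterior mean tracks least squares in the Gaussian balanced regime", {
  reg <- build_registry(registry_config(n_specimens = 18, n_lots = 3,
                                        durations = 90))
  wp <- wear_params(sd_spec = 0.02, sd_lot = 0.02, noise_scale = 0.2,
                    t_df = 500)
  tab <- simulate_observation_table(reg, wp, seed = 21)
  fit <- fit_mcmc(table = tab, model_id = "M1", chains = 2,
                  warmup = 200, draws = 200, seed = 9)
  tr <- log_transform_table(tab)
  X <- build_fixed_design(tab, "M1")
  ols <- qr.solve(X, tr$Y)
  Bhat <- apply(fit$B, c(1, 2), mean)
  expect_lt(max(abs(Bhat - ols)), 0.1)
})

test_that("WAIC matches a direct two-pass formula evaluation", {
  set.seed(31)
  ll <- matrix(rnorm(10 * 5, -3, 0.4), 10, 5)   # 10 draws x 5 points
  got <- osteotex:::waic_from_loglik(ll)
  lppd <- 0
  p_waic <- 0
  for (i in 1:5) {
    lppd <- lppd + log(mean(exp(ll[, i])))
    p_waic <- p_waic + var(ll[, i])
  }
  expect_equal(got$waic, -2 * (lppd - p_waic), tolerance = 1e-12)
  expect_equal(got$lppd, lppd, tolerance = 1e-12)
  expect_error(osteotex:::waic_from_loglik(ll[1, , drop = FALSE]),
               "at least 2")

  # identical fits give a zero WAIC difference
  tab <- small_table()
  fit <- fit_mcmc(table = tab, model_id = "M0", chains = 1,
                  warmup = 50, draws = 50, seed = 2)
  wt <- waic_table(list(A = fit, B = fit))
  expect_equal(wt$delta_waic, c(0, 0))
})

test_that("ICC arithmetic and bounds", {
  fit <- fake_fit()
  # variances: lot 1, spec 1, err = 2*3/5 * 5/3 = 2 -> ICC_lot = 0.25
  icc <- compute_icc(fit)
  expect_equal(icc$lot$mean, rep(0.25, 4), tolerance = 1e-12)
  expect_equal(icc$spec$mean, rep(0.25, 4), tolerance = 1e-12)
  expect_true(all(icc$draws$lot >= 0 & icc$draws$lot <= 1))
})

test_that("Mahalanobis distances vanish at a perfect fit", {
  fit <- fake_fit()
  fit$B <- array(0, dim = dim(fit$B))   # posterior mean 0 = Y exactly
  gof <- mahalanobis_gof(fit)
  expect_equal(gof$observed, rep(0, 12))
  expect_equal(length(gof$theoretical), 12)
  expect_true(all(diff(gof$theoretical) > 0))
})

test_that("trajectories: materials coincide at time 0 and follow X * B", {
  tab <- small_table()
  fit <- fit_mcmc(table = tab, model_id = "M3", chains = 1,
                  warmup = 100, draws = 100, seed = 4)
  tr <- posterior_trajectories(fit, times = c(0, 30, 90))
  t0 <- tr[tr$time_min == 0, ]
  for (st in unique(t0$state)) {
    for (pp in unique(t0$parameter)) {
      v <- t0$mean[t0$state == st & t0$parameter == pp]
      expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
    }
  }
  # the predicted mean at a design point is X_row B-hat
  row <- data.frame(location = "C", is_mold = FALSE, is_rescan = FALSE,
                    state = "GS", material = "FS", time_min = 90)
  Xr <- build_fixed_design(row, "M3")
  Bhat <- apply(fit$B, c(1, 2), mean)
  pred <- tr[tr$state == "GS" & tr$material == "FS" & tr$time_min == 90, ]
  expect_equal(pred$mean, as.numeric(Xr %*% Bhat), tolerance = 1e-10)
  # intervals widen away from the bulk of the data
  w30 <- tr$hi[tr$time_min == 30] - tr$lo[tr$time_min == 30]
  expect_warning(
    tr2 <- posterior_trajectories(fit, times = c(30, 5000)),
    "extrapolates")
  w5000 <- tr2$hi[tr2$time_min == 5000] - tr2$lo[tr2$time_min == 5000]
  expect_gt(mean(w5000), mean(w30))
})

test_that("posterior ellipses summarise the draw cloud correctly", {
  fit <- fake_fit(S = 400, seed = 7)
  es <- posterior_ellipses(fit, time_min = 0)
  expect_length(es, 6)
  e1 <- es[[1]]
  cloud <- t(sapply(seq_len(400), function(s) fit$B[1, , s]))
  colnames(cloud) <- fit$param_names
  expect_equal(unname(e1$center), unname(colMeans(cloud[, e1$pair])),
               tolerance = 1e-12)
  # isotropic draws give a near-circular contour
  expect_lt(max(e1$axes) / min(e1$axes), 1.2)
  # about 95 % of draws fall inside their own contour
  V <- cov(cloud[, e1$pair])
  ctr <- colMeans(cloud[, e1$pair])
  d2 <- mahalanobis(cloud[, e1$pair], ctr, V)
  inside <- mean(d2 <= qchisq(0.95, 2))
  expect_gt(inside, 0.92)
  expect_lt(inside, 0.98)
  expect_error(posterior_ellipses(fake_fit(S = 5)), "at least 10")
})

test_that("row permutation leaves WAIC and ICC essentially unchanged", {
  # rescans included so every fixed-effect column is data-identified
  tab <- small_table(n_specimens = 15, seed = 13, n_lots = 5,
                     rescans = TRUE)
  fit_a <- fit_mcmc(table = tab, model_id = "M1", chains = 2,
                    warmup = 300, draws = 300, seed = 11)
  set.seed(42)
  perm <- sample(nrow(tab))
  fit_b <- fit_mcmc(table = tab[perm, ], model_id = "M1", chains = 2,
                    warmup = 300, draws = 300, seed = 11)
  wa <- compute_waic(fit_a)$waic
  wb <- compute_waic(fit_b)$waic
  expect_lt(abs(wa - wb) / abs(wa), 0.05)
  # posterior medians of the ICC (stable against heavy-tailed draws)
  ia <- apply(compute_icc(fit_a)$draws$lot, 2, median)
  ib <- apply(compute_icc(fit_b)$draws$lot, 2, median)
  expect_lt(max(abs(ia - ib)), 0.15)
  # fixed effects are the stable summaries: much tighter agreement
  ba <- apply(fit_a$B, c(1, 2), mean)
  bb <- apply(fit_b$B, c(1, 2), mean)
  expect_lt(max(abs(ba - bb)), 0.05)
})
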