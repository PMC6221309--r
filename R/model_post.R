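# Pointwise log-likelihood matrix (draws x rows) of a fit: each point is
# one 4-vector observation row under the multivariate Student-t.
pointwise_loglik <- function(fit, Y = fit$Y, X = fit$X, zi = fit$zi) {
  S <- n_draws(fit)
  n <- nrow(Y)
  p <- ncol(Y)
  ll <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    mu <- X %*% fit$B[, , s] + fit$U_spec[zi$spec_idx, , s] +
      fit$U_lot[zi$lot_idx, , s]
    R <- Y - mu
    Sig <- diag(fit$d_err[s, ]) %*% fit$omega_err[, , s] %*%
      diag(fit$d_err[s, ])
    L <- chol(Sig)
    q <- rowSums(t(backsolve(L, t(R), transpose = TRUE))^2)
    nu <- fit$nu[s]
    ll[s, ] <- lgamma((nu + p) / 2) - lgamma(nu / 2) -
      (p / 2) * log(nu * pi) - sum(log(diag(L))) -
      ((nu + p) / 2) * log1p(q / nu)
  }
  ll
}

# WAIC from a pointwise log-likelihood matrix (draws x points): the
# deviance-scale score -2 * (lppd - p_waic).
waic_from_loglik <- function(ll) {
  if (nrow(ll) < 2L) stop("need at least 2 draws for WAIC")
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Widely applicable information criterion of a fit
#'
#' Computes `WAIC = -2 * (lppd - p_waic)` where the log pointwise
#' predictive density and the effective-parameter penalty are accumulated
#' over observation rows — one "point" is one 4-vector scan, matching the
#' multivariate likelihood. Lower WAIC indicates better expected
#' out-of-sample prediction.
#'
#' @param fit A `texture_fit`.
#' @param Y,X,zi Data and designs; default to those stored in the fit.
#' @return A list with `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(fit, Y = fit$Y, X = fit$X, zi = fit$zi) {
  waic_from_loglik(pointwise_loglik(fit, Y, X, zi))
}

#' WAIC comparison table for a model ladder
#'
#' @param fits Named list of `texture_fit` objects (e.g. M0-M3).
#' @return A `data.frame` with model, waic, p_waic and `delta_waic`
#'   relative to the best (smallest-WAIC) model, sorted by complexity
#'   order of the input.
#' @export
waic_table <- function(fits) {
  w <- vapply(fits, function(f) compute_waic(f)$waic, numeric(1))
  p <- vapply(fits, function(f) compute_waic(f)$p_waic, numeric(1))
  data.frame(model = names(fits), waic = w, p_waic = p,
             delta_waic = w - min(w), row.names = NULL)
}

#' Intraclass correlations for lot and specimen
#'
#' Per texture parameter j, the share of total unstructured variance
#' attributable to each grouping factor:
#' `ICC_lot(j) = var_lot(j) / (var_lot(j) + var_spec(j) + var_err(j))`,
#' where the error variance uses the Student-t variance
#' `scale^2 * nu / (nu - 2)`. Computed per posterior draw; posterior means
#' and central 90 % intervals are reported.
#'
#' @param fit A `texture_fit`.
#' @return A list with `lot` and `spec` summary `data.frame`s (parameter,
#'   mean, lo, hi) and the per-draw matrices in `draws`.
#' @export
compute_icc <- function(fit) {
  v_lot <- fit$d_lot^2
  v_spec <- fit$d_spec^2
  v_err <- fit$d_err^2 * fit$nu / (fit$nu - 2)
  tot <- v_lot + v_spec + v_err
  icc_lot <- v_lot / tot
  icc_spec <- v_spec / tot
  summ <- function(m) data.frame(
    parameter = fit$param_names,
    mean = colMeans(m),
    lo = apply(m, 2, stats::quantile, 0.05),
    hi = apply(m, 2, stats::quantile, 0.95), row.names = NULL)
  list(lot = summ(icc_lot), spec = summ(icc_spec),
       draws = list(lot = icc_lot, spec = icc_spec))
}

#' Mahalanobis goodness-of-fit distances
#'
#' Squared Mahalanobis distances of each observation row from its
#' posterior-mean prediction, scaled by the dimension: `d2/p` follows an
#' F(p, nu) distribution under the multivariate-t observation model, so
#' plotting the sorted scaled distances against F quantiles (a QQ plot)
#' checks the distributional fit.
#'
#' @param fit A `texture_fit`.
#' @param Y,X,zi Data and designs; default to those stored in the fit.
#' @return A `data.frame` sorted by distance with columns `observed`
#'   (d2/p) and `theoretical` (F(p, nu-hat) quantiles at matching
#'   probability points).
#' @export
mahalanobis_gof <- function(fit, Y = fit$Y, X = fit$X, zi = fit$zi) {
  p <- ncol(Y)
  B_bar <- apply(fit$B, c(1, 2), mean)
  Us_bar <- apply(fit$U_spec, c(1, 2), mean)
  Ul_bar <- apply(fit$U_lot, c(1, 2), mean)
  d_bar <- colMeans(fit$d_err)
  O_bar <- apply(fit$omega_err, c(1, 2), mean)
  nu_bar <- mean(fit$nu)
  Sig <- diag(d_bar) %*% O_bar %*% diag(d_bar)
  L <- tryCatch(chol(Sig), error = function(e)
    stop("numerical error: singular posterior-mean scale"))
  R <- Y - (X %*% B_bar + Us_bar[zi$spec_idx, , drop = FALSE] +
              Ul_bar[zi$lot_idx, , drop = FALSE])
  d2 <- rowSums(t(backsolve(L, t(R), transpose = TRUE))^2)
  obs <- sort(d2 / p)
  data.frame(observed = obs,
             theoretical = stats::qf(stats::ppoints(length(obs)), p, nu_bar))
}

#' Posterior predicted mean trajectories over time
#'
#' Fixed-effect mean trajectories for each manufacturing state x material
#' cell over a time grid, with controls at baseline (location C, bone, not
#' rescanned). Back-transformed values (`exp` of the log-scale mean) are
#' geometric means on the original measurement scale.
#'
#' @param fit A `texture_fit` (full-interaction design).
#' @param times Time grid in minutes; by default the distinct times
#'   observed in the fitted data.
#' @param states,materials Factor levels to cross.
#' @param backtransform Report `exp` of the log-scale summaries.
#' @return A `data.frame` with state, material, time_min, parameter, mean,
#'   lo, hi (95 % interval) and `extrapolated` (TRUE beyond the fitted
#'   time range).
#' @export
posterior_trajectories <- function(fit, times = NULL,
                                   states = c("UW", "GS", "SF"),
                                   materials = c("FS", "PL", "DB"),
                                   backtransform = FALSE) {
  if (is.null(times)) {
    times <- if ("logTime" %in% fit$col_names)
      sort(unique(round(exp(fit$X[, "logTime"]) - 1))) else 0
  }
  grid <- expand.grid(state = states, material = materials,
                      time_min = times, stringsAsFactors = FALSE)
  tab <- data.frame(location = "C", is_mold = FALSE, is_rescan = FALSE,
                    state = grid$state, material = grid$material,
                    time_min = grid$time_min)
  Xg <- build_fixed_design(tab, fit$model_id)
  Xg <- Xg[, fit$col_names, drop = FALSE]
  tmax <- if ("logTime" %in% fit$col_names)
    max(exp(fit$X[, "logTime"]) - 1) + 1e-6 else max(times)
  if (any(grid$time_min > tmax))
    warning("trajectory grid extrapolates beyond the fitted time range")
  S <- n_draws(fit)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cloud <- t(vapply(seq_len(S),
                      function(s) as.numeric(Xg[r, ] %*% fit$B[, , s]),
                      numeric(4)))
    if (backtransform) cloud <- exp(cloud)
    out[[r]] <- data.frame(
      state = grid$state[r], material = grid$material[r],
      time_min = grid$time_min[r], parameter = fit$param_names,
      mean = colMeans(cloud),
      lo = apply(cloud, 2, stats::quantile, 0.025),
      hi = apply(cloud, 2, stats::quantile, 0.975),
      extrapolated = grid$time_min[r] > tmax, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Posterior 95 % contour ellipses for pairs of parameters
#'
#' For each pair of texture parameters, summarises the posterior cloud of
#' the fixed-effect mean at a given condition by its 95 % normal contour
#' (centre, semi-axes, orientation), the construction behind pairwise
#' scatterplot-matrix ellipses.
#'
#' @param fit A `texture_fit`.
#' @param time_min Condition time in minutes.
#' @param state,material Condition factor levels.
#' @param pairs Matrix or list of parameter-name pairs; default all 6.
#' @param level Contour coverage (default 0.95).
#' @return A list of ellipses, each with `pair`, `center`, `axes`
#'   (semi-axis lengths), `angle` (radians) and `polygon` (64-point
#'   outline).
#' @export
posterior_ellipses <- function(fit, time_min = 0, state = "UW",
                               material = "DB", pairs = NULL,
                               level = 0.95) {
  S <- n_draws(fit)
  if (S < 10L) stop("need at least 10 draws for an ellipse")
  if (is.null(pairs))
    pairs <- utils::combn(fit$param_names, 2, simplify = FALSE)
  if (is.matrix(pairs)) pairs <- asplit(pairs, 2)
  tab <- data.frame(location = "C", is_mold = FALSE, is_rescan = FALSE,
                    state = state, material = material, time_min = time_min)
  Xg <- build_fixed_design(tab, fit$model_id)[1, fit$col_names]
  cloud <- t(vapply(seq_len(S),
                    function(s) as.numeric(Xg %*% fit$B[, , s]), numeric(4)))
  colnames(cloud) <- fit$param_names
  r2 <- stats::qchisq(level, df = 2)
  theta <- seq(0, 2 * pi, length.out = 65)[-65]
  lapply(pairs, function(pr) {
    sub <- cloud[, pr, drop = FALSE]
    ctr <- colMeans(sub)
    V <- stats::cov(sub)
    eig <- eigen(V, symmetric = TRUE)
    axes <- sqrt(pmax(eig$values, 0) * r2)
    ang <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
    rot <- eig$vectors %*% diag(axes)
    poly <- t(ctr + rot %*% rbind(cos(theta), sin(theta)))
    colnames(poly) <- pr
    list(pair = pr, center = ctr, axes = axes, angle = ang, polygon = poly)
  })
}
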