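#' Multivariate Student-t log-likelihood of one observation row
#'
#' Density of the 4-variate Student-t observation model with scale
#' `Sigma = D %*% Omega %*% D` and `nu` degrees of freedom, evaluated at a
#' residual `y - mu`. This is the observation-level likelihood of the mixed
#' model; heavy tails (small `nu`) accommodate the over-dispersion of
#' log-texture parameters relative to a Gaussian.
#'
#' @param y_row,mean_row Numeric vectors of length p.
#' @param d_err Positive scale vector (diagonal of D).
#' @param omega_err p x p correlation matrix.
#' @param nu Degrees of freedom (> 2).
#' @return Log-density (scalar).
#' @export
log_likelihood <- function(y_row, mean_row, d_err, omega_err, nu) {
  p <- length(y_row)
  if (nu <= 2) stop("nu must exceed 2")
  Sigma <- diag(d_err, p) %*% omega_err %*% diag(d_err, p)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("numerical error: scale matrix not positive definite"))
  r <- as.numeric(y_row - mean_row)
  q <- sum(backsolve(L, r, transpose = TRUE)^2)
  lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(nu * pi) -
    sum(log(diag(L))) - ((nu + p) / 2) * log1p(q / nu)
}

log_half_cauchy_r <- function(d, scale) {
  if (any(d <= 0)) return(-Inf)
  sum(log(2 / (pi * scale)) - log1p((d / scale)^2))
}

lkj_log_r <- function(omega, eta) {
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || any(abs(diag(omega) - 1) > 1e-8)) return(-Inf)
  (eta - 1) * sum(log(ev))
}

#' Joint log-prior of the model parameters
#'
#' Sum of the model's prior log-densities: independent Gaussians with mean
#' 0 and SD 5 on the fixed effects, half-Cauchy(2.5) on all scale-matrix
#' diagonals, LKJ(1.5) on the correlation matrices (up to the LKJ
#' normalizing constant) and a Gamma(shape 2, rate 0.1) prior on the
#' Student-t degrees of freedom, left-truncated at 2 (so `nu <= 2` has
#' log-prior `-Inf`).
#'
#' @param params List with elements `B` (matrix), `d_spec`, `omega_spec`,
#'   `d_lot`, `omega_lot`, `d_err`, `omega_err`, `nu`.
#' @return Log-density (scalar; `-Inf` outside the support).
#' @export
log_prior <- function(params) {
  lp <- sum(stats::dnorm(params$B, 0, 5, log = TRUE))
  lp <- lp + log_half_cauchy_r(params$d_spec, 2.5) +
    log_half_cauchy_r(params$d_lot, 2.5) +
    log_half_cauchy_r(params$d_err, 2.5)
  lp <- lp + lkj_log_r(params$omega_spec, 1.5) +
    lkj_log_r(params$omega_lot, 1.5) + lkj_log_r(params$omega_err, 1.5)
  if (params$nu <= 2) return(-Inf)
  lp + stats::dgamma(params$nu, shape = 2, rate = 0.1, log = TRUE) -
    stats::pgamma(2, shape = 2, rate = 0.1, lower.tail = FALSE, log.p = TRUE)
}

# Split-Rhat of a draws matrix (iterations x chains).
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit the multivariate Student-t mixed model by MCMC
#'
#' Samples the posterior of `Y = X B + Z U + E` with crossed Gaussian
#' random intercepts (specimen, lot) and multivariate Student-t errors,
#' under the priors described in [log_prior()]. The sampler is
#' Gibbs-within-Metropolis on the Gamma scale-mixture representation of
#' the t likelihood: fixed effects, random effects and mixture weights are
#' conjugate Gibbs updates, while scale/correlation matrices and the
#' degrees of freedom move by adaptive random-walk Metropolis (adaptation
#' during warmup only, so the post-warmup chain targets the exact
#' posterior). Chains run sequentially from seeds `seed, seed + 1, ...`.
#'
#' @param Y n x 4 matrix of log texture parameters (from
#'   [log_transform_table()]).
#' @param X Fixed design from [build_fixed_design()].
#' @param Z Random design from [build_random_design()], or the index list
#'   from the same table.
#' @param chains,warmup,draws MCMC settings; the default 2 chains x (500
#'   warmup + 500 draws) stores 1000 posterior samples.
#' @param seed Integer seed for the first chain.
#' @param table Optional observation table; if supplied, `X` and `Z` are
#'   built from it (`model_id` chooses the fixed design).
#' @param model_id Fixed design to build when `table` is given.
#' @return An object of class `texture_fit`: draw arrays (`B` is
#'   k x 4 x S), sampler diagnostics (`rhat`, `acceptance`, `converged`),
#'   and the data/designs needed by the posterior summaries.
#' @export
fit_mcmc <- function(Y, X, Z, chains = 2L, warmup = 500L, draws = 500L,
                     seed = 1L, table = NULL, model_id = "M3") {
  if (!is.null(table)) {
    tr <- log_transform_table(table)
    Y <- tr$Y
    X <- build_fixed_design(table, model_id)
    Z <- random_effect_indices(table)
  }
  if (is.matrix(Z)) {
    zi <- attr(Z, "indices")
    if (is.null(zi))
      stop("Z must carry an 'indices' attribute or be the index list itself")
  } else zi <- Z
  n <- nrow(Y)
  stopifnot(nrow(X) == n, length(zi$spec_idx) == n)

  run_chain <- function(ch) {
    set.seed(seed + ch - 1L)
    fit_mcmc_cpp(Y, X, as.integer(zi$spec_idx - 1L),
                 as.integer(zi$lot_idx - 1L),
                 zi$n_spec, zi$n_lot, as.integer(warmup), as.integer(draws),
                 sd_b = 5, c_scale = 2.5, lkj_eta = 1.5,
                 nu_shape = 2, nu_rate = 0.1)
  }
  res <- lapply(seq_len(chains), run_chain)

  bindc <- function(name) {
    a <- lapply(res, `[[`, name)
    if (length(dim(a[[1]])) == 3L) {
      out <- array(unlist(a), dim = c(dim(a[[1]])[1:2],
                                      dim(a[[1]])[3] * chains))
      out
    } else if (is.matrix(a[[1]])) {
      do.call(rbind, a)
    } else {
      unlist(a)
    }
  }
  fit <- list(
    B = bindc("B"), U_spec = bindc("U_spec"), U_lot = bindc("U_lot"),
    d_spec = bindc("d_spec"), d_lot = bindc("d_lot"), d_err = bindc("d_err"),
    omega_spec = bindc("omega_spec"), omega_lot = bindc("omega_lot"),
    omega_err = bindc("omega_err"), nu = as.numeric(bindc("nu")),
    chains = chains, warmup = warmup, draws_per_chain = draws,
    acceptance = colMeans(do.call(rbind, lapply(res, `[[`, "acceptance"))),
    Y = Y, X = X, zi = zi, model_id = model_id,
    col_names = colnames(X), param_names = param_names)

  # split-Rhat over scalar summaries: fixed effects, scales, nu
  per_chain <- function(v) matrix(v, ncol = chains)
  rhats <- c(vapply(seq_len(dim(fit$B)[1]), function(i) {
    max(vapply(1:4, function(j)
      split_rhat(per_chain(fit$B[i, j, ])), numeric(1)))
  }, numeric(1)),
  vapply(1:4, function(j) split_rhat(per_chain(fit$d_err[, j])), numeric(1)),
  vapply(1:4, function(j) split_rhat(per_chain(fit$d_spec[, j])), numeric(1)),
  split_rhat(per_chain(fit$nu)))
  fit$rhat <- rhats
  fit$max_rhat <- max(rhats, na.rm = TRUE)
  fit$divergences <- 0L   # random-walk kernel: no divergent transitions
  fit$converged <- is.finite(fit$max_rhat) && fit$max_rhat <= 1.05
  class(fit) <- "texture_fit"
  fit
}

#' @export
print.texture_fit <- function(x, ...) {
  S <- dim(x$B)[3]
  cat(sprintf("<texture_fit> %s: %d draws (%d chains x %d), n = %d, k = %d\n",
              x$model_id, S, x$chains, x$draws_per_chain, nrow(x$Y),
              dim(x$B)[1]))
  cat(sprintf("  max split-Rhat %.3f (%s), mean nu %.1f\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged",
              mean(x$nu)))
  invisible(x)
}

#' Number of stored posterior draws
#' @param fit A `texture_fit`.
#' @return Integer draw count.
#' @export
n_draws <- function(fit) dim(fit$B)[3]
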