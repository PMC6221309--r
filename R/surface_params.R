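#' Arithmetic mean height (Sa)
#'
#' Sa is the arithmetic mean of absolute height deviations from the mean
#' plane, the standard areal roughness measure: a surface that wanders far
#' from its mean plane, in either direction, has a large Sa.
#'
#' @param hm A [height_map()] (assumed leveled / form-removed).
#' @return Sa in um (non-negative scalar).
#' @export
compute_sa <- function(hm) {
  stopifnot_height_map(hm)
  z <- measured_values(hm)
  if (length(z) < 2L) stop("degenerate input: fewer than 2 measured points")
  mean(abs(z - mean(z)))
}

# Circular fftshift of a matrix so that the zero-frequency / zero-lag cell
# moves to (floor(nr/2)+1, floor(nc/2)+1).
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(seq.int(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2)))
  ci <- c(seq.int(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))
  m[ri, ci, drop = FALSE]
}

#' Normalized areal autocorrelation function
#'
#' Estimates the 2D autocorrelation of the mean-removed surface via FFT
#' (mask-false cells contribute zero after mean removal), normalized so the
#' zero-lag value is 1. Lags are circular; for the fields of view used here
#' the short-lag region that determines Sal is unaffected by wrap-around in
#' practice, and the estimator is exact for periodic test surfaces.
#'
#' @param hm A [height_map()].
#' @return A list with `acf` (matrix, zero lag at centre), `lag_x`, `lag_y`
#'   (physical lag coordinates in um for columns / rows of `acf`).
#' @export
compute_acf <- function(hm) {
  stopifnot_height_map(hm)
  z <- hm$heights
  mz <- mean(z[hm$mask])
  z0 <- z - mz
  z0[!hm$mask] <- 0
  F0 <- stats::fft(z0)
  C <- Re(stats::fft(F0 * Conj(F0), inverse = TRUE))
  if (C[1, 1] <= 0)
    stop("degenerate input: zero height variance")
  A <- C / C[1, 1]
  A <- fftshift2(A)
  nr <- nrow(A); nc <- ncol(A)
  lag_y <- (seq_len(nr) - (floor(nr / 2) + 1L)) * hm$dy
  lag_x <- (seq_len(nc) - (floor(nc / 2) + 1L)) * hm$dx
  list(acf = A, lag_x = lag_x, lag_y = lag_y)
}

#' Autocorrelation length (Sal)
#'
#' Sal is the shortest lag distance at which the normalized autocorrelation
#' function decays to the threshold `s`, i.e. the decay length in the
#' direction of fastest decorrelation. Small Sal means a spatially busy,
#' short-wavelength surface.
#'
#' The search is over the discrete lag grid: Sal is the smallest physical
#' lag distance among all lags whose ACF value is `<= s` (this resolves the
#' fastest-decay direction to the lag-grid resolution, a quarter sample
#' spacing or better in distance for the fields of view used here).
#'
#' @param hm A [height_map()].
#' @param s Decay threshold (default 0.2, the customary choice).
#' @return Sal in um. If the ACF never decays to `s` inside the grid, the
#'   maximum searchable lag is returned with attribute `flag = "no_decay"`.
#' @export
compute_sal <- function(hm, s = 0.2) {
  stopifnot_height_map(hm)
  ac <- compute_acf(hm)
  d <- sqrt(outer(ac$lag_y^2, ac$lag_x^2, `+`))
  hit <- ac$acf <= s & d > 0
  if (!any(hit)) {
    out <- max(d)
    attr(out, "flag") <- "no_decay"
    return(out)
  }
  min(d[hit])
}

# Material ratio smr(c): percentage of measured points with height >= c.
# Vectorised over thresholds c.
smr_at <- function(z_sorted, c) {
  n <- length(z_sorted)
  100 * (n - findInterval(c, z_sorted, left.open = TRUE)) / n
}

#' Areal material ratio curve (Abbott-Firestone curve)
#'
#' For a descending grid of height thresholds `c`, the curve gives the
#' percentage of measured surface points lying at or above `c` — the bearing
#' area a plane at depth `c` would contact.
#'
#' @param hm A [height_map()].
#' @param n_levels Number of threshold levels between max and min height.
#' @return A list with `heights` (descending, um) and `ratios` (percent,
#'   non-decreasing from the top of the surface downward).
#' @export
compute_material_ratio_curve <- function(hm, n_levels = 512L) {
  stopifnot_height_map(hm)
  z <- measured_values(hm)
  if (length(z) < 2L) stop("degenerate input: fewer than 2 measured points")
  zs <- sort(z)
  cs <- seq(max(z), min(z), length.out = n_levels)
  list(heights = cs, ratios = smr_at(zs, cs))
}

# Height at a given material ratio (percent), i.e. the inverse of the
# material ratio curve, taken as the upper quantile of the height
# distribution. Shared by the main Smr1 implementation and its test oracle
# so that both work on the identical curve sampling.
mr_height_quantile <- function(z, mr_pct) {
  unname(stats::quantile(z, probs = 1 - mr_pct / 100, names = FALSE, type = 7))
}

#' Upper material ratio (Smr1)
#'
#' Smr1 separates the reduced-peak region from the core of the material
#' ratio curve by the equivalent straight line construction: a 40 %-wide
#' window is slid along the material-ratio axis to find the flattest secant
#' of the Abbott curve, a least-squares line is fitted to the curve inside
#' that window, and Smr1 is the material ratio attained at the height where
#' the fitted line meets mr = 0 %. A plateau-dominated surface carries most
#' of its material close to the top, giving a small reduced-peak region and
#' hence a small Smr1; conversely a surface with prominent isolated peaks
#' has a larger Smr1.
#'
#' @param hm A [height_map()].
#' @param window_pct Width of the sliding window on the material ratio axis
#'   (percent; 40 is the standard choice).
#' @param step_pct Sampling increment of the material ratio axis (percent).
#' @return Smr1 in percent, in `[0, 100]`.
#' @export
compute_smr1 <- function(hm, window_pct = 40, step_pct = 0.5) {
  stopifnot_height_map(hm)
  z <- measured_values(hm)
  if (length(z) < 2L) stop("degenerate input: fewer than 2 measured points")
  if (max(z) == min(z)) stop("degenerate input: constant surface")
  mr <- seq(0, 100, by = step_pct)
  cs <- mr_height_quantile(z, mr)
  nwin <- as.integer(round(window_pct / step_pct))
  starts <- seq_len(length(mr) - nwin)
  drop_h <- cs[starts] - cs[starts + nwin]        # >= 0, flattest = smallest
  i0 <- starts[which.min(drop_h)]
  idx <- i0:(i0 + nwin)
  fit <- stats::lm.fit(cbind(1, mr[idx]), cs[idx])
  h0 <- fit$coefficients[1]                        # equivalent line at mr = 0
  # strictly above the intercept height: material in the reduced-peak zone
  zs <- sort(z)
  min(max(100 * (length(zs) - findInterval(h0, zs)) / length(zs), 0), 100)
}

#' Significant surface peaks by prominence pruning
#'
#' Peaks are strict local maxima of the surface (8-neighbourhood, borders
#' excluded). Insignificant peaks are pruned by topographic prominence, the
#' discrete form of Wolf pruning on the watershed change tree: a peak whose
#' height above the saddle connecting it to higher ground is less than
#' `prune_frac` of the total surface height Sz is merged into its dominating
#' hill. Non-measured cells act as barriers.
#'
#' @param hm A [height_map()].
#' @param prune_frac Pruning threshold as a fraction of Sz (default 0.05,
#'   the standard 5 % rule).
#' @return A list of class `peak_set` with `rows`, `cols` (1-based grid
#'   indices of surviving peaks), `prominence` (um) and `threshold_um`.
#' @export
find_significant_peaks <- function(hm, prune_frac = 0.05) {
  stopifnot_height_map(hm)
  sz <- compute_sz(hm)
  if (sz <= 0) stop("degenerate input: constant surface")
  z <- hm$heights
  z[!hm$mask] <- -Inf
  res <- peak_prominence_cpp(z)
  thr <- prune_frac * sz
  keep <- res$prominence >= thr
  structure(
    list(rows = res$rows[keep], cols = res$cols[keep],
         prominence = res$prominence[keep], threshold_um = thr),
    class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d significant peaks (pruning threshold %.4g um)\n",
              length(x$rows), x$threshold_um))
  invisible(x)
}

#' Arithmetic mean peak curvature (Spc)
#'
#' Mean curvature of the significant surface peaks, estimated at each peak
#' by 3-point central finite differences:
#' `Spc = -(1 / 2n) * sum(d2z/dx2 + d2z/dy2)`. Positive for convex peaks;
#' larger values mean sharper peaks. Peaks whose 4-neighbourhood contains a
#' non-measured cell are skipped (no reliable curvature estimate).
#'
#' @param hm A [height_map()].
#' @param peaks A `peak_set` from [find_significant_peaks()]; computed from
#'   `hm` if omitted.
#' @return Spc in 1/um.
#' @export
compute_spc <- function(hm, peaks = NULL) {
  stopifnot_height_map(hm)
  if (is.null(peaks)) peaks <- find_significant_peaks(hm)
  if (length(peaks$rows) == 0L)
    stop("undefined value: no significant peaks")
  z <- hm$heights
  curv <- rep(NA_real_, length(peaks$rows))
  for (k in seq_along(peaks$rows)) {
    i <- peaks$rows[k]; j <- peaks$cols[k]
    if (i <= 1L || i >= nrow(z) || j <= 1L || j >= ncol(z)) next
    nb <- c(z[i - 1, j], z[i + 1, j], z[i, j - 1], z[i, j + 1])
    if (anyNA(nb)) next
    d2y <- (z[i - 1, j] - 2 * z[i, j] + z[i + 1, j]) / hm$dy^2
    d2x <- (z[i, j - 1] - 2 * z[i, j] + z[i, j + 1]) / hm$dx^2
    curv[k] <- -0.5 * (d2x + d2y)
  }
  curv <- curv[!is.na(curv)]
  if (length(curv) == 0L)
    stop("undefined value: no peak with a fully measured neighbourhood")
  mean(curv)
}

#' All four texture parameters of a height map
#'
#' Convenience wrapper computing the 4-vector used throughout the package:
#' arithmetic mean height `Sa` (um), autocorrelation length `Sal` (um),
#' arithmetic mean peak curvature `Spc` (1/um) and upper material ratio
#' `Smr1` (percent).
#'
#' @param hm A preprocessed [height_map()].
#' @return Named numeric vector `c(Sa, Sal, Spc, Smr1)`.
#' @export
compute_all_params <- function(hm) {
  stopifnot_height_map(hm)
  c(Sa = compute_sa(hm),
    Sal = as.numeric(compute_sal(hm)),
    Spc = compute_spc(hm),
    Smr1 = compute_smr1(hm))
}
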