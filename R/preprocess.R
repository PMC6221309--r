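#' Preprocessing configuration
#'
#' Bundles the tunable settings of the metrological chain that turns a raw
#' scan into an analysis-ready height map.
#'
#' @param accept_fraction Minimum measured fraction for a scan to pass QC
#'   (inclusive bound; default 0.95).
#' @param hole_fill_max Largest 8-connected non-measured region (in points)
#'   that is filled; larger holes stay non-measured (default 225, i.e. holes
#'   of fewer than 225 points are filled).
#' @param outlier_k Robust-z threshold for outlier removal: cells whose
#'   residual from a 5x5 median surface exceeds `outlier_k` MADs are removed.
#'   3 corresponds to "normal strength".
#' @param sfilter_cutoff_um Gaussian S-filter cutoff wavelength in um (50 %
#'   amplitude transmission at this wavelength). Default 5 um, about three
#'   sample spacings of a 0.8 mm / 512 px field.
#' @param form_degree Polynomial degree of the form operator (fixed at 2).
#' @param is_mold Whether the scan is of a mold (triggers y/z mirroring so
#'   molds compare directly with their bones).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(accept_fraction = 0.95, hole_fill_max = 225L,
                              outlier_k = 3, sfilter_cutoff_um = 5,
                              form_degree = 2L, is_mold = FALSE) {
  if (accept_fraction <= 0 || accept_fraction > 1)
    stop("accept_fraction must be in (0, 1]")
  if (hole_fill_max < 0) stop("hole_fill_max must be >= 0")
  if (form_degree != 2L) stop("only degree-2 form removal is supported")
  structure(list(accept_fraction = accept_fraction,
                 hole_fill_max = as.integer(hole_fill_max),
                 outlier_k = outlier_k,
                 sfilter_cutoff_um = sfilter_cutoff_um,
                 form_degree = 2L, is_mold = isTRUE(is_mold)),
            class = "preprocess_config")
}

#' Quality control on the measured fraction of a scan
#'
#' A scan is accepted when at least `threshold` of its grid points were
#' measured (the bound is inclusive).
#'
#' @param hm A [height_map()].
#' @param threshold Acceptance threshold on the measured fraction.
#' @return A list with `fraction` and logical `accept`.
#' @export
qc_measured_fraction <- function(hm, threshold = 0.95) {
  stopifnot_height_map(hm)
  frac <- mean(hm$mask)
  list(fraction = frac, accept = frac >= threshold)
}

# Design matrix of bivariate monomials up to a given degree on the measured
# cells, in physical coordinates centred on the grid.
poly_basis <- function(hm, degree) {
  d <- dim(hm$heights)
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) * hm$dx
  ys <- (seq_len(d[1]) - (d[1] + 1) / 2) * hm$dy
  xg <- matrix(xs, d[1], d[2], byrow = TRUE)[hm$mask]
  yg <- matrix(ys, d[1], d[2])[hm$mask]
  if (degree == 1L) {
    cbind(1, xg, yg)
  } else {
    cbind(1, xg, yg, xg^2, xg * yg, yg^2)
  }
}

fit_and_subtract <- function(hm, degree) {
  A <- poly_basis(hm, degree)
  z <- hm$heights[hm$mask]
  if (qr(A)$rank < ncol(A))
    stop("degenerate input: rank-deficient surface fit")
  beta <- stats::lm.fit(A, z)$coefficients
  d <- dim(hm$heights)
  xs <- (seq_len(d[2]) - (d[2] + 1) / 2) * hm$dx
  ys <- (seq_len(d[1]) - (d[1] + 1) / 2) * hm$dy
  xg <- matrix(xs, d[1], d[2], byrow = TRUE)
  yg <- matrix(ys, d[1], d[2])
  fitted <- beta[1] + beta[2] * xg + beta[3] * yg
  if (degree == 2L)
    fitted <- fitted + beta[4] * xg^2 + beta[5] * xg * yg + beta[6] * yg^2
  out <- hm$heights - fitted
  height_map(out, dx = hm$dx, dy = hm$dy, mask = hm$mask, meta = hm$meta)
}

#' Least-squares leveling
#'
#' Subtracts the least-squares plane through the measured points, so the
#' residual surface has zero mean and no linear tilt.
#'
#' @param hm A [height_map()].
#' @return The leveled [height_map()].
#' @export
level_lsq <- function(hm) {
  stopifnot_height_map(hm)
  if (sum(hm$mask) < 3L) stop("degenerate input: fewer than 3 measured points")
  fit_and_subtract(hm, 1L)
}

#' Mirror a mold scan back into bone orientation
#'
#' A mold is a physical negative of the bone: its scan is flipped along y
#' and inverted in z. Applying the same mirroring to the mold scan makes it
#' directly comparable to the bone scan. The operation is an involution.
#'
#' @param hm A [height_map()] of a mold scan.
#' @return The mirrored [height_map()].
#' @export
mirror_mold <- function(hm) {
  stopifnot_height_map(hm)
  z <- -hm$heights[rev(seq_len(nrow(hm$heights))), , drop = FALSE]
  m <- hm$mask[rev(seq_len(nrow(hm$mask))), , drop = FALSE]
  height_map(z, dx = hm$dx, dy = hm$dy, mask = m, meta = hm$meta)
}

# 5x5 moving median with edge replication; NA cells ignored within windows.
median_filter5 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  ri <- pmin(pmax(rep(seq_len(nr), 5) + rep(-2:2, each = nr), 1L), nr)
  # build stack of 25 shifted copies
  stack <- matrix(NA_real_, nr * nc, 25L)
  col_idx <- 0L
  for (dcol in -2:2) {
    cj <- pmin(pmax(seq_len(nc) + dcol, 1L), nc)
    zc <- z[, cj, drop = FALSE]
    for (drow in -2:2) {
      ri2 <- pmin(pmax(seq_len(nr) + drow, 1L), nr)
      col_idx <- col_idx + 1L
      stack[, col_idx] <- zc[ri2, , drop = FALSE]
    }
  }
  med <- apply(stack, 1L, stats::median, na.rm = TRUE)
  matrix(med, nr, nc)
}

# 8-connected component labelling of a logical matrix (TRUE cells), by
# iterative flood fill. Returns an integer matrix of labels (0 = FALSE).
label_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nextlab <- 0L
  todo <- which(m)
  for (start in todo) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ci <- (cur - 1L) %% nr + 1L
      cj <- (cur - 1L) %/% nr + 1L
      for (a in -1:1) for (b in -1:1) {
        if (a == 0L && b == 0L) next
        ni <- ci + a; nj <- cj + b
        ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
        if (!any(ok)) next
        nidx <- (nj[ok] - 1L) * nr + ni[ok]
        hit <- nidx[m[nidx] & lab[nidx] == 0L]
        if (length(hit)) {
          lab[hit] <- nextlab
          queue <- c(queue, hit)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Robust outlier removal
#'
#' Marks isolated spikes as non-measured: cells whose residual from a 5x5
#' median-filtered surface exceeds `k` times the MAD of all residuals are
#' removed. To target isolated measurement artefacts rather than genuine
#' sharp texture, the removal threshold has a floor of half the surface Sq,
#' so a deterministic clean surface passes through unchanged. Edge
#' replication of the median window applies the same rule on the border
#' ring. Which of the resulting non-measured regions may later be filled is
#' decided by the hole-size cap: 8-connected regions smaller than
#' `cfg$hole_fill_max` points are flagged fillable (stored in
#' `meta$fillable`), larger holes stay non-measured for good.
#'
#' @param hm A leveled [height_map()].
#' @param cfg A [preprocess_config()].
#' @return The cleaned [height_map()] with `meta$fillable` set.
#' @export
remove_outliers <- function(hm, cfg = preprocess_config()) {
  stopifnot_height_map(hm)
  med <- median_filter5(hm$heights)
  resid <- hm$heights - med
  rv <- resid[hm$mask]
  madv <- stats::mad(rv, na.rm = TRUE)
  thresh <- max(cfg$outlier_k * madv, 0.5 * compute_sq(hm))
  out_mask <- hm$mask
  spikes <- !is.na(resid) & abs(resid) > thresh
  out_mask[spikes] <- FALSE
  holes <- label_components8(!out_mask)
  fillable <- matrix(FALSE, nrow(out_mask), ncol(out_mask))
  if (max(holes) > 0L) {
    sizes <- tabulate(holes[holes > 0L])
    fillable[holes > 0L] <- sizes[holes[holes > 0L]] < cfg$hole_fill_max
  }
  meta <- hm$meta
  meta$fillable <- fillable
  z <- hm$heights
  z[!out_mask] <- NA_real_
  height_map(z, dx = hm$dx, dy = hm$dy, mask = out_mask, meta = meta)
}

#' Fill non-measured points from their neighbours
#'
#' Replaces fillable non-measured cells by harmonic (iterative 4-neighbour
#' mean) inpainting: values are relaxed until the largest per-iteration
#' change falls below `tol`. Harmonic filling reproduces locally planar
#' surfaces exactly and gives smooth, artefact-free patches for small holes.
#' Cells outside `meta$fillable` (large holes) are left non-measured; if
#' `meta$fillable` is absent every non-measured cell is filled.
#'
#' @param hm A [height_map()], typically from [remove_outliers()].
#' @param tol Convergence tolerance in um (default 1e-6).
#' @return The filled [height_map()]; filled cells become measured.
#' @export
fill_nonmeasured <- function(hm, tol = 1e-6) {
  stopifnot_height_map(hm)
  fill <- hm$meta$fillable
  if (is.null(fill)) fill <- !hm$mask
  fill <- fill & !hm$mask
  if (!any(fill)) return(hm)
  if (!any(hm$mask)) stop("degenerate input: no measured points to fill from")
  z <- hm$heights
  z[!hm$mask] <- mean(z, na.rm = TRUE)   # initial guess
  nr <- nrow(z); nc <- ncol(z)
  idx <- which(fill)
  repeat {
    # 4-neighbour indices with edge clamping
    ci <- (idx - 1L) %% nr + 1L
    cj <- (idx - 1L) %/% nr + 1L
    iu <- pmax(ci - 1L, 1L); id <- pmin(ci + 1L, nr)
    jl <- pmax(cj - 1L, 1L); jr <- pmin(cj + 1L, nc)
    newv <- (z[(cj - 1L) * nr + iu] + z[(cj - 1L) * nr + id] +
             z[(jl - 1L) * nr + ci] + z[(jr - 1L) * nr + ci]) / 4
    delta <- max(abs(newv - z[idx]))
    z[idx] <- newv
    if (delta < tol) break
  }
  mask <- hm$mask | fill
  z[!mask] <- NA_real_
  meta <- hm$meta
  meta$fillable <- NULL
  height_map(z, dx = hm$dx, dy = hm$dy, mask = mask, meta = meta)
}

#' Gaussian S-filter (low-pass denoising)
#'
#' Frequency-domain Gaussian low-pass with 50 % amplitude transmission at
#' wavelength `cutoff`: the transmission at wavelength `lambda` is
#' `exp(-pi * (alpha * cutoff / lambda)^2)` with `alpha = sqrt(log(2)/pi)`,
#' the standard metrological Gaussian weighting. Short-wavelength
#' measurement noise is attenuated while wear-scale structure passes.
#' Non-measured cells are handled by normalized convolution and remain
#' non-measured afterwards.
#'
#' @param hm A filled, leveled [height_map()].
#' @param cutoff Cutoff wavelength in um; must exceed the sample spacing.
#' @return The filtered [height_map()].
#' @export
sfilter_lowpass <- function(hm, cutoff = 5) {
  stopifnot_height_map(hm)
  if (cutoff <= max(hm$dx, hm$dy))
    stop("configuration error: cutoff must exceed the sample spacing")
  alpha <- sqrt(log(2) / pi)
  nr <- nrow(hm$heights); nc <- ncol(hm$heights)
  fy <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[seq_len(nr)] / (nr * hm$dy)
  fx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[seq_len(nc)] / (nc * hm$dx)
  f2 <- outer(fy^2, fx^2, `+`)
  H <- exp(-pi * alpha^2 * cutoff^2 * f2)
  z0 <- hm$heights
  z0[!hm$mask] <- 0
  m0 <- matrix(as.numeric(hm$mask), nr, nc)
  num <- Re(stats::fft(stats::fft(z0) * H, inverse = TRUE)) / (nr * nc)
  den <- Re(stats::fft(stats::fft(m0) * H, inverse = TRUE)) / (nr * nc)
  z <- num / pmax(den, 1e-12)
  z[!hm$mask] <- NA_real_
  height_map(z, dx = hm$dx, dy = hm$dy, mask = hm$mask, meta = hm$meta)
}

#' Degree-2 form removal (F-operator)
#'
#' Subtracts the least-squares fit of the six-term bivariate quadratic
#' (1, x, y, x^2, xy, y^2), removing residual bow and twist of the scanned
#' area so that only texture remains.
#'
#' @param hm A filled [height_map()].
#' @return The form-removed [height_map()].
#' @export
remove_form_poly2 <- function(hm) {
  stopifnot_height_map(hm)
  if (sum(hm$mask) < 6L) stop("degenerate input: fewer than 6 measured points")
  fit_and_subtract(hm, 2L)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: least-squares leveling, mold mirroring (when
#' `cfg$is_mold`), robust outlier removal, hole filling, Gaussian S-filter
#' and degree-2 form removal. The measured fraction and Sq after every stage
#' are recorded in `meta$stage_log`. Scans failing the measured-fraction QC
#' are refused.
#'
#' @param hm A raw [height_map()].
#' @param cfg A [preprocess_config()].
#' @return The analysis-ready [height_map()].
#' @export
preprocess_pipeline <- function(hm, cfg = preprocess_config()) {
  stopifnot_height_map(hm)
  qc <- qc_measured_fraction(hm, cfg$accept_fraction)
  if (!qc$accept)
    stop(sprintf("QC rejected: measured fraction %.3f < %.3f",
                 qc$fraction, cfg$accept_fraction))
  log_stage <- function(log, name, h) {
    rbind(log, data.frame(stage = name, measured_fraction = mean(h$mask),
                          Sq_um = compute_sq(h)))
  }
  slog <- log_stage(NULL, "input", hm)
  out <- level_lsq(hm);                  slog <- log_stage(slog, "level", out)
  if (cfg$is_mold) {
    out <- mirror_mold(out);             slog <- log_stage(slog, "mirror", out)
  }
  out <- remove_outliers(out, cfg);      slog <- log_stage(slog, "outliers", out)
  out <- fill_nonmeasured(out);          slog <- log_stage(slog, "fill", out)
  out <- sfilter_lowpass(out, cfg$sfilter_cutoff_um)
  slog <- log_stage(slog, "sfilter", out)
  out <- remove_form_poly2(out);         slog <- log_stage(slog, "form", out)
  out$meta$stage_log <- slog
  out
}
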