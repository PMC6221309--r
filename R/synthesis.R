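#' Registry configuration for the simulated experiment
#'
#' Describes the experimental design to be synthesised: how many bone
#' specimens, how many acquisition lots, and how long each specimen stays in
#' the wear experiment. The default reproduces the study layout: 37
#' specimens in 5 lots, molds taken at 0/30/60/90 minutes and at 90-minute
#' intervals thereafter, with a duration mix (28 specimens to 180 min, 5 to
#' 270 min, 4 to 450 min) chosen so the design yields 239 samples in total
#' (37 bones + 202 molds).
#'
#' @param n_specimens Number of bone specimens.
#' @param n_lots Number of acquisition lots; specimens are assigned to lots
#'   in contiguous blocks.
#' @param durations Optional vector of per-specimen total durations in
#'   minutes, recycled to `n_specimens`. `NULL` uses the default mix above.
#' @return A list of class `registry_config`.
#' @export
registry_config <- function(n_specimens = 37L, n_lots = 5L,
                            durations = NULL) {
  n_specimens <- as.integer(n_specimens)
  n_lots <- as.integer(n_lots)
  if (n_specimens < n_lots) stop("configuration error: more lots than specimens")
  if (is.null(durations)) {
    if (n_specimens == 37L) {
      durations <- rep(180, 37L)
      durations[c(1, 10, 19, 28)] <- 450
      durations[c(4, 8, 13, 22, 31)] <- 270
    } else {
      durations <- rep(180, n_specimens)
    }
  } else {
    durations <- rep_len(durations, n_specimens)
  }
  if (any(durations <= 0)) stop("configuration error: durations must be > 0")
  structure(list(n_specimens = n_specimens, n_lots = n_lots,
                 durations = durations),
            class = "registry_config")
}

# Mold schedule for one specimen: every 30 min up to 90, then every 90 min
# up to the total duration (time 0 always included).
mold_schedule <- function(duration) {
  s <- c(seq(0, min(90, duration), by = 30))
  if (duration > 90) s <- c(s, seq(180, duration, by = 90))
  s
}

#' Build the experiment registry
#'
#' Lays out specimens, lots, manufacturing states, material types, the mold
#' schedule and the sample list. States (UW, GS, SF) and materials (FS, PL,
#' DB) are crossed by cycling specimens through the 9 state x material
#' cells, so every cell is populated. Each specimen contributes one bone
#' sample (scanned at its final time) plus one mold sample per schedule
#' time. The construction is deterministic; `seed` is accepted for
#' interface symmetry with the other generators.
#'
#' @param config A [registry_config()].
#' @param seed Ignored (the registry is deterministic); present so all
#'   generators share a calling convention.
#' @return A list of class `experiment_registry` with `specimens` (one row
#'   per specimen: specimen, lot, state, material, duration_min) and
#'   `samples` (one row per physical sample: sample_id, specimen, lot,
#'   state, material, time_min, is_mold).
#' @export
build_registry <- function(config = registry_config(), seed = NULL) {
  states <- c("UW", "GS", "SF")
  materials <- c("FS", "PL", "DB")
  n <- config$n_specimens
  cell <- (seq_len(n) - 1L) %% 9L
  spec <- data.frame(
    specimen = sprintf("S%02d", seq_len(n)),
    lot = sprintf("L%d", pmin((seq_len(n) - 1L) %/%
                                ceiling(n / config$n_lots) + 1L,
                              config$n_lots)),
    state = states[cell %/% 3L + 1L],
    material = materials[cell %% 3L + 1L],
    duration_min = config$durations,
    stringsAsFactors = FALSE)

  rows <- lapply(seq_len(n), function(i) {
    times <- mold_schedule(spec$duration_min[i])
    rbind(
      data.frame(specimen = spec$specimen[i], lot = spec$lot[i],
                 state = spec$state[i], material = spec$material[i],
                 time_min = spec$duration_min[i], is_mold = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(specimen = spec$specimen[i], lot = spec$lot[i],
                 state = spec$state[i], material = spec$material[i],
                 time_min = times, is_mold = TRUE,
                 stringsAsFactors = FALSE))
  })
  samples <- do.call(rbind, rows)
  samples <- cbind(sample_id = sprintf("SMP%03d", seq_len(nrow(samples))),
                   samples, stringsAsFactors = FALSE)
  structure(list(specimens = spec, samples = samples,
                 locations = c("C", "D", "P", "L", "R")),
            class = "experiment_registry")
}

#' @export
print.experiment_registry <- function(x, ...) {
  cat(sprintf(
    "<experiment_registry> %d specimens, %d lots, %d samples (%d bones + %d molds)\n",
    nrow(x$specimens), length(unique(x$specimens$lot)), nrow(x$samples),
    sum(!x$samples$is_mold), sum(x$samples$is_mold)))
  invisible(x)
}

#' Wear and generative model parameters
#'
#' All tunables of the synthetic data generators in one place: the surface
#' simulator (pore density, furrow geometry per manufacturing state,
#' background texture), the wear kinetics per material (fresh skin wears
#' fastest; leather mostly rounds, bark mostly truncates), and the
#' parametric observation generator that mirrors the fitted model's
#' structure (true fixed effects on the log scale, random-effect standard
#' deviations for specimen and lot, Student-t noise scale and degrees of
#' freedom).
#'
#' @param pore_density Pores per mm^2 of bone surface.
#' @param base_sa_um Amplitude (Sa-like, um) of the unworked lamellar
#'   background texture.
#' @param wear_rate Named per-material first-order wear rates (1/min); wear
#'   progress after t minutes is `1 - exp(-rate * t)`.
#' @param polish_share,truncate_share,round_share Named per-material shares
#'   of the three erosion modes: differential polishing (soft matrix
#'   levelled, hard relief resists), contact-zone peak truncation, and
#'   overall smoothing.
#' @param hard_fraction Areal fraction of wear-resistant relief under
#'   differential polishing.
#' @param striation_amp_um Amplitude of the fine 5-10 um use striations.
#' @param sd_spec,sd_lot Random-intercept SDs (log scale) for specimen and
#'   lot.
#' @param noise_scale Student-t scale (log units) of the observation noise.
#' @param t_df Degrees of freedom of the Student-t noise (> 2).
#' @param B_true Optional 16 x 4 matrix of true fixed effects on the
#'   full-interaction design (log scale); `NULL` uses the built-in default
#'   emulating the reported wear trends.
#' @return A list of class `wear_params`.
#' @export
wear_params <- function(pore_density = 30, base_sa_um = 0.5,
                        wear_rate = c(FS = 0.004, PL = 0.0008, DB = 0.002),
                        polish_share = c(FS = 1, PL = 0.3, DB = 0),
                        truncate_share = c(FS = 0, PL = 0, DB = 1),
                        round_share = c(FS = 0.3, PL = 0.5, DB = 0),
                        hard_fraction = 0.25,
                        striation_amp_um = 0.08,
                        sd_spec = 0.20, sd_lot = 0.15,
                        noise_scale = 0.25, t_df = 5,
                        B_true = NULL) {
  if (t_df <= 2) stop("configuration error: t_df must exceed 2")
  if (any(wear_rate < 0)) stop("configuration error: wear rates must be >= 0")
  if (is.null(B_true)) B_true <- default_b_true()
  structure(list(pore_density = pore_density, base_sa_um = base_sa_um,
                 wear_rate = wear_rate, polish_share = polish_share,
                 truncate_share = truncate_share,
                 round_share = round_share, hard_fraction = hard_fraction,
                 striation_amp_um = striation_amp_um,
                 sd_spec = sd_spec, sd_lot = sd_lot,
                 noise_scale = noise_scale, t_df = t_df, B_true = B_true),
            class = "wear_params")
}

# True fixed effects on the M3 design, log scale; columns Sa, Sal, Spc,
# Smr1. Values emulate the reported qualitative trends: state ordering
# UW < GS < SF in Sa/Sal/Spc at time 0, fresh skin declining Sa/Spc and
# rising Smr1 over log time, molds with slightly rounded peaks.
default_b_true <- function() {
  cn <- c("Sa", "Sal", "Spc", "Smr1")
  rn <- m3_column_names()
  B <- matrix(0, length(rn), 4, dimnames = list(rn, cn))
  B["(Intercept)", ]          <- c(-0.69, 1.80, -3.50, 2.30)
  B["locLR", ]                <- c(0.05, 0.02, 0.02, -0.03)
  B["locDP", ]                <- c(-0.04, 0.03, -0.02, 0.02)
  B["mold", ]                 <- c(0.02, 0.01, -0.12, 0.02)
  B["rescan", ]               <- c(0.01, 0.00, -0.01, 0.00)
  B["logTime", ]              <- c(-0.005, 0.002, -0.005, 0.005)
  B["manGS", ]                <- c(0.85, 0.55, 0.35, 0.40)
  B["manSF", ]                <- c(1.55, 1.05, 0.65, 0.20)
  B["manGS:logTime", ]        <- c(-0.010, -0.004, -0.008, 0.004)
  B["manSF:logTime", ]        <- c(-0.015, -0.006, -0.010, 0.002)
  B["matFS:logTime", ]        <- c(-0.100, -0.004, -0.050, 0.100)
  B["matPL:logTime", ]        <- c(-0.012, -0.002, -0.015, 0.010)
  B["manGS:matFS:logTime", ]  <- c(-0.030, 0.004, -0.010, 0.020)
  B["manGS:matPL:logTime", ]  <- c(0.010, 0.002, 0.005, -0.010)
  B["manSF:matFS:logTime", ]  <- c(-0.040, 0.006, -0.015, 0.025)
  B["manSF:matPL:logTime", ]  <- c(0.012, 0.003, 0.006, -0.012)
  B
}

# Smooth anisotropic Gaussian random field, unit variance, via spectral
# shaping of white noise. corr_x / corr_y are 1/e correlation lengths (um).
gaussian_field <- function(n_pix, dx, corr_x, corr_y) {
  wn <- matrix(stats::rnorm(n_pix^2), n_pix, n_pix)
  f <- c(0:floor(n_pix / 2), -(ceiling(n_pix / 2) - 1):-1)[seq_len(n_pix)] /
    (n_pix * dx)
  H <- exp(-((pi * corr_y * outer(f, rep(1, n_pix)))^2 +
               (pi * corr_x * outer(rep(1, n_pix), f))^2) / 2)
  z <- Re(stats::fft(stats::fft(wn) * H, inverse = TRUE)) / n_pix^2
  z / stats::sd(z)
}

# Sum of transverse grooves (running along y with slight waviness) as a
# height decrement field. Widths in um are full widths at half maximum.
groove_field <- function(n_pix, dx, spacing_um, width_range, depth_range) {
  len <- n_pix * dx
  n_g <- max(1L, stats::rpois(1, len / spacing_um))
  xs <- matrix(rep((seq_len(n_pix) - 0.5) * dx, each = n_pix), n_pix, n_pix)
  ys <- (seq_len(n_pix) - 0.5) * dx
  z <- matrix(0, n_pix, n_pix)
  for (g in seq_len(n_g)) {
    cx <- stats::runif(1, 0, len)
    w <- stats::runif(1, width_range[1], width_range[2])
    d <- stats::runif(1, depth_range[1], depth_range[2])
    amp <- stats::runif(1, 0, 4)
    lam <- stats::runif(1, 150, 400)
    phi <- stats::runif(1, 0, 2 * pi)
    cxy <- cx + amp * sin(2 * pi * ys / lam + phi)
    sig <- w / 2.355
    z <- z - d * exp(-sweep(xs, 1, cxy, `-`)^2 / (2 * sig^2))
  }
  z
}

#' Simulate a bone surface in a given manufacturing state
#'
#' Generates the time-0 microtopography of a specimen: a fine anisotropic
#' lamellar background (grain along x), random pore depressions, and the
#' manufacturing traces — dense fine transverse scratches for bone ground
#' with sandstone (GS), sparse deep transverse furrows (30-100 um wide) for
#' bone scraped with flint (SF), nothing extra for unworked bone (UW).
#'
#' @param state One of `"UW"`, `"GS"`, `"SF"`.
#' @param porosity Pore density per mm^2; default from `wp`.
#' @param seed Optional RNG seed for reproducibility.
#' @param n_pix Grid size in pixels (square grid).
#' @param dx Lateral spacing in um (default 1.5625 um, a 0.8 mm field at
#'   512 px).
#' @param wp A [wear_params()].
#' @return A fully measured [height_map()].
#' @export
simulate_base_surface <- function(state, porosity = NULL, seed = NULL,
                                  n_pix = 512L, dx = 1.5625,
                                  wp = wear_params()) {
  state <- match.arg(state, c("UW", "GS", "SF"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(porosity)) porosity <- wp$pore_density
  z <- wp$base_sa_um * 1.25 * gaussian_field(n_pix, dx, corr_x = 6, corr_y = 2.5)
  len <- n_pix * dx
  area_mm2 <- (len / 1000)^2
  n_pores <- stats::rpois(1, porosity * area_mm2)
  if (n_pores > 0) {
    xs <- (seq_len(n_pix) - 0.5) * dx
    for (k in seq_len(n_pores)) {
      cx <- stats::runif(1, 0, len); cy <- stats::runif(1, 0, len)
      depth <- stats::runif(1, 0.5, 2.5)
      rad <- stats::runif(1, 4, 25)
      z <- z - depth * exp(-(outer((xs - cy)^2, (xs - cx)^2, `+`)) /
                             (2 * rad^2))
    }
  }
  if (state == "GS")
    z <- z + groove_field(n_pix, dx, spacing_um = 15,
                          width_range = c(8, 16), depth_range = c(0.5, 2))
  if (state == "SF")
    z <- z + groove_field(n_pix, dx, spacing_um = 80,
                          width_range = c(30, 100), depth_range = c(2, 8))
  height_map(z, dx = dx, dy = dx,
             meta = list(state = state, porosity = porosity))
}

# Gaussian smoothing of a full matrix by FFT, sigma in um.
smooth_field <- function(z, dx, sigma_um) {
  n_r <- nrow(z); n_c <- ncol(z)
  fy <- c(0:floor(n_r / 2), -(ceiling(n_r / 2) - 1):-1)[seq_len(n_r)] / (n_r * dx)
  fx <- c(0:floor(n_c / 2), -(ceiling(n_c / 2) - 1):-1)[seq_len(n_c)] / (n_c * dx)
  H <- exp(-2 * pi^2 * sigma_um^2 * outer(fy^2, fx^2, `+`))
  Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (n_r * n_c)
}

#' Apply material- and time-dependent wear to a surface
#'
#' Height-dependent erosion emulating abrasive use: peaks above a moving
#' quantile are softly truncated (plateau formation) and the surface is
#' partially smoothed, in material-specific proportions — fresh skin (FS)
#' wears fastest and both truncates and rounds; processed leather (PL)
#' mostly rounds, slowly; dry bark (DB) truncates the uppermost surfaces
#' only. Fine 5-10 um use striations accumulate with wear. Zero minutes
#' returns the input unchanged.
#'
#' @param hm A [height_map()] (fully measured).
#' @param material One of `"FS"`, `"PL"`, `"DB"`.
#' @param minutes Wear time in minutes (>= 0).
#' @param wp A [wear_params()].
#' @param seed Optional RNG seed.
#' @return The worn [height_map()].
#' @export
apply_wear <- function(hm, material, minutes, wp = wear_params(),
                       seed = NULL) {
  stopifnot_height_map(hm)
  material <- match.arg(material, c("FS", "PL", "DB"))
  if (minutes < 0) stop("minutes must be >= 0")
  if (minutes == 0) return(hm)
  if (!is.null(seed)) set.seed(seed)
  a <- 1 - exp(-wp$wear_rate[[material]] * minutes)
  z <- hm$heights
  # differential polishing (compliant abrasives, chiefly fresh skin): the
  # soft bone matrix is levelled toward a low reference plane while the
  # harder, coherent high relief resists, so the polished surface is a
  # flat ground with resistant features standing proud of it
  ps <- wp$polish_share[[material]]
  if (ps > 0) {
    hard_field <- smooth_field(z, hm$dx, sigma_um = 20)
    hard <- hard_field > stats::quantile(hard_field, 1 - wp$hard_fraction,
                                         names = FALSE)
    q_low <- stats::quantile(z, 0.35, names = FALSE)
    wgt <- a * ps * ifelse(hard, 0.25, 1)
    z <- (1 - wgt) * z + wgt * q_low
  }
  # partial smoothing (rounding of relief)
  rs <- wp$round_share[[material]]
  if (rs > 0) {
    zs <- smooth_field(z, hm$dx, sigma_um = 3)
    z <- (1 - a * rs) * z + a * rs * zs
  }
  # soft truncation of peaks above a receding quantile (rigid abrasives,
  # chiefly dry bark): only the uppermost contact zones are abraded flat
  ts <- wp$truncate_share[[material]]
  if (ts > 0) {
    frac <- ts * 0.45 * a
    q <- stats::quantile(z, probs = 1 - frac, names = FALSE)
    above <- z > q
    z[above] <- q + (z[above] - q) * (1 - a)^1.5
  }
  # fine use striations, 5-10 um wide, grow with wear
  stri <- groove_field(nrow(z), hm$dx, spacing_um = 25,
                       width_range = c(5, 10),
                       depth_range = wp$striation_amp_um * c(0.5, 1.5))
  z <- z + a * stri
  meta <- hm$meta
  meta$worn <- list(material = material, minutes = minutes)
  height_map(z, dx = hm$dx, dy = hm$dy, mask = hm$mask, meta = meta)
}

# Sub-pixel circular shift by spectral phase ramp (keeps amplitude spectrum,
# hence roughness, unchanged).
fourier_shift <- function(z, sy, sx) {
  n_r <- nrow(z); n_c <- ncol(z)
  fy <- c(0:floor(n_r / 2), -(ceiling(n_r / 2) - 1):-1)[seq_len(n_r)] / n_r
  fx <- c(0:floor(n_c / 2), -(ceiling(n_c / 2) - 1):-1)[seq_len(n_c)] / n_c
  ph <- exp(-2i * pi * (outer(fy * sy, rep(1, n_c)) +
                          outer(rep(1, n_r), fx * sx)))
  Re(stats::fft(stats::fft(z) * ph, inverse = TRUE)) / (n_r * n_c)
}

#' Take a mold of a surface
#'
#' Physical molding produces a negative replica: the grid is flipped along
#' y and heights are negated, so that [mirror_mold()] recovers the bone
#' orientation. Imperfections of the replication are emulated by a small
#' sub-pixel registration jitter (spectral shift, roughness-preserving) and
#' a slight rounding of the sharpest bone peaks controlled by `spc_bias`
#' (molds resolve the finest peaks imperfectly, so their mirrored scans
#' show lower Spc than the bone).
#'
#' @param hm A [height_map()] of the bone surface.
#' @param spc_bias Peak-rounding strength in `[0, 1]`; 0 = perfect replica.
#' @param jitter_px Registration jitter SD in pixels; 0 = none.
#' @param seed Optional RNG seed.
#' @return The mold [height_map()] (negative orientation).
#' @export
mold_of <- function(hm, spc_bias = 0.25, jitter_px = 0.3, seed = NULL) {
  stopifnot_height_map(hm)
  if (!is.null(seed)) set.seed(seed)
  z <- hm$heights
  if (spc_bias > 0) {
    zs <- smooth_field(z, hm$dx, sigma_um = 2.5)
    q <- stats::quantile(z, 0.7, names = FALSE)
    s <- max(stats::sd(z) / 4, 1e-9)
    w <- stats::plogis((z - q) / s)
    z <- z - spc_bias * w * (z - zs)
  }
  if (jitter_px > 0)
    z <- fourier_shift(z, stats::rnorm(1, 0, jitter_px),
                       stats::rnorm(1, 0, jitter_px))
  z <- -z[rev(seq_len(nrow(z))), , drop = FALSE]
  meta <- hm$meta
  meta$is_mold <- TRUE
  height_map(z, dx = hm$dx, dy = hm$dy, meta = meta)
}

#' Simulate the observation table from the fitted model's structure
#'
#' Bypasses surface simulation: draws log-scale 4-vectors (Sa, Sal, Spc,
#' Smr1) directly from the generative mirror of the mixed model — fixed
#' effects `X B_true` on the full-interaction design, Gaussian random
#' intercepts for specimen and lot, and multivariate Student-t noise. Fast
#' enough for repeated model-fitting experiments.
#'
#' @param registry An [build_registry()] result.
#' @param wp A [wear_params()] (uses `B_true`, `sd_spec`, `sd_lot`,
#'   `noise_scale`, `t_df`).
#' @param seed Optional RNG seed.
#' @param rescan_final_molds Add duplicate rescan rows for the final molds
#'   of the longest-running specimens (emulates the one-year mold rescan
#'   check). Default TRUE.
#' @return A `data.frame` with one row per scan: specimen, lot, state,
#'   material, time_min, location, is_mold, is_rescan and the four raw
#'   texture parameters (Sa_um, Sal_um, Spc_inv_um, Smr1_pct). The true
#'   generative quantities are attached as attribute `truth`.
#' @export
simulate_observation_table <- function(registry, wp = wear_params(),
                                       seed = NULL,
                                       rescan_final_molds = TRUE) {
  if (!inherits(registry, "experiment_registry"))
    stop("registry must be an experiment_registry")
  if (wp$t_df <= 2) stop("configuration error: t_df must exceed 2")
  if (!is.null(seed)) set.seed(seed)
  smp <- registry$samples
  tab <- smp[rep(seq_len(nrow(smp)), each = 5L), ]
  tab$location <- rep(registry$locations, times = nrow(smp))
  tab$is_rescan <- FALSE
  if (rescan_final_molds) {
    long <- registry$specimens$specimen[
      registry$specimens$duration_min == max(registry$specimens$duration_min)]
    fin <- smp[smp$is_mold & smp$specimen %in% long &
                 smp$time_min == max(registry$specimens$duration_min), ]
    if (nrow(fin) > 0) {
      extra <- fin[rep(seq_len(nrow(fin)), each = 5L), ]
      extra$location <- rep(registry$locations, times = nrow(fin))
      extra$is_rescan <- TRUE
      tab <- rbind(tab, extra)
    }
  }
  rownames(tab) <- NULL

  X <- build_fixed_design(tab, "M3")
  Zi <- random_effect_indices(tab)
  p <- 4L
  U_spec <- matrix(stats::rnorm(Zi$n_spec * p, 0, wp$sd_spec), ncol = p)
  U_lot <- matrix(stats::rnorm(Zi$n_lot * p, 0, wp$sd_lot), ncol = p)
  mu <- X %*% wp$B_true + U_spec[Zi$spec_idx, , drop = FALSE] +
    U_lot[Zi$lot_idx, , drop = FALSE]
  w <- stats::rgamma(nrow(tab), shape = wp$t_df / 2, rate = wp$t_df / 2)
  E <- matrix(stats::rnorm(nrow(tab) * p, 0, wp$noise_scale), ncol = p) /
    sqrt(w)
  Y <- mu + E
  tab$Sa_um <- exp(Y[, 1]); tab$Sal_um <- exp(Y[, 2])
  tab$Spc_inv_um <- exp(Y[, 3]); tab$Smr1_pct <- exp(Y[, 4])
  attr(tab, "truth") <- list(B_true = wp$B_true, U_spec = U_spec,
                             U_lot = U_lot, w = w, Y_log = Y)
  tab
}
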