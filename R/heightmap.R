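#' Height-map surface object
#'
#' A `height_map` holds a regular grid of surface heights together with a
#' validity mask and the lateral sampling intervals. It is the in-memory form
#' of a single confocal scan: rows run along y (top-left origin), columns
#' along x, heights and spacings are in micrometres. Every statistic in the
#' package ignores cells whose mask entry is `FALSE` (non-measured points).
#'
#' @param heights Numeric matrix of surface heights in um. `NA` entries are
#'   treated as non-measured and folded into `mask`.
#' @param dx,dy Lateral spacing in um between adjacent columns (`dx`) and
#'   rows (`dy`); both must be positive.
#' @param mask Logical matrix of the same dimension, `TRUE` where the point
#'   was measured. Defaults to `!is.na(heights)`.
#' @param meta Optional named list of free-form provenance (specimen id,
#'   instrument settings, pipeline stage notes...).
#'
#' @return An object of class `height_map` with fields `heights`, `mask`,
#'   `dx`, `dy`, `meta`.
#' @examples
#' hm <- height_map(matrix(rnorm(64), 8, 8), dx = 1.5625, dy = 1.5625)
#' compute_sa(hm)
#' @export
height_map <- function(heights, dx, dy = dx, mask = NULL, meta = list()) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop("heights must be a numeric matrix")
  if (!is.numeric(dx) || !is.numeric(dy) || dx <= 0 || dy <= 0)
    stop("dx and dy must be positive")
  if (is.null(mask)) mask <- !is.na(heights)
  if (!is.logical(mask) || !identical(dim(mask), dim(heights)))
    stop("mask must be a logical matrix with the same dimensions as heights")
  mask <- mask & !is.na(heights)
  h <- heights
  h[!mask] <- NA_real_
  structure(
    list(heights = h, mask = mask, dx = as.numeric(dx), dy = as.numeric(dy),
         meta = meta),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf(
    "<height_map> %d x %d px, dx = %g um, dy = %g um, measured %.1f%%\n",
    d[1], d[2], x$dx, x$dy, 100 * mean(x$mask)))
  zr <- range(x$heights[x$mask])
  cat(sprintf("  z range [%.4g, %.4g] um\n", zr[1], zr[2]))
  invisible(x)
}

is_height_map <- function(x) inherits(x, "height_map")

stopifnot_height_map <- function(hm) {
  if (!is_height_map(hm)) stop("expected a height_map object")
}

#' Measured heights as a vector
#'
#' @param hm A [height_map()].
#' @return Numeric vector of heights at measured cells only.
#' @keywords internal
measured_values <- function(hm) {
  hm$heights[hm$mask]
}

# Maximum height of the scale-limited surface, max z - min z over measured
# cells. Used as the peak-pruning reference.
compute_sz <- function(hm) {
  z <- measured_values(hm)
  if (length(z) < 1L) stop("degenerate input: no measured points")
  max(z) - min(z)
}

# Root-mean-square height; internal helper for pipeline logging and the
# outlier rule.
compute_sq <- function(hm) {
  z <- measured_values(hm)
  if (length(z) < 2L) stop("degenerate input: fewer than 2 measured points")
  sqrt(mean((z - mean(z))^2))
}

#' Write a height map as 32-bit float TIFF plus JSON sidecar
#'
#' Heights are stored affinely normalized to `[0, 1]` (the TIFF float
#' container's defined range); the offset and scale in um are recorded in
#' the sidecar together with the lateral spacing (`dx_um`, `dy_um`) and the
#' `meta` list, so a scan round-trips through disk to within float32
#' precision. Non-measured cells are written as `NaN`.
#'
#' @param hm A [height_map()].
#' @param path Output TIFF path; the sidecar is written next to it with
#'   extension `.json` unless `sidecar` is given.
#' @param sidecar Optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_heightmap_tiff <- function(hm, path, sidecar = NULL) {
  stopifnot_height_map(hm)
  z <- hm$heights
  z0 <- min(z, na.rm = TRUE)
  sc <- max(z, na.rm = TRUE) - z0
  if (!is.finite(sc) || sc <= 0) sc <- 1
  zn <- (z - z0) / sc
  zn[!hm$mask] <- 0            # placeholder; the mask rides in the sidecar
  tiff::writeTIFF(zn, path, bits.per.sample = 32L, reduce = FALSE)
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(
    list(dx_um = hm$dx, dy_um = hm$dy, z_offset_um = z0, z_scale_um = sc,
         nonmeasured = which(!hm$mask), meta = hm$meta),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a height map from 32-bit float TIFF plus JSON sidecar
#'
#' @param path TIFF path written by [write_heightmap_tiff()] (or any
#'   single-channel float TIFF with `NaN` marking non-measured points).
#' @param sidecar Sidecar JSON path; defaults to `path` with `.json`.
#' @return A [height_map()].
#' @export
read_heightmap_tiff <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".json", path)
  z <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(z)) == 3L) z <- z[, , 1L]
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  z[is.nan(z)] <- NA_real_
  if (!is.null(side$z_scale_um))
    z <- z * side$z_scale_um + side$z_offset_um
  if (length(side$nonmeasured)) z[side$nonmeasured] <- NA_real_
  height_map(z, dx = side$dx_um, dy = side$dy_um,
             meta = as.list(side$meta))
}

#' Write a height map as an ASCII matrix with JSON sidecar
#'
#' Plain-text alternative to the TIFF container: whitespace-separated rows,
#' `NA` for non-measured points.
#'
#' @inheritParams write_heightmap_tiff
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_heightmap_asc <- function(hm, path, sidecar = NULL) {
  stopifnot_height_map(hm)
  utils::write.table(hm$heights, path, row.names = FALSE, col.names = FALSE)
  if (is.null(sidecar)) sidecar <- sub("\\.asc$", ".json", path)
  jsonlite::write_json(
    list(dx_um = hm$dx, dy_um = hm$dy, meta = hm$meta),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a height map from an ASCII matrix with JSON sidecar
#'
#' @inheritParams read_heightmap_tiff
#' @param path `.asc` path written by [write_heightmap_asc()].
#' @return A [height_map()].
#' @export
read_heightmap_asc <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.asc$", ".json", path)
  z <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(z) <- NULL
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  height_map(z, dx = side$dx_um, dy = side$dy_um, meta = as.list(side$meta))
}
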