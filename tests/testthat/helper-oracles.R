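# Brute-force reference implementations: naive nested-loop versions of the
# Sal lag search, the Smr1 equivalent-line scan and prominence-pruned peak
# detection, kept deliberately independent of the package's vectorised /
# compiled implementations.

sal_brute <- function(hm, s = 0.2) {
  ac <- compute_acf(hm)   # shared estimator; the lag SEARCH is the oracle
  best <- Inf
  for (i in seq_along(ac$lag_y)) {
    for (j in seq_along(ac$lag_x)) {
      d <- sqrt(ac$lag_y[i]^2 + ac$lag_x[j]^2)
      if (d > 0 && ac$acf[i, j] <= s && d < best) best <- d
    }
  }
  best
}

smr1_brute <- function(hm, window_pct = 40, step_pct = 0.5) {
  z <- hm$heights[hm$mask]
  mr <- seq(0, 100, by = step_pct)
  cs <- quantile(z, probs = 1 - mr / 100, names = FALSE, type = 7)
  nwin <- as.integer(round(window_pct / step_pct))
  best_drop <- Inf
  best_i <- NA
  for (i in seq_len(length(mr) - nwin)) {
    dr <- cs[i] - cs[i + nwin]
    if (dr < best_drop) {
      best_drop <- dr
      best_i <- i
    }
  }
  idx <- best_i:(best_i + nwin)
  # least squares by the closed-form normal equations
  mx <- mean(mr[idx]); my <- mean(cs[idx])
  b <- sum((mr[idx] - mx) * (cs[idx] - my)) / sum((mr[idx] - mx)^2)
  h0 <- my - b * mx
  n <- length(z)
  cnt <- 0
  for (v in z) if (v > h0) cnt <- cnt + 1
  min(max(100 * cnt / n, 0), 100)
}

# flood fill of the thresholded set {z >= level} from a start cell
# (frontier expansion vectorised over the 8 neighbour offsets)
flood_from <- function(z, level, start) {
  nr <- nrow(z); nc <- ncol(z)
  inset <- !is.na(z) & z >= level
  seen <- matrix(FALSE, nr, nc)
  if (!inset[start]) return(seen)
  frontier <- start
  seen[start] <- TRUE
  while (length(frontier)) {
    ci <- (frontier - 1L) %% nr + 1L
    cj <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (a in -1:1) for (b in -1:1) {
      if (a == 0L && b == 0L) next
      ni <- ci + a; nj <- cj + b
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      if (!any(ok)) next
      nidx <- (nj[ok] - 1L) * nr + ni[ok]
      hit <- nidx[inset[nidx] & !seen[nidx]]
      if (length(hit)) {
        seen[hit] <- TRUE
        nxt <- c(nxt, hit)
      }
    }
    frontier <- unique(nxt)
  }
  seen
}

peaks_brute <- function(hm, prune_frac = 0.05) {
  z <- hm$heights
  z[!hm$mask] <- NA
  nr <- nrow(z); nc <- ncol(z)
  locmax <- list()
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(z[i, j])) next
    ismax <- TRUE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ni <- i + a; nj <- j + b
      if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
      if (!is.na(z[ni, nj]) && z[ni, nj] >= z[i, j]) ismax <- FALSE
    }
    if (ismax) locmax[[length(locmax) + 1]] <- c(i, j)
  }
  zm <- z[hm$mask]
  sz <- max(zm) - min(zm)
  thr <- prune_frac * sz
  keep <- matrix(NA_integer_, 0, 2)
  levels_sorted <- sort(unique(zm), decreasing = TRUE)
  for (pk in locmax) {
    hp <- z[pk[1], pk[2]]
    start <- (pk[2] - 1) * nr + pk[1]
    # highest level at which pk's component contains a strictly higher
    # cell = the key saddle; binary search over candidate levels below hp
    cand <- levels_sorted[levels_sorted <= hp]
    lo <- 1; hi <- length(cand); saddle <- NA_real_
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2
      comp <- flood_from(z, cand[mid], start)
      if (any(z[comp] > hp, na.rm = TRUE)) {
        saddle <- cand[mid]
        hi <- mid - 1
      } else {
        lo <- mid + 1
      }
    }
    prom <- if (is.na(saddle)) {
      comp <- flood_from(z, min(zm), start)
      hp - min(z[comp], na.rm = TRUE)
    } else hp - saddle
    if (prom >= thr) keep <- rbind(keep, pk)
  }
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}
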