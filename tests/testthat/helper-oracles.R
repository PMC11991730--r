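# Independent brute-force oracles and small fixtures. These deliberately
# re-derive each quantity with the dumbest possible loop so they share no
# code with the implementation they check.

# Gaussian kernel heatmap by explicit per-pixel, per-point double loop.
bruteKernel <- function(points, dm, sigma) {
  out <- matrix(0, dm[1], dm[2])
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
    best <- 0
    for (k in seq_len(nrow(points))) {
      d2 <- (i - points$row[k])^2 + (j - points$col[k])^2
      v <- if (d2 > (4 * sigma)^2) 0 else exp(-d2 / (2 * sigma^2))
      if (v > best) best <- v
    }
    out[i, j] <- best
  }
  out
}

# Confidence statistic by explicit pixel loop on two Good-channel matrices.
bruteConfidence <- function(g, gw, tol = 1e-8) {
  nnz <- 0L
  s <- 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    if (gw[i, j] > tol) nnz <- nnz + 1L
    d <- g[i, j] - gw[i, j]
    if (d > 0) s <- s + d
  }
  1 - min(s / (nnz + 1), 1)
}

# Peak detection by exhaustive window scan: a pixel is a candidate when it
# attains the max over rows i-4..i+3, cols j-4..j+3 (clipped) and reaches
# the threshold; among exact ties where one candidate lies inside the
# other's window (offsets at most max(4, 3) apart on each axis for an
# 8-window) only the first in row-major order survives.
brutePeaks <- function(x, threshold, window = 8L) {
  H <- nrow(x); W <- ncol(x)
  lo <- -(window %/% 2L); hi <- window - 1L + lo
  sep <- max(-lo, hi)
  cand <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    win <- x[max(1, i + lo):min(H, i + hi), max(1, j + lo):min(W, j + hi)]
    if (x[i, j] >= threshold && x[i, j] == max(win))
      cand <- rbind(cand, c(i, j))
  }
  if (is.null(cand)) return(data.frame(row = integer(), col = integer()))
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (k == 1L) next
    for (m in seq_len(k - 1L)) {
      if (keep[m] &&
          abs(cand[m, 1] - cand[k, 1]) <= sep &&
          abs(cand[m, 2] - cand[k, 2]) <= sep &&
          x[cand[m, 1], cand[m, 2]] == x[cand[k, 1], cand[k, 2]]) {
        keep[k] <- FALSE
        break
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(row = cand[, 1], col = cand[, 2])
}

# A small 16 x 24 grid for fast unit tests.
tinyGrid <- function() {
  gridSpec(latMin = 32, latMax = 35.75, lonStart = 142, lonExtent = 5.75,
           cellDeg = 0.25)
}

# A reduced synthetic world for smoke tests (fast; not the default-sized
# study world).
tinyWorld <- function(seed = 1, ...) {
  buildWorld(worldConfig(nDays = c(pretrain = 10L, finetune = 8L, test = 4L),
                         seed = seed, ...))
}

# Flat numeric finite-difference gradient of f at params (a named list).
numericGradient <- function(f, params, eps = 1e-6) {
  flat <- fishgrounds:::flattenParams(params)
  out <- numeric(length(flat))
  for (i in seq_along(flat)) {
    p1 <- flat; p1[i] <- p1[i] + eps
    p2 <- flat; p2[i] <- p2[i] - eps
    out[i] <- (f(fishgrounds:::unflattenParams(p1, params)) -
               f(fishgrounds:::unflattenParams(p2, params))) / (2 * eps)
  }
  out
}

# Random ground-truth-style heatmap pair on a small raster: a few kernels
# each, so zero regions and overlaps both occur.
randomHeatmapPair <- function(dm = c(32, 32), sigma = 4) {
  nP <- sample(0:3, 2, replace = TRUE)
  mk <- function(n) {
    pts <- data.frame(row = sample.int(dm[1], n, replace = TRUE),
                      col = sample.int(dm[2], n, replace = TRUE))
    gaussianKernelHeatmap(pts, dm, sigma)
  }
  list(g = mk(nP[1]), gw = mk(nP[2]))
}

# Wrap plain Good-channel matrices as catch/trajectory Heatmap3 pairs on a
# matching grid (for confidenceTarget's typed interface).
asHeatmapPair <- function(g, gw) {
  grid <- gridSpec(latMin = 30, latMax = 30 + (nrow(g) * 2 - 1) * 0.25,
                   lonStart = 140, lonExtent = (ncol(g) * 2 - 1) * 0.25)
  mk <- function(m, prov) {
    a <- array(0, c(dim(m), 3L))
    a[, , 1] <- m
    if (prov == "trajectory") a[, , 2] <- m
    new("Heatmap3", array = a, provenance = prov, grid = grid,
        stride = 2L, sigma = 4, date = as.Date("2020-01-01"))
  }
  list(y = mk(g, "catch"), yWeak = mk(gw, "trajectory"))
}

# Good catch positions of one world day (evaluation ground truth).
dayTruthDf <- function(day) {
  good <- day$catch[day$catch$cpue > 0, , drop = FALSE]
  data.frame(lat = good$lat, lon = good$lon)
}
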