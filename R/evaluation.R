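#' Detect peaks in a predicted heatmap
#'
#' 8x8 maximum-value filtering: a pixel is a peak when it attains the
#' sliding-window maximum of its 8x8 neighbourhood (window rows
#' `i-4..i+3`, cols `j-4..j+3`, clipped at borders) and its value reaches
#' `threshold`. Within exact ties that share a window (one tied candidate
#' lies inside the other's window), only the first pixel in row-major
#' order is kept; tied candidates too far apart to share a window are
#' genuinely separate peaks and all survive. Only the Good channel of a predicted
#' heatmap is evaluated; negative predictions are clipped to zero first.
#'
#' @param x a predicted [Heatmap3-class] (Good channel used) or a plain
#'   single-channel matrix
#' @param threshold minimum peak height (default 0.1; without a floor the
#'   max filter emits peaks on near-zero noise)
#' @param window filter size in pixels (default 8)
#' @return a data.frame of peaks: `row`, `col`, `value`, plus `lat`/`lon`
#'   when `x` is a `Heatmap3`
#' @export
detectPeaks <- function(x, threshold = 0.1, window = 8L) {
  hm <- NULL
  if (is(x, "Heatmap3")) {
    hm <- x
    x <- pmax(heatmapChannel(x, "Good"), 0)
  }
  H <- nrow(x); W <- ncol(x)
  lo <- -(window %/% 2L); hi <- window - 1L + lo
  # separable sliding max with border clipping
  slideMax <- function(m, along) {
    out <- m
    for (d in setdiff(lo:hi, 0L)) {
      sh <- matrix(-Inf, H, W)
      if (along == 1L) {
        src <- seq_len(H) + d
        ok <- src >= 1L & src <= H
        sh[ok, ] <- m[src[ok], ]
      } else {
        src <- seq_len(W) + d
        ok <- src >= 1L & src <= W
        sh[, ok] <- m[, src[ok]]
      }
      out <- pmax(out, sh)
    }
    out
  }
  slid <- slideMax(slideMax(x, 1L), 2L)
  cand <- which(x == slid & x >= threshold, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(cand[, 1], cand[, 2])   # row-major
    cand <- cand[ord, , drop = FALSE]
    sep <- max(-lo, hi)   # offsets at which two pixels can share a window
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      clash <- FALSE
      if (k > 1L) for (m in which(keep)) {
        if (abs(cand[m, 1] - i) <= sep && abs(cand[m, 2] - j) <= sep &&
            x[cand[m, 1], cand[m, 2]] == x[i, j]) { clash <- TRUE; break }
      }
      keep[k] <- !clash
    }
    cand <- cand[keep, , drop = FALSE]
  }
  out <- data.frame(row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
                    value = x[cand])
  if (!is.null(hm)) {
    pos <- heatmapPixelToLatlon(out$row, out$col, hm@grid, hm@stride)
    out$lat <- pos$lat
    out$lon <- pos$lon
  }
  rownames(out) <- NULL
  out
}

#' Score one day's peaks against ground truth
#'
#' A predicted peak is a true positive when its geodesic distance to the
#' nearest ground-truth point is below `dMax`; a truth point is recalled
#' when some peak lies within `dMax`. The default matching is
#' many-to-many (the rule is purely the 200-km distance criterion);
#' `matching = "one_to_one"` instead greedily pairs nearest
#' peak--truth pairs exclusively, as a sensitivity analysis.
#'
#' @param peaks data.frame with `lat`, `lon` (from [detectPeaks()])
#' @param truth data.frame with `lat`, `lon` of Good catch records
#' @param dMax hit radius in km (default 200, one day's vessel range)
#' @param matching `"many"` (default) or `"one_to_one"`
#' @return list of tallies: `tpPeaks`, `nPeaks`, `recalled`, `nTruth`
#' @export
scoreDay <- function(peaks, truth, dMax = 200, matching = c("many", "one_to_one")) {
  matching <- match.arg(matching)
  nP <- if (is.null(peaks)) 0L else nrow(peaks)
  nT <- if (is.null(truth)) 0L else nrow(truth)
  if (nP == 0L || nT == 0L)
    return(list(tpPeaks = 0L, nPeaks = nP, recalled = 0L, nTruth = nT))
  D <- outer(seq_len(nP), seq_len(nT),
             function(i, j) geodesicKm(peaks$lat[i], peaks$lon[i],
                                       truth$lat[j], truth$lon[j]))
  if (matching == "many") {
    tp <- sum(apply(D, 1, min) < dMax)
    rec <- sum(apply(D, 2, min) < dMax)
  } else {
    Dm <- D
    tp <- 0L
    repeat {
      k <- which.min(Dm)
      if (!length(k) || Dm[k] >= dMax) break
      i <- (k - 1) %% nP + 1
      j <- (k - 1) %/% nP + 1
      tp <- tp + 1L
      Dm[i, ] <- Inf
      Dm[, j] <- Inf
    }
    rec <- tp
  }
  list(tpPeaks = as.integer(tp), nPeaks = nP, recalled = as.integer(rec),
       nTruth = nT)
}

#' Aggregate per-day tallies into an evaluation report
#'
#' Micro-averages over pooled counts across test days: precision is
#' pooled true-positive peaks over pooled peaks, recall is pooled
#' recalled truth points over pooled truth points, and
#' `F1 = 2PR/(P+R)` (0 when `P + R = 0`). Order of days is immaterial.
#'
#' @param tallies list of per-day tallies from [scoreDay()]
#' @param dates optional vector of dates for the per-day breakdown
#' @return an `fgEvalReport`: list with `precision`, `recall`, `f1`,
#'   `nPeaks`, `nTruth`, `perDay`
#' @export
aggregateEval <- function(tallies, dates = NULL) {
  tp <- sum(vapply(tallies, `[[`, 0L, "tpPeaks"))
  nP <- sum(vapply(tallies, `[[`, 0L, "nPeaks"))
  rec <- sum(vapply(tallies, `[[`, 0L, "recalled"))
  nT <- sum(vapply(tallies, `[[`, 0L, "nTruth"))
  P <- if (nP > 0) tp / nP else 0
  R <- if (nT > 0) rec / nT else 0
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  perDay <- data.frame(
    date = if (is.null(dates)) seq_along(tallies) else dates,
    tpPeaks = vapply(tallies, `[[`, 0L, "tpPeaks"),
    nPeaks = vapply(tallies, `[[`, 0L, "nPeaks"),
    recalled = vapply(tallies, `[[`, 0L, "recalled"),
    nTruth = vapply(tallies, `[[`, 0L, "nTruth"))
  structure(list(precision = P, recall = R, f1 = f1, nPeaks = nP,
                 nTruth = nT, perDay = perDay),
            class = "fgEvalReport")
}

#' @export
print.fgEvalReport <- function(x, ...) {
  cat(sprintf("fishgrounds evaluation: P=%.3f R=%.3f F1=%.3f (%d peaks, %d truth points, %d days)\n",
              x$precision, x$recall, x$f1, x$nPeaks, x$nTruth, nrow(x$perDay)))
  invisible(x)
}

#' Evaluate a trained detector on test days
#'
#' Runs [predictHeatmap()], [detectPeaks()] and [scoreDay()] over a list
#' of test days and micro-averages the tallies.
#'
#' @param model a trained detector
#' @param testDays list of `list(sst = SSTMap, truth = data.frame(lat, lon))`
#' @param threshold peak threshold (default 0.1)
#' @param dMax hit radius in km (default 200)
#' @return an `fgEvalReport`
#' @export
evaluateDetector <- function(model, testDays, threshold = 0.1, dMax = 200) {
  tallies <- lapply(testDays, function(d) {
    pk <- detectPeaks(predictHeatmap(d$sst, model), threshold = threshold)
    scoreDay(pk, d$truth, dMax = dMax)
  })
  aggregateEval(tallies, dates = as.Date(vapply(testDays,
    function(d) format(d$sst@date), "")))
}

#' Plot an SST map with predicted peaks and ground truth
#'
#' Base-graphics overlay in the style of the method's qualitative
#' figures: the SST field as an image, predicted peaks as triangles and
#' ground-truth catch points as plus signs.
#'
#' @param sst a [SSTMap-class]
#' @param peaks data.frame with `lat`, `lon` (may be empty or `NULL`)
#' @param truth data.frame with `lat`, `lon` (may be empty or `NULL`)
#' @param ... passed to [graphics::image()]
#' @return invisibly, `NULL`
#' @export
plotDayOverlay <- function(sst, peaks = NULL, truth = NULL, ...) {
  g <- sst@grid
  v <- sst@values
  v[sst@mask] <- NA
  # x axis: eastward offset from lonStart (contiguous across antimeridian)
  xs <- (seq_len(g@nCols) - 1) * g@cellDeg
  ys <- g@latMin + (seq_len(g@nRows) - 1) * g@cellDeg
  graphics::image(xs, ys, t(v[g@nRows:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = sprintf("degrees east of %gE", g@lonStart),
                  ylab = "latitude", ...)
  off <- function(p) lonOffset(p$lon, g)
  if (!is.null(peaks) && nrow(peaks))
    graphics::points(off(peaks), peaks$lat, pch = 2, cex = 1.2, lwd = 2)
  if (!is.null(truth) && nrow(truth))
    graphics::points(off(truth), truth$lat, pch = 3, cex = 1.2, lwd = 2)
  invisible(NULL)
}
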