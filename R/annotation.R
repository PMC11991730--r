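#' Daily start-to-end displacement of a trajectory
#'
#' The quantity the labeling rule calls *speed*: the geodesic distance in
#' km between the first and last position fix of one vessel-day. Days with
#' displacement above 200 km are read as transit (label Unlikely); shorter
#' or looping days are candidate fishing days (label Unknown).
#'
#' @param fixes data.frame with columns `lat`, `lon`, ordered in time;
#'   at least two rows
#' @return displacement in km
#' @export
dailyDisplacement <- function(fixes) {
  n <- nrow(fixes)
  if (is.null(n) || n < 2L) stop("a trajectory day needs at least 2 fixes")
  geodesicKm(fixes$lat[1], fixes$lon[1], fixes$lat[n], fixes$lon[n])
}

#' Mean daily position of a trajectory
#'
#' Arithmetic mean of latitude and of longitude, the single point that
#' represents a vessel-day. Longitudes are unwrapped relative to the first
#' fix before averaging so a track straddling the antimeridian (179E and
#' 179W) averages to 180E, not 0E.
#'
#' @inheritParams dailyDisplacement
#' @return one-row data.frame with `lat`, `lon`
#' @export
meanDailyPosition <- function(fixes) {
  if (is.null(nrow(fixes)) || nrow(fixes) < 1L) stop("no fixes")
  ref <- fixes$lon[1]
  d <- (fixes$lon - ref + 180) %% 360 - 180
  data.frame(lat = mean(fixes$lat), lon = normalizeLon(ref + mean(d)))
}

#' Label catch records and trajectory days
#'
#' Applies the label partition: a catch record is `Good` when CPUE > 0 and
#' `Bad` when CPUE = 0; a trajectory day is `Unlikely` when its daily
#' start-to-end displacement exceeds 200 km (transit) and `Unknown`
#' otherwise, located at its mean daily position. Every record yields
#' exactly one label; Good/Bad only ever arise from catch, and
#' Unlikely/Unknown only from trajectories.
#'
#' @param catch catch data.frame (`date`, `lat`, `lon`, `cpue`), or `NULL`
#' @param trajectories trajectory data.frame (`vessel_id`, `date`,
#'   `timestamp`, `lat`, `lon`), or `NULL`
#' @param transitKm displacement threshold in km (default 200)
#' @return labeled instances: data.frame with columns `date`, `lat`,
#'   `lon`, `label` (factor Good/Bad/Unlikely/Unknown), `source`
#'   ("catch" or "trajectory")
#' @export
labelInstances <- function(catch = NULL, trajectories = NULL, transitKm = 200) {
  out <- list()
  if (!is.null(catch) && nrow(catch)) {
    out$catch <- data.frame(
      date = catch$date, lat = catch$lat, lon = normalizeLon(catch$lon),
      label = ifelse(catch$cpue > 0, "Good", "Bad"),
      source = "catch", stringsAsFactors = FALSE)
  }
  if (!is.null(trajectories) && nrow(trajectories)) {
    key <- interaction(trajectories$vessel_id, trajectories$date, drop = TRUE)
    days <- lapply(split(trajectories, key), function(tr) {
      pos <- meanDailyPosition(tr)
      disp <- dailyDisplacement(tr)
      data.frame(date = tr$date[1], lat = pos$lat, lon = pos$lon,
                 label = if (disp > transitKm) "Unlikely" else "Unknown",
                 source = "trajectory", stringsAsFactors = FALSE)
    })
    out$traj <- do.call(rbind, days)
  }
  if (!length(out))
    return(data.frame(date = as.Date(character()), lat = numeric(),
                      lon = numeric(), label = character(), source = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$label <- factor(res$label, levels = c("Good", "Bad", "Unlikely", "Unknown"))
  res
}

#' Habitat temperature filter for trajectory instances
#'
#' Drops trajectory-sourced instances lying on cells whose SST falls
#' outside the target species' thermal band (skipjack tuna: 19--26 C) or
#' on missing cells (land/cloud, zero-filled, hence outside the band).
#' Catch-sourced instances are trusted and pass through unchanged.
#'
#' @param instances labeled instances from [labelInstances()]
#' @param sst the day's [SSTMap-class]
#' @param tLow,tHigh band edges in degrees C (defaults 19 and 26)
#' @return the filtered instances
#' @export
habitatFilter <- function(instances, sst, tLow = 19, tHigh = 26) {
  if (!nrow(instances)) return(instances)
  keep <- rep(TRUE, nrow(instances))
  tr <- which(instances$source == "trajectory")
  if (length(tr)) {
    cells <- latlonToCell(instances$lat[tr], instances$lon[tr], sst@grid)
    ij <- cbind(cells$row, cells$col)
    v <- sst@values[ij]
    missing <- sst@mask[ij]
    keep[tr] <- !missing & v >= tLow & v <= tHigh
  }
  out <- instances[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gaussian kernel heatmap
#'
#' Places an unnormalized 2-D Gaussian `exp(-||p - p_t||^2 / (2 sigma^2))`
#' at each keypoint (pixel units) and combines multiple kernels by
#' pixelwise maximum, so each keypoint keeps peak height 1. Support is
#' truncated at 4 sigma (beyond that the kernel is below 3.4e-4, of no
#' consequence to training or peak detection) which also makes "non-zero
#' pixel" well defined for the confidence statistic.
#'
#' @param points data.frame with integer pixel columns `row`, `col`
#'   (may be empty)
#' @param dim integer `c(h, w)` raster size
#' @param sigma kernel sd in pixels (default 7)
#' @return an `h x w` matrix in `[0, 1]`
#' @export
gaussianKernelHeatmap <- function(points, dim, sigma = 7) {
  if (sigma <= 0) stop("sigma must be positive")
  h <- dim[1]; w <- dim[2]
  out <- matrix(0, h, w)
  if (is.null(points) || nrow(points) == 0L) return(out)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  cut2 <- (4 * sigma)^2
  for (k in seq_len(nrow(points))) {
    d2 <- (rows - points$row[k])^2 + (cols - points$col[k])^2
    ker <- exp(-d2 / (2 * sigma^2))
    ker[d2 > cut2] <- 0
    out <- pmax(out, ker)
  }
  out
}

# Map labeled instances to heatmap pixel coordinates.
instancePixels <- function(instances, grid, stride) {
  cells <- latlonToCell(instances$lat, instances$lon, grid)
  cellToHeatmapPixel(cells$row, cells$col, stride)
}

#' Build a day's three-channel ground-truth heatmap
#'
#' Converts one day's labeled instances (a single source type) into a
#' [Heatmap3-class] with channels Good, Bad, Unlikely on the model output
#' raster. The label-to-channel map is: catch days put Good labels on the
#' Good channel and Bad labels on the Bad channel (Unlikely stays zero);
#' trajectory days put Unknown labels on BOTH the Good and the Bad channel
#' (they cannot be told apart) and Unlikely labels on the Unlikely
#' channel. Mixing catch and trajectory instances in one call is an error:
#' the two phases train on separate heatmap types.
#'
#' @param instances labeled instances of one date and one source
#' @param grid the full-resolution [GridSpec-class]
#' @param stride model output stride (grid cells per heatmap pixel)
#' @param sigma Gaussian sd in heatmap pixels (default 7)
#' @param date the day; defaults to the instances' date
#' @param source `"catch"` or `"trajectory"`; only needed when
#'   `instances` is empty (an all-zero heatmap still has a provenance)
#' @return a `Heatmap3` with catch or trajectory provenance
#' @export
buildHeatmap <- function(instances, grid, stride, sigma = 7, date = NULL,
                         source = NULL) {
  src <- unique(as.character(instances$source))
  if (length(src) > 1L)
    stop("instances mix catch and trajectory sources; build one heatmap per source")
  if (!length(src)) src <- if (is.null(source)) "catch" else source
  if (nrow(instances)) {
    if (length(unique(instances$date)) > 1L)
      stop("instances span multiple dates")
    if (is.null(date)) date <- instances$date[1]
  }
  if (is.null(date)) stop("date required for an empty instance set")
  dm <- heatmapDim(grid, stride)
  px <- if (nrow(instances)) instancePixels(instances, grid, stride) else
    data.frame(row = integer(), col = integer())
  chan <- function(lab) gaussianKernelHeatmap(px[instances$label %in% lab, , drop = FALSE],
                                              dm, sigma)
  if (identical(src, "catch")) {
    a <- array(0, c(dm, 3L))
    a[, , 1] <- chan("Good")
    a[, , 2] <- chan("Bad")
    prov <- "catch"
  } else {
    a <- array(0, c(dm, 3L))
    unk <- chan("Unknown")
    a[, , 1] <- unk
    a[, , 2] <- unk
    a[, , 3] <- chan("Unlikely")
    prov <- "trajectory"
  }
  new("Heatmap3", array = a, provenance = prov, grid = grid,
      stride = as.integer(stride), sigma = sigma, date = as.Date(date))
}

#' Merge a catch and a trajectory heatmap of one day
#'
#' Channel-wise pixel maximum of the two, used by the legacy baseline arm
#' that pre-trains on heatmaps drawing on both data sources at once.
#'
#' @param hmCatch,hmTraj [Heatmap3-class] objects of the same day/shape
#' @return a `Heatmap3` with provenance `"merged"`
#' @export
mergeHeatmaps <- function(hmCatch, hmTraj) {
  stopifnot(identical(dim(hmCatch@array), dim(hmTraj@array)))
  a <- pmax(hmCatch@array, hmTraj@array)
  new("Heatmap3", array = a, provenance = "merged", grid = hmCatch@grid,
      stride = hmCatch@stride, sigma = hmCatch@sigma, date = hmCatch@date)
}

#' @rdname buildHeatmap
#' @param x a `Heatmap3`
#' @export
heatmapArray <- function(x) x@array

#' @rdname buildHeatmap
#' @export
provenance <- function(x) x@provenance

#' @rdname buildHeatmap
#' @param channel `"Good"`, `"Bad"` or `"Unlikely"`
#' @export
heatmapChannel <- function(x, channel = c("Good", "Bad", "Unlikely")) {
  channel <- match.arg(channel)
  x@array[, , match(channel, c("Good", "Bad", "Unlikely"))]
}
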