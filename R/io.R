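#' Construct an SST map
#'
#' Wraps a numeric matrix as a [SSTMap-class] on a grid. `NA` cells are
#' treated as missing: they are recorded in the mask and filled with zero,
#' the form the model consumes. A mask may also be passed explicitly.
#'
#' @param values numeric matrix, `nRows(g) x nCols(g)`, degrees C; `NA`
#'   marks missing cells
#' @param grid a [GridSpec-class]
#' @param date the day (`Date` or coercible)
#' @param mask optional logical matrix of missing cells
#' @return a `SSTMap`
#' @export
sstMap <- function(values, grid, date, mask = NULL) {
  if (!identical(dim(values), c(grid@nRows, grid@nCols)))
    stop(sprintf("values is %dx%d but grid expects %dx%d",
                 nrow(values), ncol(values), grid@nRows, grid@nCols))
  if (is.null(mask)) mask <- is.na(values)
  mask <- mask | is.na(values)
  values[mask] <- 0
  new("SSTMap", values = values, mask = mask, grid = grid,
      date = as.Date(date))
}

#' @rdname sstMap
#' @param x a `SSTMap`
#' @export
sstValues <- function(x) x@values

#' @rdname sstMap
#' @export
sstMask <- function(x) x@mask

#' Grid accessor
#' @param x an object carrying a [GridSpec-class] (`SSTMap` or `Heatmap3`)
#' @return the `GridSpec`
#' @export
gridOf <- function(x) x@grid

#' Read / write an SST raster as plain text
#'
#' Rasters interchange as headerless comma-separated matrices, one row of
#' the grid per line, north first; empty fields or `NA` are missing cells.
#' The reader asserts that the file's dimensions match the grid.
#'
#' @param path file path
#' @param grid a [GridSpec-class] the raster must conform to
#' @param date the day the raster belongs to
#' @return `readSstCsv`: a [SSTMap-class]; `writeSstCsv`: `path`, invisibly
#' @export
readSstCsv <- function(path, grid, date) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(grid@nRows, grid@nCols)))
    stop(sprintf("raster %s is %dx%d, grid expects %dx%d", path,
                 nrow(m), ncol(m), grid@nRows, grid@nCols))
  sstMap(m, grid, date)
}

#' @rdname readSstCsv
#' @param x a [SSTMap-class]
#' @export
writeSstCsv <- function(x, path) {
  v <- x@values
  v[x@mask] <- NA
  utils::write.table(v, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write catch records
#'
#' Catch logs are tabular: columns `date`, `lat`, `lon`, `cpue` (catch per
#' unit effort, non-negative; only its dichotomy `>0` vs `=0` carries label
#' information).
#'
#' @param path CSV file path
#' @return a data.frame with columns date (`Date`), lat, lon, cpue
#' @export
readCatchCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lat", "lon", "cpue")
  if (!all(need %in% names(d)))
    stop("catch CSV must have columns: ", paste(need, collapse = ", "))
  d$date <- as.Date(d$date)
  if (any(d$cpue < 0)) stop("cpue must be non-negative")
  d$lon <- normalizeLon(d$lon)
  d[need]
}

#' @rdname readCatchCsv
#' @param x a catch data.frame
#' @export
writeCatchCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read / write vessel trajectories
#'
#' Daily trajectory fixes: columns `vessel_id`, `date`, `timestamp`, `lat`,
#' `lon`, ordered by timestamp within each vessel-day.
#'
#' @param path CSV file path
#' @return a data.frame with those columns, fixes sorted within vessel-day
#' @export
readTrajectoryCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "date", "timestamp", "lat", "lon")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  d$date <- as.Date(d$date)
  d$lon <- normalizeLon(d$lon)
  d <- d[order(d$vessel_id, d$date, d$timestamp), need]
  rownames(d) <- NULL
  d
}

#' @rdname readTrajectoryCsv
#' @param x a trajectory data.frame
#' @export
writeTrajectoryCsv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A run config carries the grid frame (`grid:` keys `lat_min`, `lat_max`,
#' `lon_start`, `lon_extent`, `cell_deg`), optional `world:`, `phase:` and
#' `loss:` sections overriding [worldConfig()], [phaseConfig()] and
#' [lossConfig()] defaults, and a `seed`.
#'
#' @param path YAML file
#' @return a list with elements `grid`, `world`, `phase`, `loss`, `seed`
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  grid <- NULL
  if (!is.null(y$grid))
    grid <- gridSpec(latMin = y$grid$lat_min, latMax = y$grid$lat_max,
                     lonStart = y$grid$lon_start, lonExtent = y$grid$lon_extent,
                     cellDeg = if (is.null(y$grid$cell_deg)) 0.25 else y$grid$cell_deg)
  world <- do.call(worldConfig, c(if (!is.null(grid)) list(grid = grid),
                                  y$world))
  phase <- do.call(phaseConfig, if (is.null(y$phase)) list() else y$phase)
  loss <- do.call(lossConfig, if (is.null(y$loss)) list() else y$loss)
  list(grid = world$grid, world = world, phase = phase, loss = loss,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

#' Persist / load a heatmap with its sidecar manifest
#'
#' Writes the three channels as headerless CSV matrices next to a YAML
#' manifest recording date, provenance, grid frame, stride and sigma, so
#' a heatmap is fully reconstructable.
#'
#' @param hm a [Heatmap3-class]
#' @param path base path (no extension); writes `<path>_good.csv`,
#'   `<path>_bad.csv`, `<path>_unlikely.csv` and `<path>.yaml`
#' @return `path` (writer) or a `Heatmap3` (reader)
#' @export
writeHeatmap <- function(hm, path) {
  ch <- c("good", "bad", "unlikely")
  for (k in 1:3)
    utils::write.table(hm@array[, , k], paste0(path, "_", ch[k], ".csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  g <- hm@grid
  yaml::write_yaml(list(date = format(hm@date), provenance = hm@provenance,
                        stride = hm@stride, sigma = hm@sigma,
                        grid = list(lat_min = g@latMin, lat_max = g@latMax,
                                    lon_start = g@lonStart,
                                    lon_extent = g@lonExtent,
                                    cell_deg = g@cellDeg)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeHeatmap
#' @export
readHeatmap <- function(path) {
  m <- yaml::read_yaml(paste0(path, ".yaml"))
  g <- gridSpec(latMin = m$grid$lat_min, latMax = m$grid$lat_max,
                lonStart = m$grid$lon_start, lonExtent = m$grid$lon_extent,
                cellDeg = m$grid$cell_deg)
  ch <- lapply(c("good", "bad", "unlikely"), function(s)
    as.matrix(utils::read.table(paste0(path, "_", s, ".csv"), sep = ",")))
  a <- array(0, c(dim(ch[[1]]), 3L))
  for (k in 1:3) a[, , k] <- ch[[k]]
  new("Heatmap3", array = a, provenance = m$provenance, grid = g,
      stride = as.integer(m$stride), sigma = as.numeric(m$sigma),
      date = as.Date(m$date))
}

#' Checkpoint a model with its architecture manifest
#'
#' Detector and confidence-net models are lists of `cfg` (the
#' architecture manifest) and `params`; they round-trip through RDS.
#'
#' @param model a detector or confidence-net model
#' @param path file path (`.rds`)
#' @return `path` (writer) or the model (reader)
#' @export
saveModel <- function(model, path) {
  if (!inherits(model, c("fgDetector", "fgConfidenceNet")))
    stop("not a fishgrounds model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("fgDetector", "fgConfidenceNet")))
    stop("file does not contain a fishgrounds model")
  model
}
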