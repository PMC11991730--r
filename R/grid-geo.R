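#' Construct a geographic raster frame
#'
#' Builds a [GridSpec-class] from its bounds. `nRows`/`nCols` are derived
#' from the bounds and cell size; the bounds must be whole multiples of
#' `cellDeg` apart. The full-scale skipjack study frame (20N--50N, 130E--150W at
#' 0.25 deg, 121 x 321 cells) is available as [skipjackGrid()].
#'
#' @param latMin,latMax latitude bounds in degrees N (cell centers of the
#'   last and first row)
#' @param lonStart longitude of column 1 in degrees (any representation;
#'   normalized to (-180, 180])
#' @param lonExtent eastward span in degrees, may cross the antimeridian
#' @param cellDeg cell size in degrees (default 0.25)
#' @return a `GridSpec`
#' @examples
#' g <- gridSpec(latMin = 30, latMax = 39.75, lonStart = 140,
#'               lonExtent = 15.75, cellDeg = 0.25)
#' g
#' @export
gridSpec <- function(latMin, latMax, lonStart, lonExtent, cellDeg = 0.25) {
  nr <- round((latMax - latMin) / cellDeg)
  nc <- round(lonExtent / cellDeg)
  if (abs(nr * cellDeg - (latMax - latMin)) > 1e-9)
    stop("latitude span is not a whole multiple of cellDeg")
  if (abs(nc * cellDeg - lonExtent) > 1e-9)
    stop("lonExtent is not a whole multiple of cellDeg")
  new("GridSpec", latMax = latMax, latMin = latMin,
      lonStart = normalizeLon(lonStart), lonExtent = lonExtent,
      cellDeg = cellDeg, nRows = as.integer(nr + 1), nCols = as.integer(nc + 1))
}

#' The North Pacific skipjack study frame
#'
#' 20N--50N, 130E--150W at 0.25 degrees: 121 rows x 321 columns, crossing
#' the antimeridian.
#' @return a [GridSpec-class]
#' @export
skipjackGrid <- function() {
  gridSpec(latMin = 20, latMax = 50, lonStart = 130, lonExtent = 80,
           cellDeg = 0.25)
}

#' @rdname gridSpec
#' @param g a `GridSpec`
#' @export
nRows <- function(g) g@nRows

#' @rdname gridSpec
#' @export
nCols <- function(g) g@nCols

#' Normalize longitudes to (-180, 180]
#'
#' @param lon longitudes in degrees, any representation
#' @return longitudes in (-180, 180]
#' @examples normalizeLon(210) # -150
#' @export
normalizeLon <- function(lon) {
  x <- (lon + 180) %% 360
  ifelse(x == 0, 180, x - 180)
}

# Eastward offset of lon from the grid origin, in degrees [0, 360).
lonOffset <- function(lon, g) (lon - g@lonStart) %% 360

# Round half toward the LOWER index (documented tie policy).
roundHalfDown <- function(x) ceiling(x - 0.5)

#' Convert a geographic point to raster indices
#'
#' Maps (lat, lon) to the nearest cell center of a [GridSpec-class].
#' Indices are 1-based: row 1 is the northernmost row (`latMax`), column 1
#' is `lonStart`. The eastward offset is taken modulo 360, so frames that
#' cross the antimeridian are contiguous. Exact half-cell ties round toward
#' the lower index.
#'
#' @param lat,lon point coordinates in degrees (vectors recycle together)
#' @param g a [GridSpec-class]
#' @return a data.frame with integer columns `row`, `col`
#' @examples
#' latlonToCell(50, 130, skipjackGrid())  # row 1, col 1
#' @export
latlonToCell <- function(lat, lon, g) {
  lon <- normalizeLon(lon)
  rowf <- (g@latMax - lat) / g@cellDeg
  colf <- lonOffset(lon, g) / g@cellDeg
  row <- roundHalfDown(rowf) + 1L
  col <- roundHalfDown(colf) + 1L
  bad <- row < 1L | row > g@nRows
  if (any(bad))
    stop(sprintf("latitude out of grid extent: %s", paste(lat[bad], collapse = ", ")))
  bad <- col < 1L | col > g@nCols
  if (any(bad))
    stop(sprintf("longitude out of grid extent: %s", paste(lon[bad], collapse = ", ")))
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Convert raster indices to the cell-center coordinates
#'
#' Inverse of [latlonToCell()] at cell centers (round-trip identity holds
#' on every cell).
#'
#' @param row,col 1-based raster indices (vectors recycle together)
#' @param g a [GridSpec-class]
#' @return a data.frame with columns `lat`, `lon` (lon in (-180, 180])
#' @export
cellToLatlon <- function(row, col, g) {
  if (any(row < 1L | row > g@nRows)) stop("row index out of range")
  if (any(col < 1L | col > g@nCols)) stop("col index out of range")
  data.frame(lat = g@latMax - (row - 1) * g@cellDeg,
             lon = normalizeLon(g@lonStart + (col - 1) * g@cellDeg))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371 km. Symmetric,
#' non-negative, zero iff the points coincide, and invariant to the
#' longitude representation (210E equals -150E), so it is safe across the
#' antimeridian. Spherical error is far below the 200-km decision
#' threshold the evaluation uses.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized)
#' @return distance(s) in km
#' @examples
#' geodesicKm(0, 0, 1, 0)  # ~111.19 km per degree of latitude
#' @export
geodesicKm <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Convert knots to km/h
#'
#' One knot is 1.852 km/h. The evaluation threshold of 200 km/day stems
#' from a vessel cruising 14 knots (26 km/h, rounded) for about eight
#' hours.
#' @param knots speed in knots
#' @return speed in km/h
#' @export
knotsToKmh <- function(knots) knots * 1.852

#' Heatmap raster dimensions for a grid and stride
#'
#' The model output raster downsamples the grid by `stride` (ceiling
#' division), one heatmap pixel per `stride x stride` block of cells.
#' @param g a [GridSpec-class]
#' @param stride integer downsampling factor
#' @return integer vector `c(h, w)`
#' @export
heatmapDim <- function(g, stride) {
  as.integer(ceiling(c(g@nRows, g@nCols) / stride))
}

# Grid cell (1-based, possibly fractional) -> heatmap pixel (1-based int).
cellToHeatmapPixel <- function(row, col, stride) {
  data.frame(row = as.integer(floor((row - 1) / stride) + 1),
             col = as.integer(floor((col - 1) / stride) + 1))
}

# Heatmap pixel -> geographic coordinates of the block center.
heatmapPixelToLatlon <- function(row, col, g, stride) {
  gr <- (row - 1) * stride + (stride + 1) / 2
  gc <- (col - 1) * stride + (stride + 1) / 2
  gr <- pmin(gr, g@nRows); gc <- pmin(gc, g@nCols)
  data.frame(lat = g@latMax - (gr - 1) * g@cellDeg,
             lon = normalizeLon(g@lonStart + (gc - 1) * g@cellDeg))
}
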