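#' @import methods
NULL

#' Geographic raster frame
#'
#' A `GridSpec` fixes the regular latitude/longitude raster on which SST
#' fields and heatmaps live. Rows run north to south (row 1 is `latMax`,
#' image convention); columns run eastward from `lonStart` for `lonExtent`
#' degrees, which may cross the antimeridian (the study frame
#' 130E--150W does). Longitudes are stored normalized to (-180, 180] and
#' column offsets are computed modulo 360, so a frame spanning 180 degrees
#' longitude is contiguous.
#'
#' @slot latMax northernmost row's latitude (degrees N, row 1)
#' @slot latMin southernmost row's latitude (degrees N, last row)
#' @slot lonStart longitude of column 1 (degrees, (-180, 180])
#' @slot lonExtent eastward span in degrees (0, 360)
#' @slot cellDeg cell size in degrees (same for both axes)
#' @slot nRows,nCols raster dimensions, consistent with the bounds
#'
#' @seealso [gridSpec()], [latlonToCell()], [cellToLatlon()]
#' @export
setClass("GridSpec",
  representation(
    latMax = "numeric", latMin = "numeric",
    lonStart = "numeric", lonExtent = "numeric",
    cellDeg = "numeric", nRows = "integer", nCols = "integer"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (object@latMax <= object@latMin) msg <- c(msg, "latMax must exceed latMin")
  if (object@cellDeg <= 0) msg <- c(msg, "cellDeg must be positive")
  if (object@lonExtent <= 0 || object@lonExtent >= 360)
    msg <- c(msg, "lonExtent must lie in (0, 360)")
  if (object@lonStart <= -180 || object@lonStart > 180)
    msg <- c(msg, "lonStart must be normalized to (-180, 180]")
  if (object@nRows != round((object@latMax - object@latMin) / object@cellDeg) + 1L)
    msg <- c(msg, "nRows inconsistent with latitude bounds and cellDeg")
  if (object@nCols != round(object@lonExtent / object@cellDeg) + 1L)
    msg <- c(msg, "nCols inconsistent with lonExtent and cellDeg")
  if (length(msg)) msg else TRUE
})

#' One day's sea surface temperature field
#'
#' Holds a single daily SST raster on a [GridSpec-class] frame. Missing
#' cells (land, cloud gaps) are flagged in `mask` and their values filled
#' with zero, the convention the model input uses.
#'
#' @slot values numeric matrix `nRows x nCols`, degrees C, missing filled 0
#' @slot mask logical matrix, `TRUE` where the cell is missing
#' @slot grid the [GridSpec-class] frame
#' @slot date the day, as a `Date`
#' @export
setClass("SSTMap",
  representation(values = "matrix", mask = "matrix", grid = "GridSpec",
                 date = "Date")
)

setValidity("SSTMap", function(object) {
  g <- object@grid
  msg <- character()
  if (!identical(dim(object@values), c(g@nRows, g@nCols)))
    msg <- c(msg, "values dimensions do not match the grid")
  if (!identical(dim(object@mask), dim(object@values)))
    msg <- c(msg, "mask dimensions do not match values")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite (fill missing with 0 and set mask)")
  if (any(object@values[object@mask] != 0)) msg <- c(msg, "masked cells must be zero-filled")
  if (length(msg)) msg else TRUE
})

#' Three-channel fishing-ground heatmap
#'
#' Ground-truth or predicted heatmap with channels ordered Good, Bad,
#' Unlikely, on the model's output raster (the [GridSpec-class] frame
#' downsampled by `stride`). Ground-truth values lie in [0, 1] and come
#' from Gaussian kernels of width `sigma` (heatmap pixels) placed at
#' labeled instances:
#' catch-provenance maps have an identically zero Unlikely channel, and
#' trajectory-provenance maps have identical Good and Bad channels (the
#' Unknown label feeds both). Predicted maps are unconstrained real fields.
#'
#' @slot array numeric `h x w x 3` array, channels Good/Bad/Unlikely
#' @slot provenance `"catch"`, `"trajectory"`, `"merged"` or `"predicted"`
#' @slot grid the full-resolution [GridSpec-class] frame
#' @slot stride integer downsampling factor from grid to heatmap pixels
#' @slot sigma Gaussian kernel sd in heatmap pixels (`NA` for predictions)
#' @slot date the day
#' @export
setClass("Heatmap3",
  representation(array = "array", provenance = "character",
                 grid = "GridSpec", stride = "integer", sigma = "numeric",
                 date = "Date")
)

setValidity("Heatmap3", function(object) {
  a <- object@array
  msg <- character()
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    msg <- c(msg, "array must be h x w x 3")
  if (!object@provenance %in% c("catch", "trajectory", "merged", "predicted"))
    msg <- c(msg, "provenance must be catch, trajectory, merged or predicted")
  if (object@stride < 1L) msg <- c(msg, "stride must be >= 1")
  ex <- heatmapDim(object@grid, object@stride)
  if (!identical(dim(a)[1:2], ex))
    msg <- c(msg, sprintf("array is %dx%d but grid/stride imply %dx%d",
                          dim(a)[1], dim(a)[2], ex[1], ex[2]))
  if (object@provenance != "predicted") {
    if (any(a < 0 | a > 1)) msg <- c(msg, "ground-truth heatmap values must lie in [0,1]")
    if (object@provenance == "catch" && any(a[, , 3] != 0))
      msg <- c(msg, "catch heatmaps must have an all-zero Unlikely channel")
    if (object@provenance == "trajectory" && any(a[, , 1] != a[, , 2]))
      msg <- c(msg, "trajectory heatmaps must have identical Good and Bad channels")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GridSpec-class pretty-printer
#' @param object a `GridSpec`
#' @export
setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells at %g deg\n", object@nRows, object@nCols,
              object@cellDeg))
  cat(sprintf("  lat %g..%gN (north to south), lon from %gE spanning %g deg%s\n",
              object@latMax, object@latMin, object@lonStart, object@lonExtent,
              if (object@lonStart + object@lonExtent > 180) " (crosses antimeridian)" else ""))
})

#' @describeIn SSTMap-class pretty-printer
#' @param object a `SSTMap`
#' @export
setMethod("show", "SSTMap", function(object) {
  v <- object@values[!object@mask]
  cat(sprintf("SSTMap %s: %d x %d, %.1f..%.1f C, %d missing cells\n",
              format(object@date), nrow(object@values), ncol(object@values),
              min(v), max(v), sum(object@mask)))
})

#' @describeIn Heatmap3-class pretty-printer
#' @param object a `Heatmap3`
#' @export
setMethod("show", "Heatmap3", function(object) {
  d <- dim(object@array)
  cat(sprintf("Heatmap3 [%s] %s: %d x %d, channel maxima G=%.3f B=%.3f U=%.3f\n",
              object@provenance, format(object@date), d[1], d[2],
              max(object@array[, , 1]), max(object@array[, , 2]),
              max(object@array[, , 3])))
})
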