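#' Target-network configuration
#'
#' The target network is a heatmap regressor: it maps a single-channel SST
#' raster to a 3-channel (Good/Bad/Unlikely) heatmap at `1/stride` the
#' input resolution. The method is backbone-agnostic; the default backbone
#' `tiny_cnn` is a small fully convolutional net (3x3 conv-ReLU blocks with
#' 2x2 max-pool downsampling and a 1x1 linear head, well under 50k
#' parameters) sized for CPU training. Any drop-in backbone honoring this
#' contract (same forward/backward signatures) can be plugged in via
#' `backbone`.
#'
#' @param inputDim integer `c(rows, cols)` of the SST input
#' @param stride downsampling factor, one of 1, 2, 4
#' @param channels widths of the first and later conv blocks
#' @param backbone backbone id; only `"tiny_cnn"` ships
#' @param standardize standardize each SST map to zero mean / unit variance
#'   over non-missing cells before input (default `TRUE`; set `FALSE` for
#'   raw degrees C)
#' @return a `DetectorConfig` (list)
#' @export
detectorConfig <- function(inputDim, stride = 4L, channels = c(8L, 16L),
                           backbone = "tiny_cnn", standardize = TRUE) {
  stride <- as.integer(stride)
  if (!stride %in% c(1L, 2L, 4L)) stop("stride must be 1, 2 or 4")
  if (backbone != "tiny_cnn") stop("unknown backbone: ", backbone)
  structure(list(inputDim = as.integer(inputDim), stride = stride,
                 outputDim = as.integer(ceiling(inputDim / stride)),
                 channels = as.integer(channels), backbone = backbone,
                 standardize = standardize),
            class = "DetectorConfig")
}

#' Initialize a target network
#'
#' He-normal weight init from the current RNG state (set a seed before
#' calling for reproducibility). The final 1x1 head is zero-initialized so
#' an untrained net predicts a flat zero heatmap.
#'
#' @param cfg a [detectorConfig()]
#' @return a detector model: list with `cfg` and `params`
#' @export
detectorInit <- function(cfg) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  params <- list(
    W1 = heInit(9L, c1, 9),        b1 = numeric(c1),
    W2 = heInit(9L * c1, c2, 9 * c1), b2 = numeric(c2),
    W3 = heInit(9L * c2, c2, 9 * c2), b3 = numeric(c2),
    W4 = matrix(0, c2, 3L),        b4 = numeric(3L)
  )
  structure(list(cfg = cfg, params = params), class = "fgDetector")
}

#' @export
print.fgDetector <- function(x, ...) {
  cat(sprintf("fishgrounds detector [%s]: %dx%d -> %dx%dx3 (stride %d), %d parameters\n",
              x$cfg$backbone, x$cfg$inputDim[1], x$cfg$inputDim[2],
              x$cfg$outputDim[1], x$cfg$outputDim[2], x$cfg$stride,
              nParams(x$params)))
  invisible(x)
}

# Zero-pad a prepared input up to a stride multiple (bottom/right), so
# pooling always sees even dims and output dims equal ceiling(input/stride).
padToStride <- function(x, stride) {
  H <- nrow(x); W <- ncol(x)
  Ht <- as.integer(ceiling(H / stride) * stride)
  Wt <- as.integer(ceiling(W / stride) * stride)
  if (Ht == H && Wt == W) return(x)
  out <- matrix(0, Ht, Wt)
  out[seq_len(H), seq_len(W)] <- x
  out
}

# Forward pass on one prepared input matrix (H x W). Returns prediction
# (h x w x 3) and caches for backprop.
detectorForward <- function(model, x) {
  p <- model$params
  stride <- model$cfg$stride
  x <- padToStride(x, stride)
  a0 <- array(x, c(dim(x), 1L))
  f1 <- conv3Forward(a0, p$W1, p$b1); r1 <- reluForward(f1$out)
  h <- r1$out
  pl1 <- NULL
  if (stride >= 2L) { pl1 <- pool2Forward(h); h <- pl1$out }
  f2 <- conv3Forward(h, p$W2, p$b2); r2 <- reluForward(f2$out)
  h <- r2$out
  pl2 <- NULL
  if (stride == 4L) { pl2 <- pool2Forward(h); h <- pl2$out }
  f3 <- conv3Forward(h, p$W3, p$b3); r3 <- reluForward(f3$out)
  f4 <- conv1Forward(r3$out, p$W4, p$b4)
  list(pred = f4$out,
       cache = list(f1 = f1, r1 = r1, pl1 = pl1, f2 = f2, r2 = r2,
                    pl2 = pl2, f3 = f3, r3 = r3, f4 = f4))
}

# Backprop of dL/dpred through the detector; returns gradients shaped
# like model$params.
detectorBackward <- function(model, cache, dpred) {
  p <- model$params
  b4 <- conv1Backward(dpred, cache$f4, p$W4)
  d <- reluBackward(b4$dx, cache$r3)
  b3 <- conv3Backward(d, cache$f3, p$W3)
  d <- b3$dx
  if (!is.null(cache$pl2)) d <- pool2Backward(d, cache$pl2)
  d <- reluBackward(d, cache$r2)
  b2 <- conv3Backward(d, cache$f2, p$W2)
  d <- b2$dx
  if (!is.null(cache$pl1)) d <- pool2Backward(d, cache$pl1)
  d <- reluBackward(d, cache$r1)
  b1 <- conv3Backward(d, cache$f1, p$W1)
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       W3 = b3$dW, b3 = b3$db, W4 = b4$dW, b4 = b4$db)
}

# Batched forward over a list of prepared input matrices, in the
# row-stacked layout (see nn.R): pred is an (h*w*B) x 3 matrix, rows
# pixel-major within sample blocks. Numerically equal to per-sample
# detectorForward.
detectorForwardB <- function(model, xs) {
  p <- model$params
  stride <- model$cfg$stride
  B <- length(xs)
  x1 <- padToStride(xs[[1]], stride)
  H <- nrow(x1); W <- ncol(x1)
  X <- matrix(unlist(lapply(xs, function(x) padToStride(x, stride)),
                     use.names = FALSE), ncol = 1L)
  f1 <- conv3ForwardM(X, H, W, B, p$W1, p$b1); r1 <- reluForward(f1$out)
  h <- r1$out
  pl1 <- NULL
  if (stride >= 2L) {
    pl1 <- pool2ForwardM(h, H, W, B); h <- pl1$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  f2 <- conv3ForwardM(h, H, W, B, p$W2, p$b2); r2 <- reluForward(f2$out)
  h <- r2$out
  pl2 <- NULL
  if (stride == 4L) {
    pl2 <- pool2ForwardM(h, H, W, B); h <- pl2$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  f3 <- conv3ForwardM(h, H, W, B, p$W3, p$b3); r3 <- reluForward(f3$out)
  pred <- r3$out %*% p$W4
  pred <- pred + rep(p$b4, each = nrow(pred))
  list(pred = pred, h = H, w = W, B = B,
       cache = list(f1 = f1, r1 = r1, pl1 = pl1, f2 = f2, r2 = r2,
                    pl2 = pl2, f3 = f3, r3 = r3))
}

# Batched backprop; dpred is (h*w*B) x 3. Parameter gradients come back
# summed over the batch.
detectorBackwardB <- function(model, cache, dpred) {
  p <- model$params
  dW4 <- crossprod(cache$r3$out, dpred)
  db4 <- colSums(dpred)
  d <- tcrossprod(dpred, p$W4)
  d <- reluBackward(d, cache$r3)
  b3 <- conv3BackwardM(d, cache$f3, p$W3)
  d <- b3$dx
  if (!is.null(cache$pl2)) d <- pool2BackwardM(d, cache$pl2)
  d <- reluBackward(d, cache$r2)
  b2 <- conv3BackwardM(d, cache$f2, p$W2)
  d <- b2$dx
  if (!is.null(cache$pl1)) d <- pool2BackwardM(d, cache$pl1)
  d <- reluBackward(d, cache$r1)
  b1 <- conv3BackwardM(d, cache$f1, p$W1, needDx = FALSE)
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       W3 = b3$dW, b3 = b3$db, W4 = dW4, b4 = db4)
}

#' Prepare an SST map as network input
#'
#' Optionally standardizes the field to zero mean and unit variance over
#' non-missing cells (missing cells stay 0), which stabilizes training of
#' the small nets; raw degrees C are used when the detector config says
#' `standardize = FALSE`.
#'
#' @param sst a [SSTMap-class]
#' @param standardize logical
#' @return a plain numeric matrix
#' @export
prepareInput <- function(sst, standardize = TRUE) {
  v <- sst@values
  if (standardize) {
    ok <- !sst@mask
    mu <- mean(v[ok])
    sd0 <- stats::sd(v[ok])
    if (!is.finite(sd0) || sd0 < 1e-12) sd0 <- 1
    v[ok] <- (v[ok] - mu) / sd0
    v[!ok] <- 0
  }
  v
}

#' Predict a heatmap for one SST map
#'
#' Runs the target network on a prepared SST input and wraps the 3-channel
#' output as a predicted [Heatmap3-class]. Deterministic given the
#' weights.
#'
#' @param sst a [SSTMap-class] on the grid the model was configured for
#' @param model a detector from [detectorInit()] (possibly trained)
#' @return a `Heatmap3` with provenance `"predicted"`
#' @export
predictHeatmap <- function(sst, model) {
  cfg <- model$cfg
  if (!identical(dim(sst@values), cfg$inputDim))
    stop(sprintf("SST map is %dx%d but the detector expects %dx%d",
                 nrow(sst@values), ncol(sst@values),
                 cfg$inputDim[1], cfg$inputDim[2]))
  x <- prepareInput(sst, cfg$standardize)
  pred <- detectorForward(model, x)$pred
  new("Heatmap3", array = pred, provenance = "predicted", grid = sst@grid,
      stride = cfg$stride, sigma = NA_real_, date = sst@date)
}

#' Loss configuration
#'
#' `"l2"` is the default squared-error heatmap loss. `"hinge_mix"` blends
#' it with a one-sided hinge that only penalizes under-detection,
#' `L = alpha * L2 + (1 - alpha) * LH`; small `alpha` pushes the model to
#' emit more peaks.
#'
#' @param kind `"l2"` or `"hinge_mix"`
#' @param alpha mixing weight in `[0, 1]` (hinge_mix only)
#' @return a `LossConfig` (list)
#' @export
lossConfig <- function(kind = c("l2", "hinge_mix"), alpha = 0.5) {
  kind <- match.arg(kind)
  if (kind == "hinge_mix" && (alpha < 0 || alpha > 1))
    stop("alpha must lie in [0, 1]")
  structure(list(kind = kind, alpha = if (kind == "l2") 1 else alpha),
            class = "LossConfig")
}

#' Heatmap losses
#'
#' `l2Loss` is `0.5 * sum((pred - truth)^2)` over all channels and pixels.
#' `hingeLoss` is `sum(ReLU(truth - pred))`: it penalizes only
#' under-detection, so any over-prediction is free. `combinedLoss` is the
#' convex blend `alpha * L2 + (1 - alpha) * LH`.
#'
#' @param pred,truth numeric arrays of identical shape
#' @param alpha mixing weight in `[0, 1]`
#' @return a non-negative scalar
#' @export
l2Loss <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  0.5 * sum((pred - truth)^2)
}

#' @rdname l2Loss
#' @export
hingeLoss <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  sum(pmax(truth - pred, 0))
}

#' @rdname l2Loss
#' @export
combinedLoss <- function(pred, truth, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  alpha * l2Loss(pred, truth) + (1 - alpha) * hingeLoss(pred, truth)
}

# Loss value and gradient wrt pred under a LossConfig.
lossValue <- function(pred, truth, loss) {
  if (loss$kind == "l2") l2Loss(pred, truth)
  else combinedLoss(pred, truth, loss$alpha)
}

lossGrad <- function(pred, truth, loss) {
  if (loss$kind == "l2") return(pred - truth)
  loss$alpha * (pred - truth) + (1 - loss$alpha) * (-(truth > pred))
}
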