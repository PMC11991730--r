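#' Ground-truth confidence of a weak label
#'
#' Scores how well one day's trajectory-derived (weak) heatmap agrees with
#' the catch-derived (strong) heatmap of the same day, on the Good
#' channel:
#' \deqn{c = 1 - \min(w_{count} \sum_{ij} ReLU(y_{ij} - \tilde y_{ij}),\ 1),
#'   \quad w_{count} = 1/(n_{nonzero} + 1)}
#' where `y` is the catch Good channel, `ytilde` the trajectory Good
#' channel, and `n_nonzero` counts non-zero pixels of the weak channel.
#' Confidence falls when catch evidence lands where the weak label is
#' silent, and only in that direction: extra weak-label area never costs
#' (the catch map is assumed to under-cover the true grounds), and the
#' `w_count` factor favours samples with larger weak regions.
#'
#' @param y the day's catch [Heatmap3-class]
#' @param yWeak the day's trajectory [Heatmap3-class], same shape
#' @param tol pixels with value below `tol` count as zero (kernels are
#'   truncated, so exact zeros exist; default 1e-8)
#' @return confidence in `[0, 1]`
#' @export
confidenceTarget <- function(y, yWeak, tol = 1e-8) {
  if (y@provenance != "catch" || yWeak@provenance != "trajectory")
    stop("confidenceTarget expects a catch heatmap and a trajectory heatmap")
  g <- y@array[, , 1]
  gw <- yWeak@array[, , 1]
  if (!identical(dim(g), dim(gw))) stop("heatmap shapes differ")
  nNonzero <- sum(gw > tol)
  wCount <- 1 / (nNonzero + 1)
  lhm <- min(wCount * sum(pmax(g - gw, 0)), 1)
  1 - lhm
}

#' Confidence-network configuration
#'
#' The confidence network scores an (SST map, weak heatmap) pair with a
#' single confidence logit. Topology: two input branches -- one for the
#' SST map (downsampled to heatmap resolution), one for the 3-channel weak
#' heatmap -- of two 3x3 stride-1 zero-padded conv layers each (ReLU),
#' flattened, concatenated, then a ReLU dense layer and a single linear
#' output unit. The sigmoid is applied only at inference.
#'
#' @param inputDim integer `c(h, w)`: the heatmap resolution both branches
#'   share
#' @param channels conv widths of the two layers per branch
#' @param hidden width of the dense head
#' @return a `ConfidenceNetConfig` (list)
#' @export
confidenceNetConfig <- function(inputDim, channels = c(8L, 16L), hidden = 64L) {
  stopifnot(all(channels > 0), hidden > 0)
  structure(list(inputDim = as.integer(inputDim),
                 channels = as.integer(channels), hidden = as.integer(hidden)),
            class = "ConfidenceNetConfig")
}

#' Initialize a confidence network
#'
#' He-normal init from the current RNG state.
#' @param cfg a [confidenceNetConfig()]
#' @return a confidence-net model: list with `cfg` and `params`
#' @export
confidenceNetInit <- function(cfg) {
  c1 <- cfg$channels[1]; c2 <- cfg$channels[2]
  flat <- prod(cfg$inputDim) * c2
  params <- list(
    A1 = heInit(9L, c1, 9),            a1 = numeric(c1),
    A2 = heInit(9L * c1, c2, 9 * c1),  a2 = numeric(c2),
    B1 = heInit(27L, c1, 27),          bb1 = numeric(c1),
    B2 = heInit(9L * c1, c2, 9 * c1),  bb2 = numeric(c2),
    Wh = heInit(2L * flat, cfg$hidden, 2 * flat), bh = numeric(cfg$hidden),
    Wo = heInit(cfg$hidden, 1L, cfg$hidden),      bo = numeric(1L)
  )
  structure(list(cfg = cfg, params = params), class = "fgConfidenceNet")
}

#' @export
print.fgConfidenceNet <- function(x, ...) {
  cat(sprintf("fishgrounds confidence net: %dx%d inputs, %d parameters\n",
              x$cfg$inputDim[1], x$cfg$inputDim[2], nParams(x$params)))
  invisible(x)
}

# Block mean downsampling of a matrix by an integer stride (ragged edge
# blocks average over fewer cells).
blockMean <- function(x, stride) {
  if (stride == 1L) return(x)
  rg <- floor((seq_len(nrow(x)) - 1) / stride)
  cg <- floor((seq_len(ncol(x)) - 1) / stride)
  s <- rowsum(x, rg)
  s <- t(rowsum(t(s), cg))
  dimnames(s) <- NULL
  s / outer(tabulate(rg + 1L), tabulate(cg + 1L))
}

# Forward: xs = h x w SST matrix (already downsampled/standardized),
# hm = h x w x 3 weak heatmap. Returns logit and caches.
confNetForward <- function(model, xs, hm) {
  p <- model$params
  a0 <- array(xs, c(dim(xs), 1L))
  fa1 <- conv3Forward(a0, p$A1, p$a1); ra1 <- reluForward(fa1$out)
  fa2 <- conv3Forward(ra1$out, p$A2, p$a2); ra2 <- reluForward(fa2$out)
  fb1 <- conv3Forward(hm, p$B1, p$bb1); rb1 <- reluForward(fb1$out)
  fb2 <- conv3Forward(rb1$out, p$B2, p$bb2); rb2 <- reluForward(fb2$out)
  feat <- c(as.vector(ra2$out), as.vector(rb2$out))
  fh <- denseForward(feat, p$Wh, p$bh); rh <- reluForward(fh$out)
  fo <- denseForward(rh$out, p$Wo, p$bo)
  list(logit = fo$out[1],
       cache = list(fa1 = fa1, ra1 = ra1, fa2 = fa2, ra2 = ra2,
                    fb1 = fb1, rb1 = rb1, fb2 = fb2, rb2 = rb2,
                    fh = fh, rh = rh, fo = fo, nA = length(ra2$out),
                    dA = dim(ra2$out), dB = dim(rb2$out)))
}

confNetBackward <- function(model, cache, dlogit) {
  p <- model$params
  bo <- denseBackward(dlogit, cache$fo, p$Wo)
  d <- reluBackward(bo$dx, cache$rh)
  bh <- denseBackward(d, cache$fh, p$Wh)
  dfeat <- bh$dx
  dA <- dfeat[seq_len(cache$nA)]; dim(dA) <- cache$dA
  dB <- dfeat[-seq_len(cache$nA)]; dim(dB) <- cache$dB
  dA <- reluBackward(dA, cache$ra2)
  ba2 <- conv3Backward(dA, cache$fa2, p$A2)
  da <- reluBackward(ba2$dx, cache$ra1)
  ba1 <- conv3Backward(da, cache$fa1, p$A1)
  dB <- reluBackward(dB, cache$rb2)
  bb2 <- conv3Backward(dB, cache$fb2, p$B2)
  db <- reluBackward(bb2$dx, cache$rb1)
  bb1 <- conv3Backward(db, cache$fb1, p$B1)
  list(A1 = ba1$dW, a1 = ba1$db, A2 = ba2$dW, a2 = ba2$db,
       B1 = bb1$dW, bb1 = bb1$db, B2 = bb2$dW, bb2 = bb2$db,
       Wh = bh$dW, bh = bh$db, Wo = bo$dW, bo = bo$db)
}

# Batched forward: xsList (h x w matrices), hmList (h x w x 3 arrays).
# Uses the row-stacked layout of nn.R; numerically equal to the
# per-sample forward.
confNetForwardB <- function(model, xsList, hmList) {
  p <- model$params
  B <- length(xsList)
  d <- dim(xsList[[1]])
  H <- d[1]; W <- d[2]; HW <- H * W
  XA <- matrix(unlist(lapply(xsList, as.vector), use.names = FALSE), ncol = 1L)
  XB <- matrix(0, HW * B, 3L)
  for (b in seq_len(B)) XB[(b - 1L) * HW + seq_len(HW), ] <-
    matrix(hmList[[b]], HW, 3L)
  fa1 <- conv3ForwardM(XA, H, W, B, p$A1, p$a1); ra1 <- reluForward(fa1$out)
  fa2 <- conv3ForwardM(ra1$out, H, W, B, p$A2, p$a2); ra2 <- reluForward(fa2$out)
  fb1 <- conv3ForwardM(XB, H, W, B, p$B1, p$bb1); rb1 <- reluForward(fb1$out)
  fb2 <- conv3ForwardM(rb1$out, H, W, B, p$B2, p$bb2); rb2 <- reluForward(fb2$out)
  flat <- function(x) {   # (HW*B) x C -> B x (HW*C), per-sample feature rows
    C <- ncol(x)
    dim(x) <- c(HW, B, C)
    x <- aperm(x, c(2L, 1L, 3L))
    dim(x) <- c(B, HW * C)
    x
  }
  Fm <- cbind(flat(ra2$out), flat(rb2$out))
  Z <- Fm %*% p$Wh
  Z <- Z + rep(p$bh, each = B)
  rh <- reluForward(Z)
  logits <- as.vector(rh$out %*% p$Wo) + p$bo
  list(logits = logits,
       cache = list(fa1 = fa1, ra1 = ra1, fa2 = fa2, ra2 = ra2,
                    fb1 = fb1, rb1 = rb1, fb2 = fb2, rb2 = rb2,
                    Fm = Fm, rh = rh, B = B, HW = HW, H = H, W = W,
                    nA = HW * ncol(ra2$out), cA = ncol(ra2$out),
                    cB = ncol(rb2$out)))
}

# Batched backward: dlogits is a length-B vector; parameter gradients are
# summed over the batch.
confNetBackwardB <- function(model, cache, dlogits) {
  p <- model$params
  B <- cache$B; HW <- cache$HW
  dWo <- crossprod(cache$rh$out, dlogits)
  dbo <- sum(dlogits)
  dZ <- tcrossprod(as.matrix(dlogits), p$Wo)
  dZ <- reluBackward(dZ, cache$rh)
  dWh <- crossprod(cache$Fm, dZ)
  dbh <- colSums(dZ)
  dF <- tcrossprod(dZ, p$Wh)
  unflat <- function(m, C) {   # B x (HW*C) -> (HW*B) x C
    dim(m) <- c(B, HW, C)
    m <- aperm(m, c(2L, 1L, 3L))
    dim(m) <- c(HW * B, C)
    m
  }
  dA <- unflat(dF[, seq_len(cache$nA), drop = FALSE], cache$cA)
  dB <- unflat(dF[, -seq_len(cache$nA), drop = FALSE], cache$cB)
  dA <- reluBackward(dA, cache$ra2)
  ba2 <- conv3BackwardM(dA, cache$fa2, p$A2)
  da <- reluBackward(ba2$dx, cache$ra1)
  ba1 <- conv3BackwardM(da, cache$fa1, p$A1, needDx = FALSE)
  dB <- reluBackward(dB, cache$rb2)
  bb2 <- conv3BackwardM(dB, cache$fb2, p$B2)
  db <- reluBackward(bb2$dx, cache$rb1)
  bb1 <- conv3BackwardM(db, cache$fb1, p$B1, needDx = FALSE)
  list(A1 = ba1$dW, a1 = ba1$db, A2 = ba2$dW, a2 = ba2$db,
       B1 = bb1$dW, bb1 = bb1$db, B2 = bb2$dW, bb2 = bb2$db,
       Wh = dWh, bh = dbh, Wo = dWo, bo = dbo)
}

# Downsample + standardize an SSTMap to the confidence net input.
confNetInput <- function(sst, stride) {
  v <- prepareInput(sst, standardize = TRUE)
  blockMean(v, stride)
}

#' Confidence-network inference
#'
#' Returns `sigmoid(logit)` in (0, 1) for an (SST map, weak heatmap) pair;
#' the sigmoid is applied only here, never during training loss
#' evaluation (which uses the raw logit in a with-logits cross-entropy).
#'
#' @param model a trained [confidenceNetInit()] model
#' @param sst the day's [SSTMap-class]
#' @param yWeak the day's trajectory [Heatmap3-class]
#' @return predicted confidence in (0, 1)
#' @export
confidenceNetPredict <- function(model, sst, yWeak) {
  xs <- confNetInput(sst, yWeak@stride)
  if (!identical(dim(xs), model$cfg$inputDim))
    stop("input shape does not match the confidence net config")
  z <- confNetForward(model, xs, yWeak@array)$logit
  1 / (1 + exp(-z))
}

#' Train the confidence network
#'
#' Minimizes the soft-label binary cross-entropy
#' `-(c log sigma(z) + (1-c) log(1 - sigma(z)))` against ground-truth
#' confidence targets with Adam, and returns the weights of the epoch with
#' the lowest validation loss.
#'
#' @param pairs list of `list(sst = SSTMap, yWeak = Heatmap3, c = target)`
#'   for days present in both the catch and the trajectory stream
#' @param phase a [phaseConfig()]; `lr`, `batchSize`, `epochs`, `valSplit`
#'   and `seed` are used
#' @param cfg optional [confidenceNetConfig()]; derived from the first
#'   pair's shape by default
#' @return list: `model` (selected weights), `history` (per-epoch
#'   data.frame with train/validation loss), `bestEpoch`
#' @export
trainConfidenceNet <- function(pairs, phase = phaseConfig(), cfg = NULL) {
  if (!length(pairs)) stop("empty confidence training set")
  if (!is.null(phase$seed)) set.seed(phase$seed)
  stride <- pairs[[1]]$yWeak@stride
  xs <- lapply(pairs, function(p) confNetInput(p$sst, stride))
  hms <- lapply(pairs, function(p) p$yWeak@array)
  cs <- vapply(pairs, function(p) p$c, 0)
  stopifnot(all(cs >= 0 & cs <= 1))
  if (is.null(cfg)) cfg <- confidenceNetConfig(dim(xs[[1]]))
  model <- confidenceNetInit(cfg)
  n <- length(pairs)
  nVal <- max(1L, round(phase$valSplit * n))
  if (n < 2L) nVal <- 0L
  idx <- sample.int(n)
  valIdx <- idx[seq_len(nVal)]
  trIdx <- setdiff(idx, valIdx)
  evalLoss <- function(params, which) {
    m <- model; m$params <- params
    if (!length(which)) return(NA_real_)
    z <- confNetForwardB(m, xs[which], hms[which])$logits
    mean(mapply(softBce, z, cs[which]))
  }
  state <- adamInit(model$params)
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  v0 <- evalLoss(model$params, valIdx)
  if (is.finite(v0)) best <- list(loss = v0, params = model$params, epoch = 0L)
  for (ep in seq_len(phase$epochs)) {
    ord <- sample(trIdx)
    epLoss <- 0
    for (start in seq(1L, length(ord), by = phase$batchSize)) {
      b <- ord[start:min(start + phase$batchSize - 1L, length(ord))]
      fw <- confNetForwardB(model, xs[b], hms[b])
      epLoss <- epLoss + sum(mapply(softBce, fw$logits, cs[b]))
      dz <- (plogisSafe(fw$logits) - cs[b]) / length(b)
      grads <- confNetBackwardB(model, fw$cache, dz)
      upd <- adamStep(model$params, grads, state, phase$lr)
      model$params <- upd$params
      state <- upd$state
    }
    vl <- evalLoss(model$params, valIdx)
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / max(1, length(trIdx)),
                                   val = vl))
    if (is.finite(vl) && vl < best$loss)
      best <- list(loss = vl, params = model$params, epoch = ep)
  }
  if (!is.finite(best$loss)) best <- list(loss = NA_real_, params = model$params,
                                          epoch = phase$epochs)
  model$params <- best$params
  list(model = model, history = hist, bestEpoch = best$epoch)
}

plogisSafe <- function(z) 1 / (1 + exp(-z))

# Numerically stable soft-label BCE with logits.
softBce <- function(z, c) {
  # log(1+exp(-|z|)) + max(z,0) - c*z
  log1p(exp(-abs(z))) + max(z, 0) - c * z
}

#' Confidence records for audit export
#'
#' Tabulates ground-truth confidence targets of paired days and, when a
#' trained confidence net is given, its predicted confidences on the same
#' pairs -- one row per (date, kind), ready for `write.csv`.
#'
#' @param pairs list of `list(sst, yWeak, c)` as used by
#'   [trainConfidenceNet()]
#' @param model optional trained confidence net
#' @return data.frame with columns `date`, `c`, `kind`
#'   (`"target"`/`"predicted"`)
#' @export
confidenceRecords <- function(pairs, model = NULL) {
  dates <- as.Date(vapply(pairs, function(p) format(p$sst@date), ""))
  out <- data.frame(date = dates,
                    c = vapply(pairs, function(p) p$c, 0),
                    kind = "target")
  if (!is.null(model)) {
    out <- rbind(out, data.frame(
      date = dates,
      c = vapply(pairs, function(p)
        confidenceNetPredict(model, p$sst, p$yWeak), 0),
      kind = "predicted"))
  }
  out
}
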