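# Minimal CNN machinery: 3x3 same-padding convolution, 1x1 convolution,
# ReLU, 2x2 max pooling, dense layers, with exact backpropagation, plus
# SGD and Adam. Kept deliberately small: the networks in this package are
# tiny (a few thousand parameters) and run on one CPU. Convolutions use a
# precomputed im2col index so the inner loop is a single BLAS matmul.

# Cache of im2col index matrices keyed by "HxW".
.convIdxCache <- new.env(parent = emptyenv())

# (H*W) x 9 matrix of linear indices into the zero-padded (H+2)x(W+2)
# image, column-major pixels, offsets ordered dj (-1,0,1) outer, di inner.
conv3Index <- function(H, W) {
  key <- paste0(H, "x", W)
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  Hp <- H + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in -1L:1L) for (di in -1L:1L) {
    k <- k + 1L
    idx[, k] <- (i + 1L + di) + (j + dj) * Hp
  }
  .convIdxCache[[key]] <- idx
  idx
}

# Expanded gather index for all input channels: (H*W) x (9*Cin), columns
# ordered channel-major ((c-1)*9 + k) into the padded (Hp*Wp*Cin) array.
conv3IndexAll <- function(H, W, Cin) {
  key <- paste0(H, "x", W, "x", Cin)
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  idx <- conv3Index(H, W)
  Hp <- H + 2L; Wp <- W + 2L
  all <- matrix(0L, H * W, 9L * Cin)
  for (c in seq_len(Cin))
    all[, ((c - 1L) * 9L + 1L):(c * 9L)] <- idx + (c - 1L) * (Hp * Wp)
  .convIdxCache[[key]] <- all
  all
}

# x: H x W x Cin array. W3: (9*Cin) x Cout (rows: channel-major blocks of
# 9 offsets). Returns list(out = H x W x Cout, Xcol) for backward.
conv3Forward <- function(x, W3, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]
  Hp <- H + 2L; Wp <- W + 2L
  xp <- array(0, c(Hp, Wp, Cin))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  Xcol <- xp[conv3IndexAll(H, W, Cin)]
  dim(Xcol) <- c(H * W, 9L * Cin)
  y <- Xcol %*% W3
  y <- y + rep(b, each = H * W)
  dim(y) <- c(H, W, length(b))
  list(out = y, Xcol = Xcol, H = H, W = W, Cin = Cin)
}

conv3Backward <- function(dy, cache, W3) {
  H <- cache$H; W <- cache$W; Cin <- cache$Cin
  Cout <- ncol(W3)
  dim(dy) <- c(H * W, Cout)
  dW <- crossprod(cache$Xcol, dy)
  db <- colSums(dy)
  dXcol <- tcrossprod(dy, W3)
  idx <- conv3Index(H, W)
  Hp <- H + 2L; Wp <- W + 2L
  # for a fixed offset the output->padded-input map is injective, so the
  # scatter-add is a plain indexed addition, vectorized over channels
  dxp <- matrix(0, Hp * Wp, Cin)
  cols9 <- seq(0L, by = 9L, length.out = Cin)
  for (k in 1:9)
    dxp[idx[, k], ] <- dxp[idx[, k], ] + dXcol[, cols9 + k]
  dim(dxp) <- c(Hp, Wp, Cin)
  dx <- dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution = per-pixel linear map across channels.
conv1Forward <- function(x, W1, b) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
  y <- xm %*% W1
  y <- y + rep(b, each = d[1] * d[2])
  dim(y) <- c(d[1], d[2], length(b))
  list(out = y, xm = xm, d = d)
}

conv1Backward <- function(dy, cache, W1) {
  d <- cache$d
  dim(dy) <- c(d[1] * d[2], ncol(W1))
  dW <- crossprod(cache$xm, dy)
  db <- colSums(dy)
  dx <- tcrossprod(dy, W1)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

reluForward <- function(x) {
  m <- x > 0
  x[!m] <- 0
  list(out = x, m = m)
}

reluBackward <- function(dy, cache) {
  dy[!cache$m] <- 0
  dy
}

# 2x2 max pooling, stride 2; H and W must be even (grid sizes in this
# package are chosen so). Ties take the first of the four positions.
pool2Forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (H %% 2L || W %% 2L) stop("pooling needs even spatial dims")
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  c2 <- x[i1, j2, , drop = FALSE]; d2 <- x[i2, j2, , drop = FALSE]
  out <- pmax(a, b, c2, d2)
  arg <- array(1L, dim(out))
  arg[b == out & a != out] <- 2L
  arg[c2 == out & a != out & b != out] <- 3L
  arg[d2 == out & a != out & b != out & c2 != out] <- 4L
  list(out = out, arg = arg, H = H, W = W, C = C)
}

pool2Backward <- function(dy, cache) {
  H <- cache$H; W <- cache$W; C <- cache$C
  dx <- array(0, c(H, W, C))
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo * C)
  jo <- rep(rep(seq_len(Wo), each = Ho), times = C)
  co <- rep(seq_len(C), each = Ho * Wo)
  arg <- as.vector(cache$arg)
  di <- c(0L, 1L, 0L, 1L)[arg]
  dj <- c(0L, 0L, 1L, 1L)[arg]
  dx[cbind(2L * io - 1L + di, 2L * jo - 1L + dj, co)] <- as.vector(dy)
  dx
}

denseForward <- function(x, Wd, b) {
  y <- as.vector(x %*% Wd) + b
  list(out = y, x = x)
}

denseBackward <- function(dy, cache, Wd) {
  list(dx = as.vector(Wd %*% dy),
       dW = tcrossprod(as.matrix(cache$x), as.matrix(dy)),  # BLAS rank-1
       db = dy)
}

# He-scaled normal init for a fan-in of n.
heInit <- function(nr, nc, fanIn) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
}

# ---- flat parameter vector helpers (finite-difference tests) ----------

flattenParams <- function(params) {
  unlist(params, use.names = FALSE)
}

unflattenParams <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- flat[(pos + 1L):(pos + n)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

nParams <- function(params) sum(vapply(params, length, 1L))

# ---- optimizers --------------------------------------------------------

sgdStep <- function(params, grads, lr) {
  for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Zero-filled gradient structure matching params.
zeroGrads <- function(params) lapply(params, function(p) p * 0)

addGrads <- function(a, b, w = 1) {
  for (nm in names(a)) a[[nm]] <- a[[nm]] + w * b[[nm]]
  a
}

scaleGrads <- function(a, s) lapply(a, function(p) p * s)

# ---- batched primitives (row-stacked layout) ---------------------------
# A batch of B samples of an H x W x C feature map is stored as an
# (H*W*B) x C matrix, rows ordered pixel-major within sample, samples in
# blocks: row = pix + (b-1)*H*W. All convolution work then reduces to one
# index gather, one BLAS matmul and (backward) one indexed scatter-add --
# no array permutations, which dominate runtime otherwise.

batchIds <- function(H, W, B) {
  key <- sprintf("b:%dx%dx%d", H, W, B)
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  ppix <- (i + 1L) + j * Hp
  offs <- (seq_len(B) - 1L) * (Hp * Wp)
  pad <- as.vector(outer(ppix, offs, `+`))
  idx <- conv3Index(H, W)
  idx2 <- matrix(0L, H * W * B, 9L)
  for (k in 1:9) idx2[, k] <- as.vector(outer(idx[, k], offs, `+`))
  out <- list(pad = pad, idx2 = idx2, Hp = Hp, Wp = Wp)
  .convIdxCache[[key]] <- out
  out
}

batchIdsFull <- function(H, W, B, Cin) {
  key <- sprintf("bf:%dx%dx%dx%d", H, W, B, Cin)
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  ids <- batchIds(H, W, B)
  M <- ids$Hp * ids$Wp * B
  full <- matrix(0L, H * W * B, 9L * Cin)
  for (c in seq_len(Cin))
    full[, (c - 1L) * 9L + 1:9] <- ids$idx2 + (c - 1L) * M
  .convIdxCache[[key]] <- full
  full
}

# X: (H*W*B) x Cin. Returns out (H*W*B) x Cout.
conv3ForwardM <- function(X, H, W, B, W3, bias) {
  Cin <- ncol(X)
  ids <- batchIds(H, W, B)
  xpad <- matrix(0, ids$Hp * ids$Wp * B, Cin)
  xpad[ids$pad, ] <- X
  Xcol <- xpad[batchIdsFull(H, W, B, Cin)]
  dim(Xcol) <- c(H * W * B, 9L * Cin)
  y <- Xcol %*% W3
  y <- y + rep(bias, each = nrow(y))
  list(out = y, Xcol = Xcol, H = H, W = W, B = B, Cin = Cin)
}

conv3BackwardM <- function(dy, cache, W3, needDx = TRUE) {
  dW <- crossprod(cache$Xcol, dy)  # sums over batch rows
  db <- colSums(dy)
  if (!needDx) return(list(dx = NULL, dW = dW, db = db))
  dXcol <- tcrossprod(dy, W3)
  ids <- batchIds(cache$H, cache$W, cache$B)
  dxpad <- matrix(0, ids$Hp * ids$Wp * cache$B, cache$Cin)
  cols9 <- seq(0L, by = 9L, length.out = cache$Cin)
  for (k in 1:9)   # per offset the scatter map is injective
    dxpad[ids$idx2[, k], ] <- dxpad[ids$idx2[, k], ] + dXcol[, cols9 + k]
  list(dx = dxpad[ids$pad, , drop = FALSE], dW = dW, db = db)
}

poolIds <- function(H, W, B) {
  key <- sprintf("p:%dx%dx%d", H, W, B)
  if (!is.null(.convIdxCache[[key]])) return(.convIdxCache[[key]])
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  offs <- (seq_len(B) - 1L) * (H * W)
  base <- function(di, dj)
    as.vector(outer((2L * io - 1L + di) + (2L * jo - 2L + dj) * H, offs, `+`))
  out <- list(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L))
  .convIdxCache[[key]] <- out
  out
}

# 2x2/stride-2 max pooling on the row-stacked layout; ties take the first
# of the four positions (same priority as pool2Forward).
pool2ForwardM <- function(X, H, W, B) {
  ids <- poolIds(H, W, B)
  a <- X[ids[[1]], , drop = FALSE]; b <- X[ids[[2]], , drop = FALSE]
  c2 <- X[ids[[3]], , drop = FALSE]; d2 <- X[ids[[4]], , drop = FALSE]
  out <- pmax(a, b, c2, d2)
  arg <- matrix(1L, nrow(out), ncol(out))
  arg[b == out & a != out] <- 2L
  arg[c2 == out & a != out & b != out] <- 3L
  arg[d2 == out & a != out & b != out & c2 != out] <- 4L
  list(out = out, arg = arg, ids = ids, N = nrow(X), C = ncol(X))
}

pool2BackwardM <- function(dy, cache) {
  dx <- matrix(0, cache$N, cache$C)
  rr <- row(cache$arg); cc <- col(cache$arg)
  for (q in 1:4) {
    sel <- cache$arg == q
    if (any(sel))
      dx[cbind(cache$ids[[q]][rr[sel]], cc[sel])] <- dy[sel]
  }
  dx
}
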