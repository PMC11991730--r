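#' Training-phase configuration
#'
#' Hyperparameters of one training phase. Defaults follow the reference
#' setting for the target network (Adam, learning rate 4e-5, batch 16,
#' 100 pre-training / 33 fine-tuning epochs, 0.2 validation split, model
#' selection by validation F1 for fine-tuning and by validation loss
#' otherwise). For desk-scale synthetic experiments see [deskPhases()].
#'
#' @param optimizer `"adam"` (default) or `"sgd"`. The confidence weight
#'   multiplies each sample's loss (hence gradient); with SGD the update
#'   is exactly the per-sample weighted gradient sum, with Adam that
#'   weighted gradient is then preconditioned.
#' @param lr learning rate (> 0)
#' @param batchSize samples per step (>= 1)
#' @param epochs maximum epochs
#' @param valSplit validation fraction, split by whole days (0 < s < 1)
#' @param metric model-selection metric: `"f1"` (highest validation F1,
#'   ties to the later epoch) or `"loss"` (lowest validation loss)
#' @param seed RNG seed applied at phase start (`NULL`: leave RNG alone)
#' @return a `PhaseConfig` (list)
#' @export
phaseConfig <- function(optimizer = c("adam", "sgd"), lr = 4e-5,
                        batchSize = 16L, epochs = 100L, valSplit = 0.2,
                        metric = c("loss", "f1"), seed = NULL) {
  optimizer <- match.arg(optimizer)
  metric <- match.arg(metric)
  stopifnot(lr > 0, batchSize >= 1, valSplit > 0, valSplit < 1)
  structure(list(optimizer = optimizer, lr = lr,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), valSplit = valSplit,
                 metric = metric, seed = seed),
            class = "PhaseConfig")
}

#' Desk-scale phase presets
#'
#' Scaled-down phase settings for the default 40 x 64 synthetic world so
#' that all comparison arms train on one CPU in minutes: Adam at 1e-3 for
#' 10 pre-training epochs (selection by validation loss), 10 fine-tuning
#' epochs (selection by validation F1) and 8 confidence-network epochs
#' (selection by validation loss).
#'
#' @return named list of [phaseConfig()]s: `pretrain`, `finetune`,
#'   `confidence`
#' @export
deskPhases <- function() {
  list(pretrain = phaseConfig(lr = 1e-3, epochs = 10L, metric = "loss"),
       finetune = phaseConfig(lr = 1e-3, epochs = 10L, metric = "f1"),
       confidence = phaseConfig(lr = 1e-3, epochs = 8L, metric = "loss"))
}

#' Freeze a confidence network
#'
#' Marks the net as frozen; [metaWeightedStep()] refuses an unfrozen
#' confidence net, since no gradient may flow into it while the target
#' network trains.
#' @param confNet a confidence-net model
#' @return the model, flagged frozen
#' @export
freezeConfidenceNet <- function(confNet) {
  confNet$frozen <- TRUE
  confNet
}

# Weighted batch gradient: (1/b) * sum_i c_i * grad L(f(x_i), y_i).
# batch: list of list(x = prepared input matrix, y = target array).
# Runs the whole batch through the stacked (BLAS) forward/backward; the
# result equals the per-sample weighted gradient sum.
weightedBatchGrads <- function(model, batch, weights, loss) {
  b <- length(batch)
  fw <- detectorForwardB(model, lapply(batch, `[[`, "x"))
  pred <- fw$pred                       # (h*w*B) x 3
  hw <- fw$h * fw$w
  Y <- matrix(0, hw * b, 3L)
  for (i in seq_len(b))
    Y[(i - 1L) * hw + seq_len(hw), ] <- matrix(batch[[i]]$y, hw, 3L)
  grp <- rep(seq_len(b), each = hw)
  l2i <- 0.5 * rowSums(rowsum((pred - Y)^2, grp))
  perLoss <- if (loss$kind == "l2") l2i else
    loss$alpha * l2i + (1 - loss$alpha) * rowSums(rowsum(pmax(Y - pred, 0), grp))
  dpred <- lossGrad(pred, Y, loss) * rep(weights / b, each = hw)
  grads <- detectorBackwardB(model, fw$cache, dpred)
  list(grads = grads, loss = sum(weights * perLoss) / b)
}

#' One confidence-weighted training step
#'
#' Updates the target network by descending the mean confidence-weighted
#' loss `(1/b) sum_i c_i L(f(x_i), y_i)`, whose gradient is the
#' per-sample weighted gradient sum of the meta-learned update rule. The
#' confidence `c_i` comes from frozen confidence-net inference on each
#' (SST, weak heatmap) pair -- no gradient flows into the confidence net.
#' With all `c_i = 1` this is exactly an unweighted step.
#'
#' @param model the target network (from [detectorInit()])
#' @param batch list of `list(sst = SSTMap, hm = Heatmap3)` samples
#' @param phase a [phaseConfig()] (optimizer and learning rate are used)
#' @param loss a [lossConfig()]
#' @param confNet a frozen confidence net, or `NULL`
#' @param weights explicit numeric weights overriding `confNet` (e.g.
#'   all 1 for a plain step); default all 1 when `confNet` is `NULL`
#' @param optState Adam state from a previous step, or `NULL` (SGD, or a
#'   fresh Adam state)
#' @return list: updated `model`, `optState`, `weights` used, batch `loss`
#' @export
metaWeightedStep <- function(model, batch, phase, loss = lossConfig("l2"),
                             confNet = NULL, weights = NULL, optState = NULL) {
  b <- length(batch)
  if (!b) stop("empty batch")
  if (is.null(weights)) {
    if (!is.null(confNet)) {
      if (!isTRUE(confNet$frozen))
        stop("confidence net must be frozen during target-network training")
      weights <- vapply(batch, function(s)
        confidenceNetPredict(confNet, s$sst, s$hm), 0)
    } else weights <- rep(1, b)
  }
  prepared <- lapply(batch, function(s)
    list(x = prepareInput(s$sst, model$cfg$standardize), y = s$hm@array))
  wb <- weightedBatchGrads(model, prepared, weights, loss)
  if (phase$optimizer == "sgd") {
    model$params <- sgdStep(model$params, wb$grads, phase$lr)
  } else {
    if (is.null(optState)) optState <- adamInit(model$params)
    upd <- adamStep(model$params, wb$grads, optState, phase$lr)
    model$params <- upd$params
    optState <- upd$state
  }
  list(model = model, optState = optState, weights = weights, loss = wb$loss)
}

# Split indices into train/validation by whole days.
splitDays <- function(n, valSplit) {
  nVal <- max(1L, round(valSplit * n))
  if (n < 2L) return(list(train = seq_len(n), val = integer()))
  idx <- sample.int(n)
  list(train = sort(idx[-seq_len(nVal)]), val = sort(idx[seq_len(nVal)]))
}

# Mean unweighted loss of the model over dataset indices (chunked batches).
datasetLoss <- function(model, prepared, idx, loss) {
  if (!length(idx)) return(NA_real_)
  tot <- 0
  for (start in seq(1L, length(idx), by = 16L)) {
    b <- idx[start:min(start + 15L, length(idx))]
    fw <- detectorForwardB(model, lapply(prepared[b], `[[`, "x"))
    hw <- fw$h * fw$w
    Y <- matrix(0, hw * length(b), 3L)
    for (i in seq_along(b))
      Y[(i - 1L) * hw + seq_len(hw), ] <- matrix(prepared[[b[i]]]$y, hw, 3L)
    l2 <- 0.5 * sum((fw$pred - Y)^2)
    tot <- tot + if (loss$kind == "l2") l2 else
      loss$alpha * l2 + (1 - loss$alpha) * sum(pmax(Y - fw$pred, 0))
  }
  tot / length(idx)
}

#' Pre-train the target network on weak (trajectory) heatmaps
#'
#' Runs confidence-weighted steps when a frozen confidence net is given
#' (the proposed method) and plain steps otherwise (the no-confidence
#' baseline). Model selection keeps the epoch with the lowest unweighted
#' validation loss.
#'
#' @param dataset list of `list(sst = SSTMap, hm = Heatmap3)` day samples
#' @param phase a [phaseConfig()]
#' @param loss a [lossConfig()] (L2 by default)
#' @param confNet frozen confidence net or `NULL`
#' @param model a detector to continue from; default a fresh
#'   [detectorInit()] on the dataset's grid
#' @return list: `model` (selected weights), `history`, `bestEpoch`
#' @export
pretrain <- function(dataset, phase = phaseConfig(), loss = lossConfig("l2"),
                     confNet = NULL, model = NULL) {
  if (!length(dataset)) stop("empty pre-training dataset")
  if (!is.null(phase$seed)) set.seed(phase$seed)
  if (is.null(model)) {
    g <- dataset[[1]]$sst@grid
    model <- detectorInit(detectorConfig(c(g@nRows, g@nCols),
                                         stride = dataset[[1]]$hm@stride))
  }
  if (!is.null(confNet) && !isTRUE(confNet$frozen))
    stop("confidence net must be frozen during pre-training")
  prepared <- lapply(dataset, function(s)
    list(x = prepareInput(s$sst, model$cfg$standardize), y = s$hm@array))
  sp <- splitDays(length(dataset), phase$valSplit)
  cWeights <- if (!is.null(confNet))
    vapply(dataset, function(s) confidenceNetPredict(confNet, s$sst, s$hm), 0)
  else rep(1, length(dataset))
  optState <- if (phase$optimizer == "adam") adamInit(model$params) else NULL
  hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
  best <- list(val = datasetLoss(model, prepared, sp$val, loss),
               params = model$params, epoch = 0L)
  if (!is.finite(best$val)) best$val <- Inf
  for (ep in seq_len(phase$epochs)) {
    ord <- sample(sp$train)
    epLoss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = phase$batchSize)) {
      b <- ord[start:min(start + phase$batchSize - 1L, length(ord))]
      wb <- weightedBatchGrads(model, prepared[b], cWeights[b], loss)
      if (phase$optimizer == "sgd") {
        model$params <- sgdStep(model$params, wb$grads, phase$lr)
      } else {
        upd <- adamStep(model$params, wb$grads, optState, phase$lr)
        model$params <- upd$params
        optState <- upd$state
      }
      epLoss <- epLoss + wb$loss; nb <- nb + 1L
    }
    vl <- datasetLoss(model, prepared, sp$val, loss)
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / max(1L, nb),
                                   val = vl))
    if (is.finite(vl) && vl < best$val)
      best <- list(val = vl, params = model$params, epoch = ep)
  }
  if (best$epoch == 0L && !length(sp$val))
    best <- list(val = NA_real_, params = model$params, epoch = phase$epochs)
  model$params <- best$params
  list(model = model, history = hist, bestEpoch = best$epoch)
}

#' Fine-tune the target network on strong (catch) heatmaps
#'
#' Plain unweighted training on catch-derived heatmaps; model selection
#' keeps the epoch with the highest validation F1 (peaks within the
#' geodesic hit radius against the validation days' Good catch records),
#' ties resolved to the later epoch. Starting from a fresh detector gives
#' the catch-only baseline arm.
#'
#' @param dataset list of `list(sst, hm, truth)` where `truth` is a
#'   data.frame of the day's Good catch positions (`lat`, `lon`)
#' @param model a detector (pre-trained weights or a fresh init)
#' @param phase a [phaseConfig()]
#' @param loss a [lossConfig()]
#' @param threshold,dMax peak threshold and hit radius for validation F1
#' @param weights optional per-day sample weights (default all 1; used by
#'   the alternative reading that applies confidence during fine-tuning)
#' @return list: `model`, `history` (epoch, train loss, val F1),
#'   `bestEpoch`
#' @export
finetune <- function(dataset, model, phase = phaseConfig(metric = "f1"),
                     loss = lossConfig("l2"), threshold = 0.1, dMax = 200,
                     weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(dataset))
  if (!length(dataset)) stop("empty fine-tuning dataset")
  if (!is.null(phase$seed)) set.seed(phase$seed)
  prepared <- lapply(dataset, function(s)
    list(x = prepareInput(s$sst, model$cfg$standardize), y = s$hm@array))
  sp <- splitDays(length(dataset), phase$valSplit)
  valF1 <- function(params) {
    if (!length(sp$val)) return(NA_real_)
    m <- model; m$params <- params
    aggregateEval(lapply(sp$val, function(i) {
      pk <- detectPeaks(predictHeatmap(dataset[[i]]$sst, m), threshold = threshold)
      scoreDay(pk, dataset[[i]]$truth, dMax = dMax)
    }))$f1
  }
  optState <- if (phase$optimizer == "adam") adamInit(model$params) else NULL
  hist <- data.frame(epoch = integer(), train = numeric(), valF1 = numeric())
  f0 <- valF1(model$params)
  best <- list(f1 = if (is.finite(f0)) f0 else -Inf, params = model$params,
               epoch = 0L)
  for (ep in seq_len(phase$epochs)) {
    ord <- sample(sp$train)
    epLoss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = phase$batchSize)) {
      b <- ord[start:min(start + phase$batchSize - 1L, length(ord))]
      wb <- weightedBatchGrads(model, prepared[b], weights[b], loss)
      if (phase$optimizer == "sgd") {
        model$params <- sgdStep(model$params, wb$grads, phase$lr)
      } else {
        upd <- adamStep(model$params, wb$grads, optState, phase$lr)
        model$params <- upd$params
        optState <- upd$state
      }
      epLoss <- epLoss + wb$loss; nb <- nb + 1L
    }
    f1 <- valF1(model$params)
    hist <- rbind(hist, data.frame(epoch = ep, train = epLoss / max(1L, nb),
                                   valF1 = f1))
    # ties go to the later epoch: more training at equal validation F1
    if (is.finite(f1) && f1 >= best$f1)
      best <- list(f1 = f1, params = model$params, epoch = ep)
  }
  if (!is.finite(best$f1)) best <- list(f1 = NA_real_, params = model$params,
                                        epoch = phase$epochs)
  model$params <- best$params
  list(model = model, history = hist, bestEpoch = best$epoch)
}

# ---- dataset assembly from a synthetic world --------------------------

# Good catch positions of a world day (the evaluation ground truth).
dayTruth <- function(day) {
  good <- day$catch[day$catch$cpue > 0, , drop = FALSE]
  data.frame(lat = good$lat, lon = good$lon)
}

# Trajectory heatmap of a world day (labels -> habitat filter -> kernels).
dayTrajectoryHeatmap <- function(day, stride, sigma = 7) {
  inst <- labelInstances(trajectories = day$trajectories)
  inst <- habitatFilter(inst, day$sst)
  buildHeatmap(inst, day$sst@grid, stride, sigma, date = day$date,
               source = "trajectory")
}

# Catch heatmap of a world day.
dayCatchHeatmap <- function(day, stride, sigma = 7) {
  inst <- labelInstances(catch = day$catch)
  buildHeatmap(inst, day$sst@grid, stride, sigma, date = day$date,
               source = "catch")
}

#' Assemble phase datasets from a synthetic world
#'
#' Builds the per-day training samples each phase consumes: trajectory
#' heatmaps for pre-training (with paired catch heatmaps and confidence
#' targets for the confidence network), catch heatmaps plus Good-record
#' truth for fine-tuning, and SST + truth for test days.
#'
#' @param world from [buildWorld()]
#' @param stride model output stride (default 2 for the small world)
#' @param sigma heatmap kernel sd in pixels (default 7)
#' @return list: `pretrainTraj`, `pretrainMerged` (legacy arm),
#'   `confPairs`, `finetuneSet`, `testSet`
#' @export
worldDatasets <- function(world, stride = 2L, sigma = 7) {
  pre <- lapply(world$pretrain, function(d) {
    hmT <- dayTrajectoryHeatmap(d, stride, sigma)
    hmC <- dayCatchHeatmap(d, stride, sigma)
    list(sst = d$sst, hm = hmT, hmCatch = hmC,
         c = confidenceTarget(hmC, hmT))
  })
  fine <- lapply(world$finetune, function(d)
    list(sst = d$sst, hm = dayCatchHeatmap(d, stride, sigma),
         hmTraj = dayTrajectoryHeatmap(d, stride, sigma),
         truth = dayTruth(d)))
  test <- lapply(world$test, function(d) list(sst = d$sst, truth = dayTruth(d)))
  merged <- lapply(pre, function(s)
    list(sst = s$sst, hm = mergeHeatmaps(s$hmCatch, s$hm)))
  confPairs <- lapply(pre, function(s)
    list(sst = s$sst, yWeak = s$hm, c = s$c))
  list(pretrainTraj = lapply(pre, function(s) list(sst = s$sst, hm = s$hm)),
       pretrainMerged = merged, confPairs = confPairs,
       finetuneSet = fine, testSet = test)
}

#' Run one comparison arm end to end
#'
#' Executes one of the four training arms on a synthetic world and
#' evaluates on the test days:
#' \describe{
#'   \item{catch_only}{fine-tune a fresh detector on catch heatmaps only.}
#'   \item{fine_tuning_legacy}{pre-train on per-day heatmaps merging
#'     trajectory and catch instances, then fine-tune (approximation of
#'     the earlier two-source pre-training baseline).}
#'   \item{w_o_confidence}{pre-train on trajectory heatmaps unweighted,
#'     then fine-tune.}
#'   \item{w_confidence}{train the confidence network on paired days,
#'     freeze it, pre-train with confidence-weighted steps, then
#'     fine-tune (the proposed method).}
#' }
#'
#' @param arm one of `"catch_only"`, `"fine_tuning_legacy"`,
#'   `"w_o_confidence"`, `"w_confidence"`
#' @param world from [buildWorld()]
#' @param phases named list of [phaseConfig()]s (`pretrain`, `finetune`,
#'   `confidence`); default [deskPhases()]
#' @param loss a [lossConfig()] for the target network
#' @param stride,sigma heatmap geometry (defaults 2 and 7)
#' @param threshold,dMax evaluation peak threshold and hit radius
#' @param seed seed controlling splits, init and shuffling
#' @param confidencePhase where the confidence weighting acts:
#'   `"pretrain"` (default) or `"finetune"` (alternative reading)
#' @param datasets optional precomputed [worldDatasets()] (reused across
#'   arms to avoid rebuilding heatmaps)
#' @return list: `arm`, `report` (an `fgEvalReport`), `model`,
#'   `histories`, `confidence` (training result or `NULL`), `seed`
#' @export
runExperiment <- function(arm = c("catch_only", "fine_tuning_legacy",
                                  "w_o_confidence", "w_confidence"),
                          world, phases = deskPhases(),
                          loss = lossConfig("l2"), stride = 2L, sigma = 7,
                          threshold = 0.1, dMax = 200, seed = 1L,
                          confidencePhase = c("pretrain", "finetune"),
                          datasets = NULL) {
  arm <- match.arg(arm)
  confidencePhase <- match.arg(confidencePhase)
  set.seed(seed)
  if (is.null(datasets)) datasets <- worldDatasets(world, stride, sigma)
  g <- world$cfg$grid
  model <- detectorInit(detectorConfig(c(g@nRows, g@nCols), stride = stride))
  histories <- list()
  confRes <- NULL
  if (arm == "w_confidence") {
    confRes <- trainConfidenceNet(datasets$confPairs, phases$confidence)
    confRes$model <- freezeConfidenceNet(confRes$model)
  }
  if (arm != "catch_only") {
    preSet <- if (arm == "fine_tuning_legacy") datasets$pretrainMerged
              else datasets$pretrainTraj
    confNet <- if (arm == "w_confidence" && confidencePhase == "pretrain")
      confRes$model else NULL
    pr <- pretrain(preSet, phases$pretrain, loss, confNet = confNet,
                   model = model)
    model <- pr$model
    histories$pretrain <- pr$history
  }
  ftWeights <- NULL
  if (arm == "w_confidence" && confidencePhase == "finetune")
    ftWeights <- vapply(datasets$finetuneSet, function(s)
      confidenceNetPredict(confRes$model, s$sst, s$hmTraj), 0)
  ft <- finetune(datasets$finetuneSet, model, phases$finetune, loss,
                 threshold = threshold, dMax = dMax, weights = ftWeights)
  model <- ft$model
  histories$finetune <- ft$history
  report <- evaluateDetector(model, datasets$testSet, threshold = threshold,
                             dMax = dMax)
  list(arm = arm, report = report, model = model, histories = histories,
       confidence = confRes, seed = seed)
}

#' Compare training arms across seeded synthetic worlds
#'
#' Builds one synthetic world per seed (default [worldConfig()] except for
#' the seed), runs the requested arms on each, and collects the test
#' metrics -- the qualitative comparison table of the method: arms using
#' trajectory pre-training are expected to emit more peaks and recall more
#' grounds than catch-only training, and confidence weighting to edge out
#' plain pre-training.
#'
#' @param seeds integer vector; one world and run per seed
#' @param arms arms to run (see [runExperiment()])
#' @param worldArgs named list of [worldConfig()] overrides (the seed is
#'   supplied per run)
#' @inheritParams runExperiment
#' @return data.frame: seed, arm, precision, recall, f1, nPeaks, nTruth
#' @export
compareArms <- function(seeds = 1:20,
                        arms = c("catch_only", "w_o_confidence", "w_confidence"),
                        phases = deskPhases(), loss = lossConfig("l2"),
                        stride = 2L, sigma = 7, threshold = 0.1, dMax = 200,
                        worldArgs = list()) {
  rows <- list()
  for (s in seeds) {
    cfg <- do.call(worldConfig, c(list(seed = s), worldArgs))
    world <- buildWorld(cfg)
    ds <- worldDatasets(world, stride, sigma)
    for (arm in arms) {
      r <- runExperiment(arm, world, phases = phases, loss = loss,
                         stride = stride, sigma = sigma,
                         threshold = threshold, dMax = dMax, seed = s,
                         datasets = ds)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, arm = arm, precision = r$report$precision,
        recall = r$report$recall, f1 = r$report$f1,
        nPeaks = r$report$nPeaks, nTruth = r$report$nTruth)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
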