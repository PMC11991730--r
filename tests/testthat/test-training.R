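# Build a tiny typed batch (SSTMap + trajectory Heatmap3) on the tiny grid.
tinyBatch <- function(n, seed = 1) {
  set.seed(seed)
  g <- tinyGrid()
  d <- as.Date("2020-01-01")
  lapply(seq_len(n), function(i) {
    sst <- sstMap(matrix(rnorm(16 * 24, 20, 1), 16, 24), g, d + i)
    inst <- data.frame(date = d + i, lat = runif(1, 32.5, 35.5),
                       lon = runif(1, 142.5, 147), label = "Unknown",
                       source = "trajectory")
    list(sst = sst, hm = buildHeatmap(inst, g, 2L, sigma = 2, date = d + i))
  })
}

test_that("all-ones confidence reproduces the plain step bitwise", {
  batch <- tinyBatch(4, seed = 2)
  phase <- phaseConfig(optimizer = "sgd", lr = 0.05)
  set.seed(10)
  m0 <- detectorInit(detectorConfig(c(16, 24), stride = 2))
  a <- metaWeightedStep(m0, batch, phase, weights = rep(1, 4))
  b <- metaWeightedStep(m0, batch, phase)           # default plain step
  expect_identical(a$model$params, b$model$params)
})

test_that("zero confidence leaves SGD weights exactly unchanged", {
  batch <- tinyBatch(3, seed = 3)
  set.seed(11)
  m0 <- detectorInit(detectorConfig(c(16, 24), stride = 2))
  upd <- metaWeightedStep(m0, batch, phaseConfig(optimizer = "sgd", lr = 0.1),
                          weights = rep(0, 3))
  expect_identical(upd$model$params, m0$params)
})

test_that("a (1, 0)-weighted pair updates by half the lone-sample gradient", {
  batch <- tinyBatch(2, seed = 4)
  set.seed(12)
  m0 <- detectorInit(detectorConfig(c(16, 24), stride = 2))
  m0$params$W4 <- matrix(rnorm(16 * 3, sd = 0.1), 16, 3)
  phase <- phaseConfig(optimizer = "sgd", lr = 0.2)
  mixed <- metaWeightedStep(m0, batch, phase, weights = c(1, 0))
  solo <- metaWeightedStep(m0, batch[1], phase, weights = 1)
  dMixed <- fishgrounds:::flattenParams(mixed$model$params) -
    fishgrounds:::flattenParams(m0$params)
  dSolo <- fishgrounds:::flattenParams(solo$model$params) -
    fishgrounds:::flattenParams(m0$params)
  expect_equal(dMixed, dSolo / 2, tolerance = 1e-12)
})

test_that("the weighted batch gradient equals the per-sample weighted sum", {
  set.seed(13)
  model <- detectorInit(detectorConfig(c(8, 8), stride = 2, channels = c(2, 2)))
  model$params$W4 <- matrix(rnorm(6, sd = 0.3), 2, 3)
  xs <- lapply(1:3, function(i) matrix(rnorm(64), 8, 8))
  ys <- lapply(1:3, function(i) array(runif(48), c(4, 4, 3)))
  wts <- c(0.7, 0.2, 1)
  wb <- fishgrounds:::weightedBatchGrads(
    model, lapply(1:3, function(i) list(x = xs[[i]], y = ys[[i]])),
    wts, lossConfig("l2"))
  ref <- fishgrounds:::zeroGrads(model$params)
  for (i in 1:3) {
    fw <- fishgrounds:::detectorForward(model, xs[[i]])
    ref <- fishgrounds:::addGrads(
      ref, fishgrounds:::detectorBackward(model, fw$cache,
                                          wts[i] * (fw$pred - ys[[i]])))
  }
  ref <- fishgrounds:::scaleGrads(ref, 1 / 3)
  expect_equal(fishgrounds:::flattenParams(wb$grads),
               fishgrounds:::flattenParams(ref), tolerance = 1e-12)
})

test_that("an unfrozen confidence net is rejected during target training", {
  batch <- tinyBatch(2, seed = 5)
  set.seed(14)
  cn <- confidenceNetInit(confidenceNetConfig(c(8, 12), channels = c(2, 2),
                                              hidden = 4))
  m0 <- detectorInit(detectorConfig(c(16, 24), stride = 2))
  expect_error(metaWeightedStep(m0, batch, phaseConfig(), confNet = cn),
               "frozen")
  expect_error(pretrain(batch, phaseConfig(), confNet = cn), "frozen")
  ok <- metaWeightedStep(m0, batch, phaseConfig(lr = 1e-3),
                         confNet = freezeConfidenceNet(cn))
  expect_true(all(ok$weights > 0 & ok$weights < 1))
})

test_that("pre-training reduces loss and is seed-reproducible", {
  ds <- tinyBatch(10, seed = 6)
  phase <- phaseConfig(lr = 2e-3, epochs = 5, batchSize = 4, seed = 77)
  r1 <- pretrain(ds, phase)
  r2 <- pretrain(ds, phase)
  expect_identical(fishgrounds:::flattenParams(r1$model$params),
                   fishgrounds:::flattenParams(r2$model$params))
  h <- r1$history
  expect_lt(min(h$train[3:5]), h$train[1])
  expect_lte(min(h$val), h$val[1] + 1e-12)   # selection contract
  expect_error(pretrain(list(), phase), "empty")
})

test_that("fine-tuning selects by validation F1 and never below epoch zero", {
  set.seed(15)
  g <- tinyGrid()
  d <- as.Date("2020-02-01")
  ds <- lapply(1:8, function(i) {
    lat <- runif(1, 32.5, 35.5); lon <- runif(1, 142.5, 147)
    sst <- sstMap(matrix(rnorm(16 * 24, 20, 1), 16, 24), g, d + i)
    inst <- data.frame(date = d + i, lat = lat, lon = lon, label = "Good",
                       source = "catch")
    list(sst = sst, hm = buildHeatmap(inst, g, 2L, sigma = 2, date = d + i),
         truth = data.frame(lat = lat, lon = lon))
  })
  set.seed(16)
  model <- detectorInit(detectorConfig(c(16, 24), stride = 2))
  r <- finetune(ds, model, phaseConfig(lr = 2e-3, epochs = 4, batchSize = 4,
                                       seed = 21, metric = "f1"))
  f0 <- r$history$valF1
  best <- max(c(0, f0), na.rm = TRUE)
  # the selected epoch attains the running maximum (ties to later epochs)
  expect_equal(r$bestEpoch %in% c(0, which(f0 == best)), TRUE)
  expect_error(finetune(list(), model), "empty")
})

test_that("arms are wired as claimed: catch-only never reads trajectories", {
  w <- tinyWorld(seed = 7)
  ds <- worldDatasets(w, 2L)
  phases <- list(pretrain = phaseConfig(lr = 1e-3, epochs = 2),
                 finetune = phaseConfig(lr = 1e-3, epochs = 2, metric = "f1"),
                 confidence = phaseConfig(lr = 1e-3, epochs = 2))
  r1 <- runExperiment("catch_only", w, phases = phases, seed = 5,
                      datasets = ds)
  # corrupt every trajectory-derived object: catch_only must not notice
  ds2 <- ds
  ds2$pretrainTraj <- NULL
  ds2$pretrainMerged <- NULL
  ds2$confPairs <- NULL
  r2 <- runExperiment("catch_only", w, phases = phases, seed = 5,
                      datasets = ds2)
  expect_identical(fishgrounds:::flattenParams(r1$model$params),
                   fishgrounds:::flattenParams(r2$model$params))
  expect_equal(r1$report$f1, r2$report$f1)
  # the proposed arm consumes a trained, frozen confidence net
  r3 <- runExperiment("w_confidence", w, phases = phases, seed = 5,
                      datasets = ds)
  expect_true(isTRUE(r3$confidence$model$frozen))
  expect_s3_class(r3$report, "fgEvalReport")
  # schema: every report carries the comparison-table columns
  for (r in list(r1, r3)) {
    expect_true(all(c("precision", "recall", "f1", "nPeaks") %in% names(r$report)))
  }
})

test_that("experiment runs are reproducible under a fixed seed", {
  w <- tinyWorld(seed = 8)
  ds <- worldDatasets(w, 2L)
  phases <- list(pretrain = phaseConfig(lr = 1e-3, epochs = 2),
                 finetune = phaseConfig(lr = 1e-3, epochs = 2, metric = "f1"),
                 confidence = phaseConfig(lr = 1e-3, epochs = 2))
  a <- runExperiment("w_o_confidence", w, phases = phases, seed = 9,
                     datasets = ds)
  b <- runExperiment("w_o_confidence", w, phases = phases, seed = 9,
                     datasets = ds)
  expect_identical(fishgrounds:::flattenParams(a$model$params),
                   fishgrounds:::flattenParams(b$model$params))
  expect_equal(a$report$f1, b$report$f1)
})
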