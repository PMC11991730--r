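test_that("noise-free SST is monotone in latitude and seed-reproducible", {
  cfg <- worldConfig(noiseAmp = 0, nEddies = 0, landCols = 0)
  sst <- generateSst(3, cfg)
  v <- sstValues(sst)
  # rows run north (cold) to south (warm): strictly increasing down columns
  expect_true(all(diff(v[, 1]) > 0))
  expect_equal(v[, 1], v[, 64])          # purely meridional
  expect_lt(max(abs(v[1, ] - 14)), 1e-9)
  expect_lt(max(abs(v[40, ] - 29)), 1e-9)
  # identical day + seed -> identical field; other seed differs
  cfg2 <- worldConfig(seed = 2)
  expect_identical(sstValues(generateSst(5, cfg2)),
                   sstValues(generateSst(5, cfg2)))
  expect_false(identical(sstValues(generateSst(5, cfg2)),
                         sstValues(generateSst(5, worldConfig(seed = 3)))))
})

test_that("default fields have land, texture and finite values", {
  cfg <- worldConfig(seed = 4)
  sst <- generateSst(1, cfg)
  expect_true(all(is.finite(sstValues(sst))))
  expect_equal(sum(sstMask(sst)), 3 * 40)      # the land stripe
  expect_true(all(sstValues(sst)[sstMask(sst)] == 0))
})

test_that("true grounds always sit inside the habitat band", {
  cfg <- worldConfig(seed = 5)
  for (d in 1:30) {
    sst <- generateSst(d, cfg)
    tg <- placeTrueGrounds(sst, cfg)
    expect_lte(nrow(tg), cfg$nTrueGrounds)
    if (nrow(tg)) {
      cells <- latlonToCell(tg$lat, tg$lon, cfg$grid)
      v <- sstValues(sst)[cbind(cells$row, cells$col)]
      expect_true(all(v >= 19 & v <= 26))
    }
  }
  # an all-warm ocean leaves no habitat: empty ground set
  hot <- sstMap(matrix(30, 40, 64), cfg$grid, "2020-01-01")
  expect_equal(nrow(placeTrueGrounds(hot, cfg)), 0L)
})

test_that("ground placement prefers strong SST gradients", {
  cfg <- worldConfig(seed = 6, nTrueGrounds = 1L)
  grads <- numeric(0)
  allGrads <- numeric(0)
  for (d in 1:100) {
    sst <- generateSst(d, cfg)
    v <- sstValues(sst)
    gm <- sqrt((rbind(v[-1, ], v[nrow(v), ]) - v)^2 +
               (cbind(v[, -1], v[, ncol(v)]) - v)^2)
    band <- v >= 19 & v <= 26 & !sstMask(sst)
    tg <- placeTrueGrounds(sst, cfg)
    if (!nrow(tg)) next
    cells <- latlonToCell(tg$lat, tg$lon, cfg$grid)
    grads <- c(grads, gm[cbind(cells$row, cells$col)])
    allGrads <- c(allGrads, mean(gm[band]))
  }
  # sampled cells are steeper than the band average, persistently
  expect_gt(mean(grads), mean(allGrads))
})

test_that("vessel-days close the loop with the labeling rules", {
  cfg <- worldConfig(seed = 7, pTransit = 1)
  sst <- generateSst(1, cfg)
  tg <- placeTrueGrounds(sst, cfg)
  vc <- simulateVesselsAndCatch(tg, cfg, as.Date("2020-01-01"))
  inst <- labelInstances(trajectories = vc$trajectories)
  expect_true(all(inst$label == "Unlikely"))
  # full observation, no jitter: a Good record at every true ground
  cfg2 <- worldConfig(seed = 8, fractionCatchObserved = 1,
                      trajectoryNoiseKm = 0, pZeroCpue = 0)
  sst2 <- generateSst(2, cfg2)
  tg2 <- placeTrueGrounds(sst2, cfg2)
  vc2 <- simulateVesselsAndCatch(tg2, cfg2, as.Date("2020-01-02"))
  good <- vc2$catch[vc2$catch$cpue > 0, ]
  expect_equal(nrow(good), nrow(tg2))
  expect_equal(sort(good$lat), sort(tg2$lat))
  inst2 <- labelInstances(catch = vc2$catch)
  expect_true(all(inst2$label == "Good"))
})

test_that("the transit share matches pTransit within a binomial interval", {
  cfg <- worldConfig(seed = 9, pTransit = 0.3, nVessels = 10L)
  n <- 0L; transit <- 0L
  for (d in 1:20) {
    sst <- generateSst(d, cfg)
    tg <- placeTrueGrounds(sst, cfg)
    vc <- simulateVesselsAndCatch(tg, cfg, as.Date("2020-01-01") + d)
    inst <- labelInstances(trajectories = vc$trajectories)
    n <- n + nrow(inst)
    transit <- transit + sum(inst$label == "Unlikely")
  }
  expect_equal(n, 200L)
  ci <- 0.3 + c(-1, 1) * 3 * sqrt(0.3 * 0.7 / 200)
  expect_gt(transit / n, ci[1])
  expect_lt(transit / n, ci[2])
})

test_that("worlds split into disjoint, exhaustive, seed-stable phases", {
  w <- tinyWorld(seed = 10)
  dates <- lapply(c("pretrain", "finetune", "test"),
                  function(s) sapply(w[[s]], function(d) format(d$date)))
  expect_equal(lengths(dates), c(10L, 8L, 4L))
  expect_equal(anyDuplicated(unlist(dates)), 0L)
  w2 <- tinyWorld(seed = 10)
  expect_identical(sstValues(w$pretrain[[3]]$sst),
                   sstValues(w2$pretrain[[3]]$sst))
  expect_identical(w$finetune[[2]]$catch, w2$finetune[[2]]$catch)
  w3 <- tinyWorld(seed = 11)
  expect_false(identical(sstValues(w$pretrain[[3]]$sst),
                         sstValues(w3$pretrain[[3]]$sst)))
})

test_that("generated records flow through annotation with the intended labels", {
  w <- tinyWorld(seed = 12)
  for (day in w$pretrain[1:5]) {
    inst <- labelInstances(catch = day$catch, trajectories = day$trajectories)
    expect_true(all(inst$label[inst$source == "catch"] %in% c("Good", "Bad")))
    expect_true(all(inst$label[inst$source == "trajectory"] %in%
                    c("Unlikely", "Unknown")))
    filt <- habitatFilter(inst, day$sst)
    hm <- buildHeatmap(filt[filt$source == "trajectory", , drop = FALSE],
                       day$sst@grid, 2L, source = "trajectory",
                       date = day$date)
    expect_true(all(heatmapArray(hm) >= 0 & heatmapArray(hm) <= 1))
  }
})

test_that("more positional trajectory noise lowers the mean confidence target", {
  mkMean <- function(noise) {
    w <- buildWorld(worldConfig(nDays = c(pretrain = 15L, finetune = 2L,
                                          test = 2L),
                                seed = 13, trajectoryNoiseKm = noise))
    mean(sapply(worldDatasets(w, 2L)$confPairs, `[[`, "c"))
  }
  expect_gt(mkMean(5), mkMean(250))
})

test_that("world CSV round-trips through the annotation readers", {
  w <- tinyWorld(seed = 14)
  dir <- tempfile("world")
  writeWorldCsv(w, dir)
  catch <- readCatchCsv(file.path(dir, "finetune_catch.csv"))
  traj <- readTrajectoryCsv(file.path(dir, "pretrain_trajectories.csv"))
  expect_equal(nrow(catch), sum(sapply(w$finetune, function(d) nrow(d$catch))))
  expect_true(all(c("vessel_id", "timestamp") %in% names(traj)))
  sst <- readSstCsv(file.path(dir, sprintf("sst_%s.csv",
                                           format(w$test[[1]]$date))),
                    w$cfg$grid, w$test[[1]]$date)
  expect_equal(sstValues(sst), sstValues(w$test[[1]]$sst))
  expect_equal(sstMask(sst), sstMask(w$test[[1]]$sst))
  unlink(dir, recursive = TRUE)
})

test_that("a kernel-painting oracle predictor is scored perfectly on a clean world", {
  w <- buildWorld(worldConfig(nDays = c(pretrain = 2L, finetune = 2L,
                                        test = 6L),
                              seed = 15, fractionCatchObserved = 1,
                              trajectoryNoiseKm = 0, pZeroCpue = 0))
  g <- w$cfg$grid
  tallies <- lapply(w$test, function(day) {
    cells <- latlonToCell(day$trueGrounds$lat, day$trueGrounds$lon, g)
    px <- fishgrounds:::cellToHeatmapPixel(cells$row, cells$col, 2L)
    hm <- gaussianKernelHeatmap(px, heatmapDim(g, 2L), sigma = 7)
    pred <- new("Heatmap3",
                array = array(c(hm, hm * 0, hm * 0), c(dim(hm), 3L)),
                provenance = "predicted", grid = g, stride = 2L,
                sigma = NA_real_, date = day$date)
    scoreDay(detectPeaks(pred, threshold = 0.1), dayTruthDf(day))
  })
  r <- aggregateEval(tallies)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
})
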