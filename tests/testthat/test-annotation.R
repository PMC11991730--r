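fixesDf <- function(lat, lon) data.frame(lat = lat, lon = lon)

test_that("daily displacement separates transit from candidate fishing days", {
  expect_equal(dailyDisplacement(fixesDf(c(30, 30), c(150, 150))), 0)
  # ~2 deg of longitude at 30N is under the 200-km transit threshold
  d1 <- dailyDisplacement(fixesDf(c(30, 30), c(150, 152)))
  expect_equal(d1, geodesicKm(30, 150, 30, 152))
  expect_lt(d1, 200)
  # 2.5 deg of latitude is a transit day
  d2 <- dailyDisplacement(fixesDf(c(30, 32.5), c(150, 150)))
  expect_gt(d2, 200)
  expect_equal(d2, 2.5 * 6371 * pi / 180, tolerance = 1e-10)
  expect_error(dailyDisplacement(fixesDf(30, 150)), "2 fixes")
})

test_that("mean daily position averages safely across the antimeridian", {
  expect_equal(meanDailyPosition(fixesDf(33, 145)),
               data.frame(lat = 33, lon = 145))
  m <- meanDailyPosition(fixesDf(c(0, 0), c(179, -179)))
  expect_equal(m$lon, 180)
  m2 <- meanDailyPosition(fixesDf(c(34, 36), c(150, 151)))
  expect_equal(m2$lat, 35)
  expect_error(meanDailyPosition(fixesDf(numeric(), numeric())), "fixes")
})

test_that("labeling follows the CPUE and displacement rules exactly", {
  catch <- data.frame(date = as.Date("2020-01-01"), lat = c(33, 34),
                      lon = c(145, 146), cpue = c(2.5, 0))
  traj <- rbind(
    data.frame(vessel_id = "A", date = as.Date("2020-01-01"),
               timestamp = 1:2, lat = c(33, 35.3), lon = 145),      # ~256 km
    data.frame(vessel_id = "B", date = as.Date("2020-01-01"),
               timestamp = 1:2, lat = c(33, 33.2), lon = 145))      # short
  inst <- labelInstances(catch, traj)
  expect_setequal(levels(inst$label), c("Good", "Bad", "Unlikely", "Unknown"))
  expect_equal(as.character(inst$label[inst$source == "catch"]),
               c("Good", "Bad"))
  trajLab <- inst[inst$source == "trajectory", ]
  expect_equal(sort(as.character(trajLab$label)), c("Unknown", "Unlikely"))
  # every record yields exactly one label, and source constrains the label
  expect_equal(nrow(inst), 4L)
  expect_true(all(inst$label[inst$source == "catch"] %in% c("Good", "Bad")))
  expect_true(all(inst$label[inst$source == "trajectory"] %in%
                  c("Unlikely", "Unknown")))
})

test_that("habitat filter drops trajectory points outside 19-26 C or on land", {
  g <- tinyGrid()
  v <- matrix(22, nRows(g), nCols(g))
  v[, 1] <- 18.9          # too cold
  v[, 2] <- 26.1          # too warm
  v[, 3] <- NA            # land / missing
  sst <- sstMap(v, g, "2020-01-01")
  mk <- function(col, source) {
    p <- cellToLatlon(3, col, g)
    data.frame(date = as.Date("2020-01-01"), lat = p$lat, lon = p$lon,
               label = if (source == "catch") "Good" else "Unknown",
               source = source)
  }
  inst <- rbind(mk(1, "trajectory"), mk(2, "trajectory"), mk(3, "trajectory"),
                mk(5, "trajectory"), mk(1, "catch"))
  out <- habitatFilter(inst, sst)
  # only the 22 C trajectory point survives; catch passes untouched
  expect_equal(nrow(out), 2L)
  expect_setequal(out$source, c("trajectory", "catch"))
  expect_equal(latlonToCell(out$lat[out$source == "trajectory"],
                            out$lon[out$source == "trajectory"], g)$col, 5L)
})

test_that("Gaussian kernels have unit peaks and the exact closed form", {
  hm <- gaussianKernelHeatmap(data.frame(row = 10, col = 10), c(32, 32),
                              sigma = 7)
  expect_equal(hm[10, 10], 1)
  expect_equal(hm[10, 17], exp(-0.5))       # pixel distance sigma
  expect_equal(hm[17, 10], exp(-0.5))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_equal(gaussianKernelHeatmap(data.frame(row = integer(),
                                                col = integer()),
                                     c(8, 8), 7),
               matrix(0, 8, 8))
  expect_error(gaussianKernelHeatmap(data.frame(row = 1, col = 1), c(8, 8),
                                     sigma = 0), "sigma")
})

test_that("kernel rasters agree with a per-pixel brute-force loop", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1:4, 1)
    pts <- data.frame(row = sample.int(32, n, replace = TRUE),
                      col = sample.int(32, n, replace = TRUE))
    sig <- sample(c(2, 4, 7), 1)
    expect_equal(gaussianKernelHeatmap(pts, c(32, 32), sig),
                 bruteKernel(pts, c(32, 32), sig), tolerance = 1e-12)
  }
  # two points one pixel apart: midpoint takes the max of the two kernels
  pts <- data.frame(row = c(5, 5), col = c(5, 6))
  expect_equal(gaussianKernelHeatmap(pts, c(12, 12), 2),
               bruteKernel(pts, c(12, 12), 2), tolerance = 1e-12)
})

test_that("per-day heatmaps implement the label-to-channel table", {
  g <- tinyGrid()
  d <- as.Date("2020-01-01")
  catchInst <- data.frame(date = d, lat = c(34, 33), lon = c(144, 145),
                          label = c("Good", "Bad"), source = "catch")
  hmC <- buildHeatmap(catchInst, g, 2L, sigma = 2)
  expect_s4_class(hmC, "Heatmap3")
  expect_equal(provenance(hmC), "catch")
  expect_equal(max(heatmapChannel(hmC, "Good")), 1)
  expect_equal(max(heatmapChannel(hmC, "Bad")), 1)
  expect_equal(heatmapChannel(hmC, "Unlikely"),
               matrix(0, 8, 12))
  trajInst <- data.frame(date = d, lat = c(34, 33.5, 33), lon = c(144, 144.5, 146),
                         label = c("Unknown", "Unknown", "Unlikely"),
                         source = "trajectory")
  hmT <- buildHeatmap(trajInst, g, 2L, sigma = 2)
  expect_equal(heatmapChannel(hmT, "Good"), heatmapChannel(hmT, "Bad"))
  expect_equal(max(heatmapChannel(hmT, "Unlikely")), 1)
  # permutation invariance in the instance list
  hmT2 <- buildHeatmap(trajInst[c(3, 1, 2), ], g, 2L, sigma = 2)
  expect_identical(heatmapArray(hmT), heatmapArray(hmT2))
  # mixed sources refuse to combine
  expect_error(buildHeatmap(rbind(catchInst, trajInst), g, 2L, sigma = 2),
               "mix")
  # no instances at all -> all-zero channels
  hm0 <- buildHeatmap(catchInst[0, ], g, 2L, sigma = 2, date = d)
  expect_true(all(heatmapArray(hm0) == 0))
})

test_that("heatmaps round-trip channel maxima with instance presence", {
  g <- tinyGrid()
  d <- as.Date("2020-01-01")
  inst <- data.frame(date = d, lat = 34, lon = 144, label = "Good",
                     source = "catch")
  hm <- buildHeatmap(inst, g, 2L, sigma = 3)
  expect_equal(max(heatmapChannel(hm, "Good")), 1)   # a kernel peaks at 1
  expect_equal(max(heatmapChannel(hm, "Bad")), 0)    # no Bad instance
  expect_true(all(heatmapArray(hm) >= 0 & heatmapArray(hm) <= 1))
})

test_that("heatmaps round-trip through their CSV + manifest persistence", {
  g <- tinyGrid()
  inst <- data.frame(date = as.Date("2020-01-01"), lat = c(34, 33.5),
                     lon = c(144, 145.25), label = c("Unknown", "Unlikely"),
                     source = "trajectory")
  hm <- buildHeatmap(inst, g, 2L, sigma = 3)
  base <- tempfile("hm")
  writeHeatmap(hm, base)
  back <- readHeatmap(base)
  expect_equal(heatmapArray(back), heatmapArray(hm), tolerance = 1e-12)
  expect_equal(provenance(back), "trajectory")
  expect_equal(back@stride, 2L)
  expect_equal(back@sigma, 3)
  expect_equal(back@grid@latMax, g@latMax)
})
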