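#' Synthetic world configuration
#'
#' Parameters of the fully synthetic ocean/vessel/catch simulator that
#' stands in for real SST, logbook and AIS archives. Daily SST is a
#' meridional (north--south) gradient plus smooth low-pass noise and
#' Gaussian eddies; true fishing grounds sit in the 19--26 C habitat band
#' with probability proportional to the local SST-gradient magnitude;
#' vessels either transit (long straight day-tracks, start--end
#' displacement above 200 km) or loiter near a true ground; catch logs
#' observe each ground only partially and include zero-CPUE visits.
#'
#' @param grid the raster frame (default: a 40 x 64 cell, 0.25-degree
#'   frame at 30--39.75N, 140E--155.75E)
#' @param nDays named integer vector: days per phase split
#'   (pretrain/finetune/test, default 120/40/20)
#' @param sstNorth,sstSouth SST at the north and south edge in C (14, 29;
#'   they straddle the habitat band so it forms a latitudinal strip)
#' @param noiseScale length scale of the smooth SST noise in cells (3)
#' @param noiseAmp sd of the smooth noise in C (0.8)
#' @param nEddies Gaussian eddies per day (4)
#' @param eddyAmp eddy amplitude in C (2.5)
#' @param eddyRadius eddy radius in cells (4)
#' @param habitatBand thermal band of the target species in C (c(19, 26))
#' @param nTrueGrounds true fishing grounds per day (3)
#' @param minGroundSepKm minimum pairwise separation between a day's true
#'   grounds in km (300; grounds closer than the 200-km evaluation radius
#'   would count as one location, so distinct grounds are kept clearly
#'   apart)
#' @param fractionCatchObserved probability a true ground appears in the
#'   catch log as a CPUE>0 record (0.6: catch data are partial)
#' @param pZeroCpue probability a loitering vessel-day logs a zero-CPUE
#'   record at its visited location (0.3)
#' @param nVessels vessels per day (6)
#' @param pTransit probability a vessel-day is transit (0.3)
#' @param trajectoryNoiseKm sd of the jitter between a loitering vessel's
#'   daily mean position and its true ground, in km (60; positional label
#'   noise)
#' @param landCols western columns masked as land (3; 0 disables)
#' @param seed world seed; every field and record is determined by it
#' @return a `WorldConfig` (list)
#' @export
worldConfig <- function(grid = NULL,
                        nDays = c(pretrain = 120L, finetune = 40L, test = 20L),
                        sstNorth = 14, sstSouth = 29,
                        noiseScale = 3, noiseAmp = 0.8,
                        nEddies = 4L, eddyAmp = 2.5, eddyRadius = 4,
                        habitatBand = c(19, 26),
                        nTrueGrounds = 3L, minGroundSepKm = 300,
                        fractionCatchObserved = 0.6,
                        pZeroCpue = 0.3, nVessels = 6L, pTransit = 0.3,
                        trajectoryNoiseKm = 60, landCols = 3L, seed = 1L) {
  if (is.null(grid))
    grid <- gridSpec(latMin = 30, latMax = 39.75, lonStart = 140,
                     lonExtent = 15.75, cellDeg = 0.25)
  stopifnot(fractionCatchObserved > 0, fractionCatchObserved <= 1,
            pZeroCpue >= 0, pZeroCpue <= 1, pTransit >= 0, pTransit <= 1,
            habitatBand[1] < habitatBand[2])
  if (!(min(sstNorth, sstSouth) < habitatBand[1] &&
        max(sstNorth, sstSouth) > habitatBand[2]))
    stop("SST gradient endpoints must straddle the habitat band")
  structure(list(grid = grid, nDays = nDays, sstNorth = sstNorth,
                 sstSouth = sstSouth, noiseScale = noiseScale,
                 noiseAmp = noiseAmp, nEddies = as.integer(nEddies),
                 eddyAmp = eddyAmp, eddyRadius = eddyRadius,
                 habitatBand = habitatBand,
                 nTrueGrounds = as.integer(nTrueGrounds),
                 minGroundSepKm = minGroundSepKm,
                 fractionCatchObserved = fractionCatchObserved,
                 pZeroCpue = pZeroCpue, nVessels = as.integer(nVessels),
                 pTransit = pTransit, trajectoryNoiseKm = trajectoryNoiseKm,
                 landCols = as.integer(landCols), seed = as.integer(seed)),
            class = "WorldConfig")
}

# Circular (wrap-around) Gaussian smoothing of a matrix, separable.
smoothCircular <- function(m, sd) {
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-(-half:half)^2 / (2 * sd^2))
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (o in -half:half)
      out <- out + k[o + half + 1] * v[((seq_len(n) - 1 + o) %% n) + 1]
    out
  }
  m <- apply(m, 2, sm1)
  t(apply(m, 1, sm1))
}

#' Generate one day's synthetic SST field
#'
#' Meridional gradient between the configured endpoints, plus low-pass
#' Gaussian noise rescaled to `noiseAmp`, plus `nEddies` Gaussian bumps of
#' random sign, centre and radius. The westernmost `landCols` columns are
#' masked as land (missing, zero-filled). Deterministic in
#' `(cfg$seed, day)`.
#'
#' @param day 1-based day index
#' @param cfg a [worldConfig()]
#' @return a [SSTMap-class]
#' @export
generateSst <- function(day, cfg) {
  g <- cfg$grid
  set.seed((abs(cfg$seed) %% 1000003L) * 2039L + day)
  lat <- g@latMax - (seq_len(g@nRows) - 1) * g@cellDeg
  base <- cfg$sstSouth + (cfg$sstNorth - cfg$sstSouth) *
    (lat - g@latMin) / (g@latMax - g@latMin)
  v <- matrix(base, g@nRows, g@nCols)
  if (cfg$noiseAmp > 0) {
    z <- smoothCircular(matrix(stats::rnorm(g@nRows * g@nCols), g@nRows, g@nCols),
                        cfg$noiseScale)
    s <- stats::sd(as.vector(z))
    if (s > 0) v <- v + z / s * cfg$noiseAmp
  }
  if (cfg$nEddies > 0 && cfg$eddyAmp > 0) {
    rows <- matrix(seq_len(g@nRows), g@nRows, g@nCols)
    cols <- matrix(seq_len(g@nCols), g@nRows, g@nCols, byrow = TRUE)
    for (e in seq_len(cfg$nEddies)) {
      ci <- stats::runif(1, 1, g@nRows)
      cj <- stats::runif(1, 1, g@nCols)
      amp <- sample(c(-1, 1), 1) * cfg$eddyAmp * stats::runif(1, 0.5, 1)
      rad <- cfg$eddyRadius * stats::runif(1, 0.7, 1.3)
      v <- v + amp * exp(-((rows - ci)^2 + (cols - cj)^2) / (2 * rad^2))
    }
  }
  if (cfg$landCols > 0) v[, seq_len(cfg$landCols)] <- NA
  sstMap(v, g, as.Date("2020-01-01") + (day - 1))
}

#' Place the day's true fishing grounds
#'
#' Samples up to `nTrueGrounds` distinct cells from the habitat band
#' (19--26 C, non-missing), with probability proportional to the local
#' SST-gradient magnitude -- grounds concentrate along fronts and eddy
#' edges, the patterns fishers read. Grounds are drawn sequentially with
#' a `minGroundSepKm` exclusion radius so a day's grounds are distinct
#' locations at the evaluation's 200-km resolution. Returns an empty set
#' when the band is empty, and fewer grounds when the band cannot hold
#' `nTrueGrounds` separated ones.
#'
#' @param sst the day's [SSTMap-class]
#' @param cfg a [worldConfig()]
#' @return data.frame with `lat`, `lon` (0 to `nTrueGrounds` rows)
#' @export
placeTrueGrounds <- function(sst, cfg) {
  g <- sst@grid
  v <- sst@values
  band <- !sst@mask & v >= cfg$habitatBand[1] & v <= cfg$habitatBand[2]
  idx <- which(band)
  if (!length(idx)) return(data.frame(lat = numeric(), lon = numeric()))
  gy <- rbind(v[2, , drop = FALSE] - v[1, , drop = FALSE],
              (v[-(1:2), , drop = FALSE] - v[seq_len(nrow(v) - 2), , drop = FALSE]) / 2,
              v[nrow(v), , drop = FALSE] - v[nrow(v) - 1, , drop = FALSE])
  gx <- cbind(v[, 2, drop = FALSE] - v[, 1, drop = FALSE],
              (v[, -(1:2), drop = FALSE] - v[, seq_len(ncol(v) - 2), drop = FALSE]) / 2,
              v[, ncol(v), drop = FALSE] - v[, ncol(v) - 1, drop = FALSE])
  grad <- sqrt(gx^2 + gy^2)
  w <- grad[idx] + 1e-6
  rc <- arrayInd(idx, dim(v))
  pos <- cellToLatlon(rc[, 1], rc[, 2], g)
  chosen <- integer()
  avail <- seq_along(idx)
  while (length(chosen) < cfg$nTrueGrounds && length(avail)) {
    k <- avail[sample.int(length(avail), 1L, prob = w[avail])]
    chosen <- c(chosen, k)
    far <- geodesicKm(pos$lat[avail], pos$lon[avail],
                      pos$lat[k], pos$lon[k]) >= cfg$minGroundSepKm
    avail <- avail[far]
  }
  pos[chosen, , drop = FALSE]
}

# Clamp a point into the grid's geographic extent (small margin).
clampToGrid <- function(lat, lon, g, marginCells = 1) {
  m <- marginCells * g@cellDeg
  lat <- pmin(pmax(lat, g@latMin + m), g@latMax - m)
  off <- lonOffset(lon, g)
  off <- pmin(pmax(off, m), g@lonExtent - m)
  data.frame(lat = lat, lon = normalizeLon(g@lonStart + off))
}

#' Simulate one day's vessels and catch log
#'
#' Each vessel-day is a transit with probability `pTransit`: a near
#' straight hourly track whose start--end displacement exceeds 200 km
#' (labelled Unlikely downstream). Otherwise the vessel loiters around a
#' true ground whose centre is jittered by `trajectoryNoiseKm` (positional
#' label noise; the day labels Unknown). The catch log records each true
#' ground with probability `fractionCatchObserved` as a CPUE>0 row
#' (log-normal CPUE; only the >0 dichotomy matters downstream), and each
#' loitering vessel adds a zero-CPUE row at its visited centre with
#' probability `pZeroCpue`.
#'
#' @param trueGrounds data.frame `lat`, `lon` from [placeTrueGrounds()]
#' @param cfg a [worldConfig()]
#' @param date the day's date
#' @return list: `trajectories` (vessel_id, date, timestamp, lat, lon) and
#'   `catch` (date, lat, lon, cpue) data.frames
#' @export
simulateVesselsAndCatch <- function(trueGrounds, cfg, date = as.Date("2020-01-01")) {
  g <- cfg$grid
  kmLat <- 111.19
  trajRows <- list()
  zeroRows <- list()
  for (v in seq_len(cfg$nVessels)) {
    nFix <- sample(8:12, 1)
    hours <- seq(0, 23, length.out = nFix)
    if (stats::runif(1) < cfg$pTransit || nrow(trueGrounds) == 0L) {
      # transit: straight track, displacement in (220, 420) km
      start <- clampToGrid(stats::runif(1, g@latMin, g@latMax),
                           g@lonStart + stats::runif(1, 0, g@lonExtent), g,
                           marginCells = 2)
      len <- stats::runif(1, 220, 420)
      ang <- stats::runif(1, 0, 2 * pi)
      frac <- seq(0, 1, length.out = nFix)
      lat <- start$lat + frac * len * sin(ang) / kmLat
      lon <- start$lon + frac * len * cos(ang) / (kmLat * cos(start$lat * pi / 180))
      # keep inside the frame; reflect latitude if the line runs out
      p <- clampToGrid(lat, lon, g)
      # clamping can shorten the track below 200 km; re-aim toward the
      # frame interior until the displacement is a genuine transit
      tries <- 0
      while (geodesicKm(p$lat[1], p$lon[1], p$lat[nFix], p$lon[nFix]) <= 210 &&
             tries < 20) {
        ang <- stats::runif(1, 0, 2 * pi)
        lat <- start$lat + frac * len * sin(ang) / kmLat
        lon <- start$lon + frac * len * cos(ang) / (kmLat * cos(start$lat * pi / 180))
        p <- clampToGrid(lat, lon, g)
        tries <- tries + 1
      }
    } else {
      gi <- sample.int(nrow(trueGrounds), 1)
      jit <- stats::rnorm(2, 0, cfg$trajectoryNoiseKm)
      centre <- clampToGrid(
        trueGrounds$lat[gi] + jit[1] / kmLat,
        trueGrounds$lon[gi] + jit[2] / (kmLat * cos(trueGrounds$lat[gi] * pi / 180)),
        g)
      wig <- 15  # km, loitering wiggle around the centre
      lat <- centre$lat + stats::rnorm(nFix, 0, wig / kmLat)
      lon <- centre$lon + stats::rnorm(nFix, 0, wig / (kmLat * cos(centre$lat * pi / 180)))
      p <- clampToGrid(lat, lon, g)
      if (stats::runif(1) < cfg$pZeroCpue)
        zeroRows[[length(zeroRows) + 1L]] <-
          data.frame(date = date, lat = centre$lat, lon = centre$lon, cpue = 0)
    }
    trajRows[[v]] <- data.frame(vessel_id = sprintf("V%02d", v), date = date,
                                timestamp = hours, lat = p$lat, lon = p$lon)
  }
  obs <- if (nrow(trueGrounds)) stats::runif(nrow(trueGrounds)) < cfg$fractionCatchObserved
         else logical(0)
  goodRows <- if (any(obs))
    data.frame(date = date, lat = trueGrounds$lat[obs], lon = trueGrounds$lon[obs],
               cpue = stats::rlnorm(sum(obs), meanlog = 1, sdlog = 0.5))
  else NULL
  catch <- do.call(rbind, c(list(goodRows), zeroRows))
  if (is.null(catch))
    catch <- data.frame(date = as.Date(character()), lat = numeric(),
                        lon = numeric(), cpue = numeric())
  list(trajectories = do.call(rbind, trajRows), catch = catch)
}

#' Build a full synthetic world
#'
#' Generates `sum(nDays)` consecutive days -- SST field, true grounds,
#' trajectories and catch log per day -- and splits them into disjoint
#' phase ranges: pre-training (trajectory) days, fine-tuning (catch) days
#' and test (catch) days. Pre-training days keep their catch logs too, so
#' paired (catch, trajectory) heatmaps for confidence-target construction
#' come from that split. Fully determined by `cfg$seed`.
#'
#' @param cfg a [worldConfig()]
#' @return a list with `cfg` and lists `pretrain`, `finetune`, `test` of
#'   world-days (each `list(date, sst, trueGrounds, catch, trajectories)`)
#' @export
buildWorld <- function(cfg = worldConfig()) {
  nAll <- sum(cfg$nDays)
  days <- vector("list", nAll)
  for (d in seq_len(nAll)) {
    sst <- generateSst(d, cfg)   # seeds the RNG for the whole day
    tg <- placeTrueGrounds(sst, cfg)
    vc <- simulateVesselsAndCatch(tg, cfg, date = sst@date)
    days[[d]] <- list(date = sst@date, sst = sst, trueGrounds = tg,
                      catch = vc$catch, trajectories = vc$trajectories)
  }
  n1 <- cfg$nDays[["pretrain"]]; n2 <- cfg$nDays[["finetune"]]
  list(cfg = cfg,
       pretrain = days[seq_len(n1)],
       finetune = days[n1 + seq_len(n2)],
       test = days[(n1 + n2 + 1):nAll])
}

#' Write a world to interchange CSV/raster files
#'
#' Emits the same formats the annotation readers consume: per-split catch
#' and trajectory CSVs and one SST raster CSV per day, so synthetic and
#' real data are interchangeable.
#'
#' @param world from [buildWorld()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeWorldCsv <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("pretrain", "finetune", "test")) {
    dd <- world[[split]]
    catch <- do.call(rbind, lapply(dd, `[[`, "catch"))
    traj <- do.call(rbind, lapply(dd, `[[`, "trajectories"))
    writeCatchCsv(catch, file.path(dir, paste0(split, "_catch.csv")))
    writeTrajectoryCsv(traj, file.path(dir, paste0(split, "_trajectories.csv")))
    for (d in dd)
      writeSstCsv(d$sst, file.path(dir, sprintf("sst_%s.csv", format(d$date))))
  }
  invisible(dir)
}
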