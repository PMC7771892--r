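test_that("hybrid frames are excluded with order preserved and counts reported", {
  fr <- lapply(1:3, function(i) matrix(i, 4, 4))
  st <- ImageStack(fr, c("BF", "HYBRID", "DF"))
  out <- suppressMessages(excludeHybridFrames(st))
  expect_identical(attr(out, "removed"), 1L)
  expect_identical(frameLabels(out), c("BF", "DF"))
  expect_identical(ledIndex(out), c(1L, 3L))
  expect_identical(out[[1]], fr[[1]])
  expect_identical(out[[2]], fr[[3]])
  ## all-BF stack is a no-op
  stb <- ImageStack(fr, rep("BF", 3))
  expect_identical(frames(excludeHybridFrames(stb)), frames(stb))
  ## removing everything BF fails
  sth <- ImageStack(fr, c("HYBRID", "HYBRID", "DF"))
  expect_error(excludeHybridFrames(sth), "unusable")
})

test_that("hybrid exclusion count matches a brute-force per-LED NA computation", {
  geom <- FPMGeometry(ledGrid(9, 2.2), arrayHeight = 50, wavelength = 532,
                      objectiveNA = 0.16, hybridBand = 0.02)
  obj <- makeBarTarget(96, barPeriods = c(6, 4), pixelSize = 0.4)
  st <- simulateStack(obj, geom, 40)
  out <- suppressMessages(excludeHybridFrames(st))
  ## oracle: recompute every LED's illumination NA from raw trigonometry
  p <- ledPositions(geom)
  naOracle <- sin(atan(sqrt(p[, 1]^2 + p[, 2]^2) / 50))
  nHybrid <- sum(naOracle > 0.14 & naOracle < 0.18)
  expect_identical(attr(out, "removed"), nHybrid)
  expect_identical(nFrames(out), nrow(p) - nHybrid)
})

test_that("the default SdA schedule feeds S4 to iterations 1..N-1 and S3 to the last", {
  sch <- ReconSchedule(10)
  expect_identical(sch@stackRoles, c(rep("S4", 9), "S3"))
  expect_identical(ReconSchedule(1)@stackRoles, "S3")
  expect_error(validObject(new("ReconSchedule", nIterations = 2L,
                               stackRoles = "S3", frameOrder = integer(),
                               stepSize = 1, delta = 1e-3)),
               "every iteration")
})

test_that("reconstruction errors when the schedule requests a missing stack role", {
  obj <- makeBarTarget(96, barPeriods = c(6, 4), pixelSize = 0.4)
  geom <- smallGeometry()
  st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
  expect_error(
    fpmReconstruct(list(S3 = st), obj, geom, ReconSchedule(3)),
    "S4")
})

test_that("a ground-truth initialisation is a fixed point of the noise-free update", {
  obj <- makeBarTarget(96, barPeriods = c(8, 6), pixelSize = 0.4)
  geom <- smallGeometry(n = 5, pitch = 5.5)
  st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
  rec0 <- fpmReconstruct(st, obj, geom, ReconSchedule(6, stackRoles = "S1"))
  ## feed the converged field back in: one more sweep must not move it
  init <- ComplexObject(Mod(reconField(rec0)), Arg(reconField(rec0)),
                        pixelSize = 0.4)
  rec1 <- fpmReconstruct(st, obj, geom, ReconSchedule(1, stackRoles = "S1"),
                         init = init)
  expect_lt(mean(Mod(reconField(rec1) - reconField(rec0))^2) /
              mean(Mod(reconField(rec0))^2), 1e-6)
})

test_that("noise-free round trip recovers the band-limited object and residuals decrease", {
  obj <- makeBarTarget(96, barPeriods = c(8, 6, 4), pixelSize = 0.4)
  geom <- FPMGeometry(ledGrid(9, 4.4, circleDiameter = 40), 50, 532, 0.2)
  st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
  rec <- fpmReconstruct(st, obj, geom, ReconSchedule(10, stackRoles = "S1"))
  bl <- bandLimitField(obj, syntheticNA(rec), 532)
  al <- alignFields(reconField(rec), bl)
  expect_gt(imageSSIM(Mod(al), Mod(bl)), 0.9)
  expect_true(all(diff(residuals(rec)) <= 1e-8))
})

test_that("per-iteration residuals are non-increasing on noise-free stacks over several objects", {
  geom <- smallGeometry(n = 5, pitch = 5.5)
  for (seed in 1:5) {
    obj <- makeTextureObject(96, seed = seed, pixelSize = 0.4)
    st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
    rec <- fpmReconstruct(st, geom = geom, object = obj,
                          schedule = ReconSchedule(5, stackRoles = "S1"))
    r <- residuals(rec)
    ## tolerate 1% per-step fluctuation after the first iteration
    expect_true(all(diff(r) <= 0.01 * r[-length(r)]))
  }
})

test_that("recovered spectrum energy is confined to the synthetic NA disc", {
  obj <- makeTextureObject(96, seed = 3, pixelSize = 0.4)
  geom <- smallGeometry(n = 5, pitch = 5.5)
  st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
  rec <- fpmReconstruct(st, obj, geom, ReconSchedule(4, stackRoles = "S1"))
  O <- fftShift2(stats::fft(reconField(rec)))
  df <- 1 / (96 * 0.4)
  rPix <- syntheticNA(rec) / 0.532 / df
  d <- seq_len(96) - (floor(96 / 2) + 1)
  outside <- sqrt(outer(d^2, d^2, "+")) > rPix + 1
  expect_lt(sum(Mod(O[outside])^2), 1e-20 * sum(Mod(O)^2))
})

test_that("all-zero darkfield frames reproduce the BF-only reconstruction exactly", {
  ## geometry whose DF passband windows are disjoint from the BF-covered
  ## central window, so a zero frame is a vacuous constraint
  n <- 96; m <- 24; dx <- 0.5
  dfreq <- 1 / (n * dx)
  naObj <- 0.1
  sOut <- 30                                    # DF window centre, pixels
  naIll <- sOut * dfreq * 0.532
  dmm <- 50 * tan(asin(naIll))
  pos <- rbind(c(0, 0), c(dmm, 0), c(-dmm, 0), c(0, dmm), c(0, -dmm))
  geom <- FPMGeometry(pos, 50, 532, naObj)
  expect_identical(frameLabels(geom), c("BF", rep("DF", 4)))
  obj <- makeTextureObject(96, seed = 4, pixelSize = dx)
  st <- simulateStack(obj, geom, m)
  fr <- frames(st)
  fr[, , 2:5] <- 0
  stz <- ImageStack(fr, frameLabels(st), ledIndex(st))
  stbf <- ImageStack(fr[, , 1, drop = FALSE], "BF", 1L)
  ## deliberately sparse coverage: reconstruction warns but proceeds
  expect_warning(
    recZ <- fpmReconstruct(stz, obj, geom, ReconSchedule(3, stackRoles = "S1")),
    "coverage gap")
  recB <- suppressWarnings(
    fpmReconstruct(stbf, obj, geom, ReconSchedule(3, stackRoles = "S1")))
  expect_equal(reconField(recZ), reconField(recB), tolerance = 1e-12)
})

test_that("synthetic NA equals objective NA plus the maximum illumination NA used", {
  geom <- smallGeometry(n = 5, pitch = 5.5)
  obj <- makeTextureObject(96, seed = 1, pixelSize = 0.4)
  st <- suppressMessages(excludeHybridFrames(simulateStack(obj, geom, 40)))
  rec <- fpmReconstruct(st, obj, geom, ReconSchedule(1, stackRoles = "S1"))
  expect_equal(syntheticNA(rec),
               0.2 + max(illuminationNA(geom)[ledIndex(st)]),
               tolerance = 1e-12)
})
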