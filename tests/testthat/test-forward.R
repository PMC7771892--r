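test_that("uniform object gives a constant on-axis frame and empty darkfield frames", {
  obj <- ComplexObject(matrix(1, 64, 64), matrix(0, 64, 64), pixelSize = 0.4)
  geom <- smallGeometry(n = 3, pitch = 14)
  st <- simulateStack(obj, geom, lrShape = 24, exposure = 100)
  lab <- frameLabels(st)
  onAxis <- st[[which(rowSums(ledPositions(geom)^2) == 0)]]
  expect_equal(max(abs(onAxis - 100)), 0, tolerance = 1e-9)
  for (i in which(lab == "DF"))
    expect_lt(max(st[[i]]), 1e-15 * 100)
  ## summed DF signal vanishes for a structure-free object
  expect_lt(sum(frames(st)[, , lab == "DF"]), 1e-12)
})

test_that("mean frame intensity obeys Parseval against a direct-summation oracle", {
  set.seed(42)
  n <- 64; m <- 24
  amp <- matrix(stats::runif(n * n, 0.2, 1), n)
  ph <- matrix(stats::runif(n * n, 0, pi), n)
  obj <- ComplexObject(amp, ph, pixelSize = 0.4)
  geom <- smallGeometry(n = 3, pitch = 14)
  st <- simulateStack(obj, geom, lrShape = m, exposure = 1)
  ## oracle: spectrum from an explicit DFT-matrix product (no fft), then
  ## direct summation of |spectrum|^2 inside the shifted pupil window
  O <- fftShift2(directDFT2(amp * exp(1i * ph)))
  df <- 1 / (n * 0.4)
  shift <- round(waveVectors(geom) / df)
  rPix <- (0.2 / 0.532) / df
  cm <- floor(m / 2) + 1; cN <- floor(n / 2) + 1
  dd <- seq_len(m) - cm
  pupil <- outer(dd^2, dd^2, "+") <= rPix^2
  for (i in seq_len(length(geom))) {
    W <- O[cN + shift[i, 1] + dd, cN + shift[i, 2] + dd]
    energyOracle <- sum(Mod(W[pupil])^2) / m^2   # Parseval, LR grid
    meanOracle <- energyOracle / m^2 * (m / n)^4
    expect_equal(mean(st[[i]]), meanOracle, tolerance = 1e-8)
  }
})

test_that("forward model is shift-consistent: plane-wave tilted object on axis equals oblique illumination", {
  set.seed(7)
  n <- 64
  amp <- matrix(stats::runif(n * n, 0.2, 1), n)
  obj <- ComplexObject(amp, scalePhase(amp) * 0, pixelSize = 0.4)
  h <- 50
  df <- 1 / (n * 0.4)
  ## LED whose wavevector lands exactly on an integer frequency pixel
  sPix <- 6
  kx <- sPix * df
  naIll <- kx * 0.532
  dmm <- h * tan(asin(naIll))
  geomOblique <- FPMGeometry(rbind(c(dmm, 0)), h, 532, 0.2)
  geomOnAxis <- FPMGeometry(rbind(c(0, 0)), h, 532, 0.2)
  f1 <- simulateStack(obj, geomOblique, 24)[[1]]
  ## tilt the object with the matching plane wave instead
  rowPhase <- exp(2i * pi * sPix * (seq_len(n) - 1) / n)
  field <- amp * matrix(rowPhase, n, n)   # carrier along the row axis
  objTilt <- ComplexObject(Mod(field), Arg(field), pixelSize = 0.4)
  f2 <- simulateStack(objTilt, geomOnAxis, 24)[[1]]
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("degradation is seed-deterministic, seed-sensitive and an identity when disabled", {
  obj <- makeBarTarget(64, barPeriods = c(6, 4), pixelSize = 0.4)
  st <- simulateStack(obj, smallGeometry(), 32, exposure = 1e4)
  idn <- degradeStack(st, NoiseModel(0, 0, 0, seed = 3))
  expect_identical(frames(idn), frames(st))
  a <- degradeStack(st, NoiseModel(100, 50, 1, seed = 3))
  b <- degradeStack(st, NoiseModel(100, 50, 1, seed = 3))
  c <- degradeStack(st, NoiseModel(100, 50, 1, seed = 4))
  expect_identical(frames(a), frames(b))
  expect_false(identical(frames(a), frames(c)))
  expect_true(all(frames(a) >= 0))
  expect_error(NoiseModel(-1, 0, 0), "non-negative")
  expect_error(NoiseModel(0, -2, 0), "non-negative")
})

test_that("Gaussian degradation at sigma 1000 gives sample variance near 1e6", {
  st <- ImageStack(list(matrix(10000, 320, 320)), "DF")
  noisy <- degradeStack(st, NoiseModel(0, 1000, 0, seed = 5))
  expect_equal(stats::var(as.vector(noisy[[1]])), 1e6, tolerance = 0.03)
})

test_that("Poisson degradation reproduces the gain-scaled moments", {
  mu <- 400; g <- 2
  st <- ImageStack(list(matrix(mu, 320, 320)), "DF")  # > 1e5 samples
  noisy <- degradeStack(st, NoiseModel(0, 0, g, seed = 6))
  v <- as.vector(noisy[[1]])
  expect_equal(mean(v), mu, tolerance = 0.01)
  expect_equal(stats::var(v), mu * g, tolerance = 0.03)
})

test_that("configuration errors are raised for impossible grids", {
  obj <- ComplexObject(matrix(1, 64, 64), pixelSize = 0.4)
  geomWide <- FPMGeometry(ledGrid(3, 30), 50, 532, 0.2)
  expect_error(simulateStack(obj, geomWide, 32), "wrap")
  ## pupil radius exceeding the LR frequency grid
  geom <- smallGeometry(n = 3, pitch = 10)
  expect_error(simulateStack(obj, geom, 8), "pupil radius")
})
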