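test_that("background mask excludes the dilated dark object of a two-level frame", {
  n <- 48; r <- 4; s1 <- 5
  ctr <- 24
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  f <- matrix(200, n, n)
  f[d2 <= r^2] <- 20
  M <- buildBackgroundMask(f, s1Radius = s1)
  ## the excluded set lies between the inner and outer Euclidean bounds
  ## of disc-dilated-by-disc
  expect_true(all(!M[d2 <= (r + s1 - 1)^2]))
  expect_true(all(M[d2 > (r + s1)^2]))
  expect_error(buildBackgroundMask(matrix(5, 8, 8)), "constant")
})

test_that("default SdA radii are 20 (s1) and 8 (s2) pixels", {
  expect_identical(formals(buildBackgroundMask)$s1Radius, 20L)
  expect_identical(formals(computeObjectMap)$s2Radius, 8L)
})

test_that("initial background subtraction removes a constant background and clamps at zero", {
  ## 4x4 hand-worked example: constant 5 with one 9-valued pixel
  f <- rbind(c(5, 5, 5, 5), c(5, 5, 9, 5), c(5, 5, 5, 5), c(5, 5, 5, 5))
  M <- matrix(TRUE, 4, 4); M[2, 3] <- FALSE
  st <- ImageStack(list(matrix(7, 4, 4), f), c("BF", "DF"))
  s2 <- subtractInitialBackground(st, M)
  expected <- matrix(0, 4, 4); expected[2, 3] <- 4
  expect_identical(s2[[2]], expected)
  ## BF frames pass through unchanged
  expect_identical(s2[[1]], matrix(7, 4, 4))
  expect_identical(stackRole(s2), "S2")
  ## constant DF frame is removed entirely
  stc <- ImageStack(list(matrix(7, 4, 4), matrix(3, 4, 4)), c("BF", "DF"))
  expect_true(all(subtractInitialBackground(stc, M)[[2]] == 0))
  expect_true(all(s2[[2]] >= 0))
  expect_error(subtractInitialBackground(st, matrix(FALSE, 4, 4)), "empty")
})

test_that("object map is empty for a structureless BF sum and exact for a dark disc", {
  n <- 32
  M <- matrix(TRUE, n, n)
  uni <- ImageStack(list(matrix(100, n, n)), "BF", role = "S2")
  expect_true(all(computeObjectMap(uni, M, s2Radius = 2) == 0))
  ## disc of lowered BF sum: pre-dilation map equals exactly the disc
  d2 <- outer((seq_len(n) - 16)^2, (seq_len(n) - 16)^2, "+")
  disc <- d2 <= 5^2
  f <- matrix(100, n, n); f[disc] <- 40
  Mband <- d2 > 10^2
  st <- ImageStack(list(f), "BF", role = "S2")
  got <- computeObjectMap(st, Mband, s2Radius = 0)
  ## per-pixel inequality oracle: 1/f > max over Mband of 1/f
  oracle <- (1 / f > max(1 / f[Mband])) * 1
  expect_identical(got, oracle)
  expect_identical(unname(got[disc]), rep(1, sum(disc)))
  expect_identical(unname(got[!disc]), rep(0, sum(!disc)))
})

test_that("amplification map matches hand arithmetic and is clamped at zero", {
  ## two 3x3 DF frames summing to 2 everywhere except 8 at the centre
  f1 <- matrix(1, 3, 3); f1[2, 2] <- 5
  f2 <- matrix(1, 3, 3); f2[2, 2] <- 3
  M <- matrix(TRUE, 3, 3); M[2, 2] <- FALSE
  st <- ImageStack(list(matrix(9, 3, 3), f1, f2), c("BF", "DF", "DF"),
                   role = "S2")
  idf <- computeAmplificationMap(st, M)
  expected <- matrix(0, 3, 3); expected[2, 2] <- 6
  expect_identical(idf, expected)
  ## all-zero DF frames give an identically zero map
  z <- ImageStack(list(matrix(9, 3, 3), matrix(0, 3, 3)), c("BF", "DF"),
                  role = "S2")
  expect_true(all(computeAmplificationMap(z, M) == 0))
})

test_that("the 3x3 amplification worked example traces through bit-for-bit", {
  s2f <- matrix(1, 3, 3); s2f[2, 2] <- 50
  Ibf <- matrix(0, 3, 3); Ibf[2, 2] <- 1
  Idf <- matrix(0, 3, 3); Idf[2, 2] <- 6
  M <- matrix(TRUE, 3, 3); M[2, 2] <- FALSE
  maps <- new("SdAMaps", backgroundMask = M, objectMap = Ibf,
              amplificationMap = Idf, sbr = numeric(), s1Radius = 1,
              s2Radius = 1)
  st <- ImageStack(list(matrix(2, 3, 3), s2f), c("BF", "DF"), role = "S2")
  out <- amplifyAndBuildStacks(st, maps)
  ## manual trace: A centre = 50 * 6 = 300, border = 1;
  ## threshold = mean + 3 sd over border = 1 + 0 = 1; S2' centre = 299;
  ## S3 centre = original 50; SBR = 50 / 1 > 1 so S4 = S3
  expS3 <- matrix(0, 3, 3); expS3[2, 2] <- 50
  expect_identical(out$S3[[2]], expS3)
  expect_identical(out$S4[[2]], expS3)
  expect_identical(unname(out$sbr), 50)
  ## BF frame passes through
  expect_identical(out$S3[[1]], matrix(2, 3, 3))
  expect_identical(out$S4[[1]], matrix(2, 3, 3))
})

test_that("offset-only degradation yields S3 exactly equal to the noise-free DF frames", {
  sc <- discScene(seed = 2)
  noisy <- degradeStack(sc$stack, NoiseModel(offset = 500, seed = 1))
  cor <- sdaCorrect(noisy, sc$geometry, s1Radius = 3, s2Radius = 2)
  for (j in seq_along(sc$dfs)) {
    expect_identical(cor$S3[[1 + j]], sc$dfs[[j]])
    expect_identical(cor$S4[[1 + j]], sc$dfs[[j]])
  }
})

test_that("SdA structural invariants hold on randomized noisy scenes", {
  for (seed in 1:4) {
    sc <- discScene(seed = seed, size = 40, discRadius = 6)
    noisy <- degradeStack(sc$stack,
                          NoiseModel(offset = 300, gaussianSigma = 40,
                                     poissonGain = 1, seed = seed))
    cor <- sdaCorrect(noisy, sc$geometry, s1Radius = 3, s2Radius = 2)
    M <- backgroundMask(cor$maps)
    Ibf <- objectMap(cor$maps)
    ## a pixel is never both background and object
    expect_false(any(M & Ibf == 1))
    expect_true(all(amplificationMap(cor$maps) >= 0))
    dfi <- which(frameLabels(cor$S3) == "DF")
    for (i in dfi) {
      s2f <- cor$S2[[i]]; s3f <- cor$S3[[i]]; s4f <- cor$S4[[i]]
      ## direct-reassignment property: S3 pixels are 0 or the S2 value
      expect_true(all(s3f == 0 | s3f == s2f))
      expect_true(all(s2f >= 0) && all(s3f >= 0) && all(s4f >= 0))
      ## support shrinkage
      expect_true(all(s2f[s3f > 0] > 0))
      expect_true(all(s3f[s4f > 0] > 0 | s4f[s4f > 0] > 0))
      ## background pixels of the corrected stacks are exactly zero
      expect_identical(unname(s3f[M]), rep(0, sum(M)))
      expect_identical(unname(s4f[M]), rep(0, sum(M)))
    }
    ## S4 = S3 identically on frames with SBR > 1
    for (j in which(sbr(cor$maps) > 1)) {
      i <- as.integer(names(sbr(cor$maps))[j])
      expect_identical(cor$S4[[i]], cor$S3[[i]])
    }
    ## end-to-end determinism
    cor2 <- sdaCorrect(degradeStack(sc$stack,
                                    NoiseModel(offset = 300, gaussianSigma = 40,
                                               poissonGain = 1, seed = seed)),
                       sc$geometry, s1Radius = 3, s2Radius = 2)
    expect_identical(frames(cor$S3), frames(cor2$S3))
    expect_identical(frames(cor$S4), frames(cor2$S4))
  }
})

test_that("Otsu threshold equals the exhaustive within-class variance minimizer", {
  for (seed in 1:6) {
    set.seed(seed)
    ## bimodal-ish synthetic histograms
    x <- c(stats::rnorm(600, 60, 12), stats::rnorm(400, 170, 20))
    x <- matrix(pmin(pmax(x, 0), 255), 40)
    t1 <- otsuThreshold(x)
    ## oracle: direct minimisation of the within-class variance over all
    ## histogram bin mids
    breaks <- seq(min(x), max(x), length.out = 257)
    h <- hist(as.vector(x), breaks = breaks, plot = FALSE)
    wcv <- vapply(seq_along(h$mids), function(i) {
      lo <- rep(h$mids[seq_len(i)], h$counts[seq_len(i)])
      hi <- if (i < length(h$mids))
        rep(h$mids[(i + 1):length(h$mids)], h$counts[(i + 1):length(h$mids)])
      else numeric()
      v <- 0
      if (length(lo) > 0) v <- v + sum((lo - mean(lo))^2)
      if (length(hi) > 0) v <- v + sum((hi - mean(hi))^2)
      v
    }, numeric(1))
    best <- which(wcv == min(wcv))
    t2 <- (h$mids[best[1]] + h$mids[best[length(best)]]) / 2
    expect_equal(t1, t2, tolerance = 1e-10)
  }
})
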