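# Build a minimal single-echo container directly from a k-space matrix.
containerFromK <- function(K, nCoil = 1L, kIndexOrder = NULL) {
  nKx <- nrow(K); nKy <- ncol(K)
  if (is.null(kIndexOrder)) kIndexOrder <- 0:(nKy - 1L)
  data <- array(0 + 0i, c(nKx, length(kIndexOrder), nCoil, 1L))
  for (c in seq_len(nCoil)) data[, , c, 1] <- K[, kIndexOrder + 1L]
  ln <- data.frame(kIndex = kIndexOrder, exc = seq_along(kIndexOrder),
                   shot = 0L, echo = 1L,
                   tExc = seq_along(kIndexOrder) * 0.01,
                   tRo = 0.004, tAbs = seq_along(kIndexOrder) * 0.01 + 0.004,
                   polarity = 1L)
  new("KSpaceData", data = data, lines = ln,
      meta = list(type = "TEST", matrix = c(nKx, nKy), teMs = 4,
                  zMm = 0, voxelMm = c(1, 1, 1)))
}

test_that("fftRecon implements the centered unitary inverse DFT", {
  n <- 32
  # delta at DC (0-based floor(N/2)) -> constant image
  K <- matrix(0 + 0i, n, n)
  K[floor(n / 2) + 1, floor(n / 2) + 1] <- 1
  img <- imageData(fftRecon(containerFromK(K)))[, , 1, 1]
  expect_lt(max(Mod(img - img[1, 1])), 1e-12)
  expect_gt(Mod(img[1, 1]), 0)

  # forward-DFT of a phantom then fftRecon -> phantom to machine precision
  ph <- makePhantom(nx = n, ny = n, nz = 1L)
  x <- protonDensity(ph)[, , 1] + 0i
  K <- breathfield:::ft2c(x)
  img <- imageData(fftRecon(containerFromK(K)))[, , 1, 1]
  expect_lt(max(Mod(img - x)), 1e-12)

  # Parseval: image energy equals k-space energy (unitary scaling)
  set.seed(3)
  K <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  img <- imageData(fftRecon(containerFromK(K)))[, , 1, 1]
  expect_equal(sum(Mod(img)^2), sum(Mod(K)^2), tolerance = 1e-10)

  # missing lines -> completeness error
  bad <- containerFromK(K, kIndexOrder = 0:(n - 2L))
  expect_error(fftRecon(bad), class = "bf_completeness_error")
})

test_that("CG-SENSE matches the inverse DFT on fully sampled single-coil data", {
  n <- 32
  ph <- makePhantom(nx = n, ny = n, nz = 1L)
  x <- protonDensity(ph)[, , 1] + 0i
  K <- breathfield:::ft2c(x)
  set <- containerFromK(K)
  sens <- new("CoilSensitivities", sens = array(1 + 0i, c(n, n, 1)),
              support = matrix(TRUE, n, n))
  rec <- cgSense(set, sens, nIter = 30, tol = 1e-12)
  ref <- imageData(fftRecon(set))[, , 1, 1]
  expect_lt(nrmse(imageData(rec)[, , 1, 1], ref), 1e-8)

  # all-zero k-space -> all-zero image without iterating
  set0 <- containerFromK(K * 0)
  rec0 <- cgSense(set0, sens)
  expect_true(all(imageData(rec0) == 0))
  expect_equal(rec0@info$iterations[1, 1], 0L)
})

test_that("CG-SENSE solves R=2 undersampled 2-coil data exactly (noiseless)", {
  n <- 32
  ph <- makePhantom(nx = n, ny = n, nz = 1L)
  x <- protonDensity(ph)[, , 1] + 0i
  sens <- makeCoilSensitivities(n, n, 2L)
  # even ky lines only (R = 2)
  keep <- seq(0, n - 2, by = 2)
  data <- array(0 + 0i, c(n, length(keep), 2L, 1L))
  for (c in 1:2) {
    K <- breathfield:::ft2c(coilMaps(sens)[, , c] * x)
    data[, , c, 1] <- K[, keep + 1L]
  }
  ln <- data.frame(kIndex = keep, exc = 1L, shot = 0L, echo = 1L,
                   tExc = 0, tRo = 0.014, tAbs = 0.014, polarity = 1L)
  set <- new("KSpaceData", data = data, lines = ln,
             meta = list(type = "EPI4", matrix = c(n, n), teMs = 14,
                         shots = 1L, senseFactor = 2L, zMm = 0,
                         voxelMm = c(1, 1, 1)))
  rec <- cgSense(set, sens, nIter = 30, tol = 1e-12)
  expect_lt(nrmse(imageData(rec)[, , 1, 1], x), 1e-6)
  expect_lte(max(rec@info$iterations), 30L)
})

test_that("CG-SENSE at R=1 equals sensitivity-weighted coil combination", {
  n <- 32
  ph <- makePhantom(nx = n, ny = n, nz = 1L)
  x <- (protonDensity(ph)[, , 1] + 0.2) + 0i  # nonzero everywhere
  sens <- makeCoilSensitivities(n, n, 3L)
  data <- array(0 + 0i, c(n, n, 3L, 1L))
  coilImgs <- array(0 + 0i, c(n, n, 3L))
  for (c in 1:3) {
    K <- breathfield:::ft2c(coilMaps(sens)[, , c] * x)
    data[, , c, 1] <- K
    coilImgs[, , c] <- breathfield:::ift2c(K)
  }
  ln <- data.frame(kIndex = 0:(n - 1L), exc = 1L, shot = 0L, echo = 1L,
                   tExc = 0, tRo = 0.004, tAbs = 0.004, polarity = 1L)
  set <- new("KSpaceData", data = data, lines = ln,
             meta = list(type = "TEST", matrix = c(n, n), teMs = 4, zMm = 0,
                         voxelMm = c(1, 1, 1)))
  rec <- cgSense(set, sens, nIter = 50, tol = 1e-12)
  ref <- sensCombine(coilImgs, sens)
  expect_lt(nrmse(imageData(rec)[, , 1, 1], ref), 1e-6)
})

test_that("reconstruction is linear in the data", {
  n <- 32
  set.seed(7)
  K1 <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  K2 <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  a <- 2.5 - 1i; b <- -0.7 + 0.3i
  r1 <- imageData(fftRecon(containerFromK(K1)))
  r2 <- imageData(fftRecon(containerFromK(K2)))
  r12 <- imageData(fftRecon(containerFromK(a * K1 + b * K2)))
  expect_lt(max(Mod(r12 - (a * r1 + b * r2))), 1e-10)
})

test_that("CG residual is non-increasing on consistent data", {
  # track the relative residual by running with increasing iteration caps
  n <- 32
  ph <- makePhantom(nx = n, ny = n, nz = 1L)
  x <- protonDensity(ph)[, , 1] + 0i
  sens <- makeCoilSensitivities(n, n, 2L)
  keep <- seq(0, n - 2, by = 2)
  data <- array(0 + 0i, c(n, length(keep), 2L, 1L))
  for (c in 1:2)
    data[, , c, 1] <- breathfield:::ft2c(coilMaps(sens)[, , c] * x)[, keep + 1L]
  ln <- data.frame(kIndex = keep, exc = 1L, shot = 0L, echo = 1L,
                   tExc = 0, tRo = 0.014, tAbs = 0.014, polarity = 1L)
  set <- new("KSpaceData", data = data, lines = ln,
             meta = list(type = "TEST", matrix = c(n, n), teMs = 14, zMm = 0,
                         voxelMm = c(1, 1, 1)))
  res <- vapply(c(2L, 5L, 10L, 20L), function(k)
    cgSense(set, sens, nIter = k, tol = 0)@info$relres[1, 1], numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("EPI reference correction removes an injected odd-line phase ramp", {
  st <- studySetup(traceS = 15)
  sq <- epi4Seq(volumes = 2L, ghost = list(const = 0.3, slope = 0.02))
  sim <- simulateAcquisition(st$phantom, sq, st$trace, st$model,
                             sens = makeCoilSensitivities(64, 64, 2L),
                             seed = 4, slices = 8L)
  sens <- makeCoilSensitivities(64, 64, 2L)
  # the reference twin here carries the ghost but no field fluctuation; a
  # ghost-free twin comes from the same sequence without injection
  simClean <- simulateAcquisition(st$phantom, epi4Seq(volumes = 2L), st$trace,
                                  st$model, sens = sens, seed = 4, slices = 8L)
  recGhost <- reconTimeSeries(sim$reference, sens, tol = 1e-10)
  corr <- epiReferenceCorrect(sim$reference, sim$refLines)
  recFixed <- reconTimeSeries(corr, sens, tol = 1e-10)
  recClean <- reconTimeSeries(simClean$reference, sens, tol = 1e-10)
  errBefore <- sum((recGhost - recClean)^2)
  errAfter <- sum((recFixed - recClean)^2)
  expect_lt(errAfter, 0.01 * errBefore)  # ghost energy reduced by > 99%

  # zero discrepancy -> identity
  same <- epiReferenceCorrect(simClean$reference,
                              data.frame(slice = 1, const = 0, slope = 0))
  expect_equal(kData(same), kData(simClean$reference), tolerance = 1e-12)

  # double application is refused via the meta flag
  expect_error(epiReferenceCorrect(corr, sim$refLines),
               class = "bf_configuration_error")
  # EPI data without reference coefficients -> configuration error
  expect_error(epiReferenceCorrect(sim$kspace, NULL),
               class = "bf_configuration_error")
})

test_that("RSS combination is the root-sum-of-squares and phase-invariant", {
  arr <- array(0 + 0i, c(2, 2, 1, 2))
  arr[, , 1, 1] <- 3; arr[, , 1, 2] <- 4
  vols <- new("ImageVolume", data = arr, voxelMm = c(1, 1, 1),
              teMs = c(1, 2), info = list())
  rss <- rssCombine(vols)
  expect_true(all(abs(imageData(rss) - 5) < 1e-12))

  # single echo -> |I|
  one <- new("ImageVolume", data = arr[, , , 1, drop = FALSE],
             voxelMm = c(1, 1, 1), teMs = 1, info = list())
  expect_true(all(abs(imageData(rssCombine(one)) - 3) < 1e-12))

  # invariant to per-echo global phase
  arr2 <- arr
  arr2[, , 1, 1] <- arr2[, , 1, 1] * exp(1i * 0.8)
  arr2[, , 1, 2] <- arr2[, , 1, 2] * exp(-1i * 2.1)
  vols2 <- new("ImageVolume", data = arr2, voxelMm = c(1, 1, 1),
               teMs = c(1, 2), info = list())
  expect_equal(imageData(rssCombine(vols2)), imageData(rss), tolerance = 1e-12)

  # geometry mismatch across a list of echoes
  half <- new("ImageVolume", data = arr[1:1, , , , drop = FALSE],
              voxelMm = c(1, 1, 1), teMs = c(1, 2), info = list())
  expect_error(rssCombine(list(one, half)), class = "bf_consistency_error")
})
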