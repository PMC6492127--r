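test_that("temporal unwrapping recovers ramps and sinusoids exactly", {
  # constant series is unchanged
  ph <- array(0.7, c(2, 3, 5))
  s <- unwrapPhaseTemporal(toyPhaseSeries(ph))
  expect_equal(s@phase, ph)

  # wrapped +2.5 rad/frame ramp -> unwrapped ramp recovered exactly
  nt <- 12
  truth <- outer(array(0.3, c(2, 3)), (seq_len(nt) - 1) * 2.5, `+`)
  dim(truth) <- c(2, 3, nt)
  s <- unwrapPhaseTemporal(toyPhaseSeries(wrapToPi(truth)))
  expect_equal(s@phase, truth, tolerance = 1e-12)
  # frame 1 unchanged, jumps bounded by pi
  expect_equal(s@phase[, , 1], wrapToPi(truth)[, , 1])
  expect_true(all(abs(apply(s@phase, c(1, 2), diff)) <= pi + 1e-12))

  # sinusoidal truth with 4 rad amplitude, forward-wrapped
  truth <- array(rep(4 * sin(2 * pi * (seq_len(40)) / 15), each = 6), c(2, 3, 40))
  truth <- sweep(truth, c(1, 2), matrix(seq(0, 1, length.out = 6), 2, 3), `+`)
  s <- unwrapPhaseTemporal(toyPhaseSeries(wrapToPi(truth)))
  # unwrapping is exact up to the initial wrap of frame 1 (a 2*pi*k offset)
  off <- s@phase[, , 1] - truth[, , 1]
  expect_equal(sweep(s@phase, c(1, 2), off, `-`), truth, tolerance = 1e-10)

  expect_warning(unwrapPhaseTemporal(toyPhaseSeries(array(0, c(2, 2, 1)))),
                 "single-frame")
})

test_that("phase-to-field conversion divides by 2*pi*TE and is mean-free", {
  # zero phase -> zero field
  s <- toyPhaseSeries(array(0, c(2, 2, 4)), unwrapped = TRUE)
  expect_true(all(phaseToField(s) == 0))

  # +2*pi deviation at one frame, TE 4.08 ms -> 245.10 Hz minus the induced mean
  nt <- 10
  ph <- array(0, c(1, 1, nt)); ph[1, 1, 4] <- 2 * pi
  f <- phaseToField(toyPhaseSeries(ph, te = 0.00408, unwrapped = TRUE))
  expected <- (2 * pi - 2 * pi / nt) / (2 * pi * 0.00408)
  expect_equal(f[1, 1, 4], expected, tolerance = 1e-10)
  expect_equal(1 / 0.00408, 245.098, tolerance = 1e-4)  # the 1/TE scale itself

  # antisymmetric +-pi/2 deviations give exactly -61.27 / +61.27 Hz
  ph <- array(0, c(1, 1, 2)); ph[1, 1, ] <- c(-pi / 2, pi / 2)
  f <- phaseToField(toyPhaseSeries(ph, te = 0.00408, unwrapped = TRUE))
  expect_equal(f[1, 1, 1], -(pi / 2) / (2 * pi * 0.00408), tolerance = 1e-10)
  expect_equal(f[1, 1, 1], -61.2745, tolerance = 1e-3)

  # zero temporal mean per voxel, any input
  set.seed(2)
  ph <- array(rnorm(5 * 4 * 20), c(5, 4, 20))
  f <- phaseToField(toyPhaseSeries(ph, unwrapped = TRUE))
  expect_lt(max(abs(apply(f, c(1, 2), mean))), 1e-10)

  bad <- toyPhaseSeries(ph, unwrapped = TRUE)
  bad@te <- -1
  expect_error(phaseToField(bad), class = "bf_parameter_error")
  expect_error(phaseToField(toyPhaseSeries(ph, unwrapped = FALSE)),
               class = "bf_parameter_error")
})

test_that("in-mask averaging takes the plane mean and drops empty slices", {
  f <- array(5, c(3, 4, 6))
  mask <- matrix(TRUE, 3, 4)
  pr <- averageFieldInMask(f, mask, c(0, 3, 6), (0:5) * 0.344)
  expect_true(all(fieldProfile(pr) == 5))

  f[2, , 1] <- 0; f[2, 1:2, 1] <- c(2, 4)
  mask2 <- matrix(FALSE, 3, 4); mask2[2, 1:2] <- TRUE; mask2[1, ] <- TRUE
  expect_warning(pr <- averageFieldInMask(f, mask2, c(0, 3, 6), (0:5) * 0.344),
                 "empty mask")
  expect_equal(pr@dropped, 3L)
  expect_equal(fieldProfile(pr)[2, 1], 3)  # mean of 2 and 4

  # CLT bound: noisy linear field averaged over many voxels approaches truth
  set.seed(11)
  nvox <- 60; nt <- 40
  R <- sin(2 * pi * (1:nt) / 13)
  cTrue <- 6
  f <- array(0, c(1, nvox, nt))
  for (t in seq_len(nt)) f[1, , t] <- R[t] * cTrue + rnorm(nvox, 0, 0.5)
  pr <- averageFieldInMask(f, matrix(TRUE, 1, nvox), 0, (1:nt) * 0.344)
  expect_true(all(abs(fieldProfile(pr)[1, ] - R * cTrue) < 3 * 0.5 / sqrt(nvox) + 1e-9))
})

test_that("outlier detection flags bursts and stays quiet on clean data", {
  nt <- 60
  R <- sin(2 * pi * (1:nt) / 13)
  f0 <- rbind(3 * R, 8 * R)
  expect_length(detectOutlierFrames(toyProfile(f0), R), 0L)

  # +40 Hz swallow-scale burst on one frame is flagged
  f0b <- f0; f0b[, 25] <- f0b[, 25] + 40
  expect_identical(detectOutlierFrames(toyProfile(f0b), R), 25L)

  # pure-noise null: false-positive fraction below 1% at k = 4
  set.seed(42)
  nt <- 1000
  Rn <- sin(2 * pi * (1:nt) / 13)
  fn <- matrix(rnorm(8 * nt, 0, 1), 8, nt)
  flagged <- detectOutlierFrames(toyProfile(fn), Rn, k = 4)
  expect_lt(length(flagged) / nt, 0.01)

  expect_error(detectOutlierFrames(toyProfile(f0[, 1:10, drop = FALSE]), R[1:10]),
               class = "bf_insufficient_data_error")
})

test_that("coupling fit equals the scalar normal-equation closed form", {
  # 3-frame toy: R = [1,2,3], f0 = [2,4,6] -> c = 2 Hz/unit
  cal <- fitTraceCoupling(toyProfile(matrix(c(2, 4, 6), 1)), c(1, 2, 3),
                          windowS = 10, minFrames = 3L)
  expect_equal(couplingHz(cal), 2)
  expect_equal(residualRmsHz(cal), 0)

  # noiseless exact recovery, and oracle equivalence with lm() per slice
  set.seed(5)
  nt <- 90
  R <- sin(2 * pi * (1:nt) / 13) + 0.2 * rnorm(nt)
  cTrue <- c(3, 5.5, 9)
  f0 <- outer(cTrue, R)
  cal <- fitTraceCoupling(toyProfile(f0), R, windowS = 40)
  expect_equal(couplingHz(cal), cTrue, tolerance = 1e-10)

  f0n <- f0 + matrix(rnorm(length(f0), 0, 0.3), nrow(f0))
  cal <- fitTraceCoupling(toyProfile(f0n), R, windowS = 1e6)
  lmRef <- vapply(1:3, function(z) unname(coef(lm(f0n[z, ] ~ R - 1))), numeric(1))
  expect_equal(couplingHz(cal), lmRef, tolerance = 1e-9)

  # degenerate inputs
  expect_error(fitTraceCoupling(toyProfile(f0), rep(1, nt) * 0, windowS = 40),
               class = "bf_fit_error")
  expect_error(fitTraceCoupling(toyProfile(f0), R, windowS = 40,
                                excluded = seq_len(nt)),
               class = "bf_fit_error")
  expect_error(fitTraceCoupling(toyProfile(f0[, 1:5, drop = FALSE]), R[1:5],
                                windowS = 40),
               class = "bf_fit_error")
})

test_that("excluded frames and the 30-s window are honoured", {
  nt <- 200
  tt <- (seq_len(nt) - 1) * 0.344
  R <- sin(2 * pi * tt / 4.5)
  f0 <- matrix(4 * R, 1)
  # corrupt frames outside the window and one excluded frame inside it
  f0[1, tt > 30] <- 100
  f0[1, 10] <- -70
  cal <- fitTraceCoupling(toyProfile(f0, frameTimes = tt), R, windowS = 30,
                          excluded = 10L)
  expect_equal(couplingHz(cal), 4, tolerance = 1e-10)
  expect_equal(cal@fitWindow, 30)
})

test_that("end-to-end calibration on simulated FLASH recovers the profile", {
  st <- studySetup(seed = 9, traceS = 70)
  # noiseless: relative RMS error < 1e-8
  fl <- simulateFlash(st$phantom, st$trace, st$model, durationS = 60, seed = 2)
  cal <- calibrateField(fl$series, fl$mask, st$trace)
  relErr <- sqrt(mean((couplingHz(cal) - st$coupling)^2)) / sqrt(mean(st$coupling^2))
  expect_lt(relErr, 1e-8)
  expect_gte(cal@nFramesUsed, 10L)

  # image SNR 20: relative RMS error < 5% across a handful of seeds
  ok <- vapply(1:10, function(sd) {
    fl <- simulateFlash(st$phantom, st$trace, st$model, durationS = 60,
                        noiseSd = 0.05, seed = sd)
    cal <- calibrateField(fl$series, fl$mask, st$trace)
    sqrt(mean((couplingHz(cal) - st$coupling)^2)) / sqrt(mean(st$coupling^2)) < 0.05
  }, logical(1))
  expect_gte(sum(ok), 9L)
})

test_that("a swallow burst in the FLASH data is flagged and excluded", {
  st <- studySetup(seed = 4, traceS = 70)
  mdl <- makeBreathingModel(st$coupling,
                            swallows = data.frame(time = 15, amplitudeHz = 40,
                                                  durationS = 1.5))
  fl <- simulateFlash(st$phantom, st$trace, mdl, durationS = 60, seed = 2)
  cal <- calibrateField(fl$series, fl$mask, st$trace)
  # frames near t = 15 s (frame index ~ 15/0.344) must be excluded
  burstFrames <- which(abs(fl$frameTimes - 15) < 1)
  expect_true(any(burstFrames %in% excludedFrames(cal)))
  # and the fit still recovers the generating coupling
  relErr <- sqrt(mean((couplingHz(cal) - st$coupling)^2)) / sqrt(mean(st$coupling^2))
  expect_lt(relErr, 0.05)
})
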