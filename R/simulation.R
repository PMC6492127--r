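## Acquisition simulator. Generates every input the pipeline needs — digital
## cervical-cord phantom, quasi-periodic bellows trace, z-dependent breathing
## field profile, FLASH calibration series, multi-echo GRE and 4-shot
## interleaved EPI k-space — with ground truth retained.
##
## Signal model: sample value of line (exc, echo) for coil c, slice z is
##   F2[ S_c(r) PD(r) exp(-tRO/T2*(r)) ](k) * exp(+i 2pi f0(z, t_event) tRO)
## plus complex Gaussian noise. The field is evaluated once per excitation
## (static within each readout train), so oracle-field correction is exact;
## no Bloch/steady-state simulation beyond the T2* envelope (flip angle and
## T1 effects are folded into the PD amplitude). The phantom is evaluated
## directly on the reconstruction grid (inverse crime accepted: the tests
## target the correction, not gridding fidelity).

.ellipse <- function(nx, ny, cx, cy, rx, ry) {
  x <- matrix(seq_len(nx), nx, ny)
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Build a digital cervical-cord phantom
#'
#' An elliptical "neck" of tissue containing a CSF annulus around an
#' elliptical spinal cord, replicated over axial slices. Cord T2* defaults
#' to 25 ms (within the corrected in-vivo range); CSF and background tissue
#' have distinct PD and T2*. The object is kept well inside the FOV so the
#' ghost metric has a clean guard band. Slice 1 is the most superior; zMm
#' increases inferiorly.
#'
#' @param nx,ny in-plane matrix size (>= 32)
#' @param nz number of axial slices
#' @param voxelMm voxel size, mm (default c(2, 2, 3))
#' @param cordT2sMs cord T2* in ms (default 25)
#' @param seed RNG seed (the default phantom is fully deterministic; the
#'   seed only feeds the mild PD texture)
#' @return a \linkS4class{PhantomSpec}
#' @export
makePhantom <- function(nx = 64L, ny = 64L, nz = 8L, voxelMm = c(2, 2, 3),
                        cordT2sMs = 25, seed = 1L) {
  if (nx < 32L || ny < 32L) .bfStop("bf_parameter_error", "matrix must be >= 32")
  set.seed(seed)
  cx <- nx / 2 + 0.5; cy <- ny / 2 + 0.5
  neck <- .ellipse(nx, ny, cx, cy, 0.33 * nx, 0.36 * ny)
  csf <- .ellipse(nx, ny, cx, cy + 0.08 * ny, 0.11 * nx, 0.11 * ny)
  cord <- .ellipse(nx, ny, cx, cy + 0.08 * ny, 0.065 * nx, 0.06 * ny)
  pdSl <- matrix(0, nx, ny)
  pdSl[neck] <- 0.8
  pdSl[csf] <- 1.2
  pdSl[cord] <- 1.0
  t2Sl <- matrix(1, nx, ny)          # placeholder outside object (PD = 0 there)
  t2Sl[neck] <- 15
  t2Sl[csf] <- 70
  t2Sl[cord] <- cordT2sMs
  # piecewise-constant compartments; a smooth object keeps oracle tests exact
  pd <- array(rep(pdSl, nz), c(nx, ny, nz))
  t2s <- array(rep(t2Sl, nz), c(nx, ny, nz))
  mask <- array(rep(cord, nz), c(nx, ny, nz))
  new("PhantomSpec", pd = pd, t2sMs = t2s, cordMask = mask,
      zMm = (seq_len(nz) - 1) * voxelMm[3], voxelMm = voxelMm)
}

#' Simulate a quasi-periodic respiratory bellows trace
#'
#' A sinusoid with per-cycle period and amplitude jitter, sampled at
#' \code{fsHz}, riding on a constant baseline offset (removed later by
#' \code{\link{syncTrace}}). Sequence trigger marks are placed at the sample
#' nearest each multiple of \code{triggerIntervalS}. Defaults follow normal
#' shallow breathing: mean period 4.5 s (observed calibration periods span
#' roughly 3.6-7.7 s across subjects).
#'
#' @param durationS record length, seconds (>= 2 periods)
#' @param periodMeanS mean respiratory period, s (default 4.5)
#' @param periodSdS per-cycle period SD, s (default 0.4)
#' @param amp trace amplitude, bellows units (default 1)
#' @param fsHz sampling rate (default 50)
#' @param triggerIntervalS spacing of sequence triggers, s (default 0.344,
#'   the FLASH volume TR)
#' @param baseline constant offset, bellows units (default 50)
#' @param seed RNG seed
#' @return a raw \linkS4class{RespTrace}
#' @export
makeTrace <- function(durationS, periodMeanS = 4.5, periodSdS = 0.4, amp = 1,
                      fsHz = 50, triggerIntervalS = 0.344, baseline = 50,
                      seed = 1L) {
  if (durationS < 2 * periodMeanS)
    .bfStop("bf_parameter_error", "trace duration must cover at least 2 periods")
  set.seed(seed)
  tt <- seq(0, durationS, by = 1 / fsHz)
  # piecewise-constant frequency per cycle, continuous phase
  phase <- numeric(length(tt))
  ampPhase <- numeric(length(tt))
  tCur <- 0; phCur <- 0; i0 <- 1L
  while (tCur < durationS) {
    Tcyc <- max(1, stats::rnorm(1, periodMeanS, periodSdS))
    aCyc <- amp * max(0.2, stats::rnorm(1, 1, 0.05))
    i1 <- which(tt < tCur + Tcyc)
    i1 <- if (length(i1)) max(i1) else i0
    idx <- i0:max(i0, i1)
    phase[idx] <- phCur + 2 * pi * (tt[idx] - tCur) / Tcyc
    ampPhase[idx] <- aCyc
    phCur <- phCur + 2 * pi * ((min(tCur + Tcyc, durationS) - tCur) / Tcyc)
    tCur <- tCur + Tcyc
    i0 <- max(i0, i1) + 1L
    if (i0 > length(tt)) break
  }
  if (i0 <= length(tt)) { phase[i0:length(tt)] <- phCur; ampPhase[i0:length(tt)] <- amp }
  value <- baseline + ampPhase * sin(phase)
  trigger <- logical(length(tt))
  trigTimes <- seq(0, durationS, by = triggerIntervalS)
  trigger[unique(vapply(trigTimes, function(x) which.min(abs(tt - x)), integer(1)))] <- TRUE
  new("RespTrace", time = tt, value = value, trigger = trigger, synced = FALSE)
}

#' Breathing-field coupling profile along z
#'
#' Closed-form profile \code{baseAmpHz + gradientHzPerMm * z} (Hz per
#' bellows unit), monotone non-decreasing in magnitude toward inferior z —
#' field fluctuations grow toward the thorax. The defaults give a peak field
#' excursion of roughly 3-11 Hz at unit trace amplitude over a typical
#' 8-slice, 3-mm stack.
#'
#' @param zMm slice positions, mm (increasing inferiorly)
#' @param baseAmpHz coupling at z = 0 (default 3)
#' @param gradientHzPerMm linear growth, Hz/unit/mm (default 0.4)
#' @return numeric coupling per slice, Hz per bellows unit
#' @export
makeCouplingProfile <- function(zMm, baseAmpHz = 3, gradientHzPerMm = 0.4) {
  if (!length(zMm)) .bfStop("bf_parameter_error", "need at least one slice")
  if (baseAmpHz < 0 || gradientHzPerMm < 0)
    .bfStop("bf_parameter_error", "profile must be non-negative and non-decreasing")
  baseAmpHz + gradientHzPerMm * zMm
}

#' Breathing model for the simulators
#'
#' Bundles the generating linear link: the coupling profile (Hz per bellows
#' unit per slice), optional zero-mean Gaussian link noise (model violation
#' of the trace-to-field link, Hz), optional additive swallow bursts
#' (Gaussian bumps in time, seconds FWHM ~ 1-2 s, amplitudes up to ~40 Hz,
#' deliberately unlinked to the trace), and an optional \code{fieldFun(z, t)}
#' override that replaces the linear model entirely.
#'
#' @param coupling numeric per-slice coupling, Hz per bellows unit
#' @param linkNoiseSd SD of additive link noise, Hz (default 0)
#' @param swallows data.frame(time, amplitudeHz, durationS) or NULL
#' @param fieldFun optional function(zIndex, t) -> Hz overriding the model
#' @return a list with class "BreathingModel"
#' @export
makeBreathingModel <- function(coupling, linkNoiseSd = 0, swallows = NULL,
                               fieldFun = NULL) {
  structure(list(coupling = coupling, linkNoiseSd = linkNoiseSd,
                 swallows = swallows, fieldFun = fieldFun),
            class = "BreathingModel")
}

# Evaluate the generating field f0(zIdx, t) for all slices at times tt.
# Returns [nSlice, length(tt)]; link noise is drawn from the current RNG
# stream (caller controls seeding).
.modelField <- function(model, trace, tt, nSlice) {
  if (!is.null(model$fieldFun)) {
    f0 <- outer(seq_len(nSlice), tt, Vectorize(model$fieldFun))
  } else {
    R <- traceAtTimes(trace, tt)
    if (length(model$coupling) < nSlice)
      .bfStop("bf_consistency_error", "coupling profile shorter than slice count")
    f0 <- outer(model$coupling[seq_len(nSlice)], R)
  }
  if (!is.null(model$swallows) && nrow(model$swallows)) {
    for (i in seq_len(nrow(model$swallows))) {
      sw <- model$swallows[i, ]
      sig <- sw$durationS / 2.355  # FWHM -> sigma
      burst <- sw$amplitudeHz * exp(-(tt - sw$time)^2 / (2 * sig^2))
      f0 <- sweep(f0, 2, burst, `+`)
    }
  }
  if (model$linkNoiseSd > 0)
    f0 <- f0 + matrix(stats::rnorm(length(f0), 0, model$linkNoiseSd), nrow(f0))
  f0
}

#' Simulate a FLASH calibration scan
#'
#' A sagittal slice through the cord center is extracted from the phantom;
#' frame at time t carries phase \eqn{\phi_0(r) + 2\pi f_0(z(r), t)\,TE}
#' plus complex Gaussian noise, where \eqn{f_0 = R(t)\,c(z)} (+ link noise
#' and swallow bursts per the model). Frame times are the mid-acquisition
#' times k*volumeTr + volumeTr/2. The ground-truth field series is returned
#' alongside.
#'
#' @param phantom a \linkS4class{PhantomSpec}
#' @param trace a synced \linkS4class{RespTrace}
#' @param model a \code{\link{makeBreathingModel}} result
#' @param durationS scan duration, seconds (default 60)
#' @param volumeTrS volume TR, seconds (default 0.344)
#' @param teS echo time, seconds (default 0.00408)
#' @param noiseSd complex-noise SD per channel, in units of the cord
#'   magnitude (e.g. 0.05 for image SNR 20; default 0 = noiseless)
#' @param seed RNG seed
#' @return list: \code{series} (\linkS4class{PhaseSeries}), \code{mask}
#'   (sagittal cord mask [nz, nx]), \code{truthField} [nz, nFrame] Hz,
#'   \code{truthCoupling}, \code{frameTimes}
#' @export
simulateFlash <- function(phantom, trace, model, durationS = 60,
                          volumeTrS = 0.344, teS = 0.00408, noiseSd = 0,
                          seed = 1L) {
  stopifnot(is(phantom, "PhantomSpec"))
  if (max(trace@time) < durationS)
    .bfStop("bf_duration_error", "trace shorter than the requested scan")
  set.seed(seed)
  d <- dim(phantom@pd)
  cxi <- round(d[1L] / 2)  # mid-sagittal plane through the cord center
  magSag <- t(phantom@pd[cxi, , ])          # [nz, ny]
  maskSag <- t(phantom@cordMask[cxi, , ] * 1) > 0
  nz <- nrow(magSag); nx <- ncol(magSag)
  nFrame <- floor(durationS / volumeTrS)
  frameTimes <- (seq_len(nFrame) - 1) * volumeTrS + volumeTrS / 2
  f0True <- .modelField(model, trace, frameTimes, nz)
  phi0 <- matrix(0.3 * sin(2 * pi * seq_len(nz) / nz), nz, nx) +
    matrix(0.2 * cos(2 * pi * seq_len(nx) / nx), nz, nx, byrow = TRUE)
  mag <- array(rep(magSag, nFrame), c(nz, nx, nFrame))
  phs <- array(0, c(nz, nx, nFrame))
  cordMag <- mean(magSag[maskSag])
  for (t in seq_len(nFrame)) {
    ph <- phi0 + .phaseSign * 2 * pi * f0True[, t] * teS  # recycles over columns
    z <- magSag * exp(1i * ph)
    if (noiseSd > 0) {
      z <- z + cordMag * noiseSd *
        (matrix(stats::rnorm(nz * nx), nz, nx) + 1i * matrix(stats::rnorm(nz * nx), nz, nx))
    }
    mag[, , t] <- Mod(z)
    phs[, , t] <- wrapToPi(Arg(z))
  }
  series <- new("PhaseSeries", magnitude = mag, phase = phs, te = teS,
                frameTimes = frameTimes, zMm = phantom@zMm, unwrapped = FALSE)
  list(series = series, mask = maskSag, truthField = f0True,
       truthCoupling = if (is.null(model$fieldFun)) model$coupling[seq_len(nz)] else NULL,
       frameTimes = frameTimes)
}

## ---- imaging sequences -----------------------------------------------------

#' Sequence descriptors for the imaging simulators
#'
#' \code{megreSeq()}: 2-D multi-echo gradient echo, one phase-encode line
#' per TR, all echoes of that line per excitation (defaults: the 10-echo
#' protocol, TE 3.51..36.20 ms, TR 1000 ms).
#' \code{epi4Seq()}: 4-shot interleaved 2-D EPI (defaults TE 14 ms, shot TR
#' 650 ms — volume TR 2.6 s, echo spacing 1.06 ms, SENSE factor 2); shot m
#' (0-based) acquires phase-encode indices R*(m + shots*r), r = 0, 1, ...
#'
#' @param matrixSize c(nKx, nKy)
#' @param teMs echo time(s), ms
#' @param trMs repetition time per excitation, ms
#' @param volumes number of EPI volumes
#' @param senseFactor ky undersampling factor
#' @param espMs EPI echo spacing, ms
#' @param ghost optional list(const, slope): odd-line phase injected in
#'   hybrid space (radians, radians/sample) to emulate the uncorrected
#'   odd/even EPI discrepancy
#' @export
megreSeq <- function(matrixSize = c(64L, 64L),
                     teMs = c(3.51, 6.68, 10.37, 14.06, 17.75, 21.44, 25.13,
                              28.82, 32.51, 36.20),
                     trMs = 1000) {
  list(type = "MEGRE", matrix = as.integer(matrixSize), teMs = teMs,
       trMs = trMs, shots = NA_integer_, senseFactor = 1L)
}

#' @rdname megreSeq
#' @export
epi4Seq <- function(matrixSize = c(64L, 64L), teMs = 14, trMs = 650,
                    volumes = 120L, senseFactor = 2L, espMs = 1.06,
                    ghost = NULL) {
  list(type = "EPI4", matrix = as.integer(matrixSize), teMs = teMs,
       trMs = trMs, shots = 4L, senseFactor = as.integer(senseFactor),
       espMs = espMs, volumes = as.integer(volumes), ghost = ghost)
}

# Build the line table for a sequence spec. exc is 1-based; kIndex 0-based.
.makeLines <- function(seq) {
  nKy <- seq$matrix[2L]
  if (identical(seq$type, "MEGRE")) {
    nE <- length(seq$teMs)
    ln <- expand.grid(echo = seq_len(nE), j = 0:(nKy - 1L))
    data.frame(kIndex = ln$j, exc = ln$j + 1L, shot = ln$j,
               echo = ln$echo, tExc = ln$j * seq$trMs / 1000,
               tRo = seq$teMs[ln$echo] / 1000,
               tAbs = ln$j * seq$trMs / 1000 + seq$teMs[ln$echo] / 1000,
               polarity = 1L)
  } else if (identical(seq$type, "EPI4")) {
    shots <- seq$shots; R <- seq$senseFactor
    nTrain <- nKy %/% (shots * R)
    if (nTrain * shots * R != nKy)
      .bfStop("bf_parameter_error", "matrix ky must be divisible by shots * senseFactor")
    rows <- expand.grid(r = 0:(nTrain - 1L), m = 0:(shots - 1L),
                        v = 0:(seq$volumes - 1L))
    exc0 <- rows$v * shots + rows$m
    te <- seq$teMs[1L] / 1000
    tRo <- te + (rows$r - floor(nTrain / 2)) * seq$espMs / 1000
    if (any(tRo < 0))
      .bfStop("bf_parameter_error", "echo train extends to negative readout times; raise TE")
    data.frame(kIndex = R * (rows$m + shots * rows$r), exc = exc0 + 1L,
               shot = rows$m, echo = 1L, tExc = exc0 * seq$trMs / 1000,
               tRo = tRo, tAbs = exc0 * seq$trMs / 1000 + tRo,
               polarity = ifelse(rows$r %% 2L == 0L, 1L, -1L))
  } else .bfStop("bf_parameter_error", paste("unknown sequence type:", seq$type))
}

#' Simulate a multi-coil imaging acquisition (MEGRE or 4-shot EPI)
#'
#' Generates the k-space container for the given sequence with the signal
#' model above, together with a fluctuation-free twin built from the
#' identical noise realization, the ground-truth field per (slice,
#' excitation), and (for EPI with an injected ghost) the reference-line
#' coefficients.
#'
#' @param phantom a \linkS4class{PhantomSpec}
#' @param seq a \code{\link{megreSeq}} or \code{\link{epi4Seq}} descriptor
#'   whose matrix matches the phantom grid
#' @param trace a synced \linkS4class{RespTrace} covering the scan
#' @param model a \code{\link{makeBreathingModel}} result
#' @param sens a \linkS4class{CoilSensitivities} (NULL = one uniform coil)
#' @param noiseSd complex-noise SD per channel, k-space units (default 0)
#' @param seed RNG seed
#' @param slices subset of phantom slices to simulate (default: all)
#' @return list: \code{kspace}, \code{reference} (fluctuation-free twin),
#'   \code{truthField} [nSlice, nExc] Hz, \code{eventTimes},
#'   \code{refLines} (or NULL)
#' @export
simulateAcquisition <- function(phantom, seq, trace, model, sens = NULL,
                                noiseSd = 0, seed = 1L, slices = NULL) {
  stopifnot(is(phantom, "PhantomSpec"))
  d <- dim(phantom@pd)
  if (!all(seq$matrix == d[1:2]))
    .bfStop("bf_consistency_error", "sequence matrix must match the phantom grid")
  if (is.null(slices)) slices <- seq_len(d[3L])
  nSlice <- length(slices)
  ln <- .makeLines(seq)
  scanEnd <- max(ln$tAbs)
  if (max(trace@time) < scanEnd)
    .bfStop("bf_duration_error",
            sprintf("trace (%.1f s) shorter than the scan (%.1f s)",
                    max(trace@time), scanEnd))
  if (is.null(sens)) {
    sens <- new("CoilSensitivities",
                sens = array(1 + 0i, c(d[1L], d[2L], 1L)),
                support = matrix(TRUE, d[1L], d[2L]))
  }
  nCoil <- dim(sens@sens)[3L]
  set.seed(seed)

  # field per (slice, excitation), evaluated at the sequence-specific event time
  exc <- sort(unique(ln$exc))
  tExc <- ln$tExc[match(exc, ln$exc)]
  evOffset <- if (identical(seq$type, "EPI4")) seq$teMs[1L] / 1000 else 0
  eventTimes <- tExc + evOffset
  # slice-mapped model so a subset simulation sees the right coupling /
  # absolute slice indices
  subModel <- model
  if (is.null(model$fieldFun)) {
    subModel$coupling <- model$coupling[slices]
  } else {
    subModel$fieldFun <- function(i, t) model$fieldFun(slices[i], t)
  }
  f0True <- .modelField(subModel, trace, eventTimes, nSlice)

  # distinct readout times -> distinct T2* envelopes; one base FFT per
  # (slice, coil, envelope), then per-line phase modulation
  uRo <- sort(unique(ln$tRo))
  nLine <- nrow(ln)
  nKx <- seq$matrix[1L]
  data <- array(0 + 0i, c(nKx, nLine, nCoil, nSlice))
  ref <- data
  xs <- (seq_len(nKx) - 1L) - floor(nKx / 2)
  for (si in seq_len(nSlice)) {
    s <- slices[si]
    pd <- phantom@pd[, , s]
    t2 <- phantom@t2sMs[, , s] / 1000
    for (c in seq_len(nCoil)) {
      baseK <- lapply(uRo, function(tr) ft2c(sens@sens[, , c] * pd * exp(-tr / pmax(t2, 1e-9)) * (pd > 0)))
      for (l in seq_len(nLine)) {
        K <- baseK[[match(ln$tRo[l], uRo)]]
        col <- K[, ln$kIndex[l] + 1L]
        phase <- .phaseSign * 2 * pi * f0True[si, ln$exc[l] - min(ln$exc) + 1L] * ln$tRo[l]
        colMod <- col * exp(1i * phase)
        if (!is.null(seq$ghost) && ln$polarity[l] < 0) {
          gcorr <- exp(1i * (seq$ghost$const + seq$ghost$slope * xs))
          colMod <- as.vector(ft1c(ift1c(colMod) * gcorr))
          col <- as.vector(ft1c(ift1c(col) * gcorr))
        }
        data[, l, c, si] <- colMod
        ref[, l, c, si] <- col
      }
    }
  }
  if (noiseSd > 0) {
    noise <- noiseSd * (array(stats::rnorm(length(data)), dim(data)) +
                          1i * array(stats::rnorm(length(data)), dim(data)))
    data <- data + noise
    ref <- ref + noise
  }
  meta <- list(type = seq$type, teMs = seq$teMs, trMs = seq$trMs,
               matrix = seq$matrix, shots = seq$shots,
               senseFactor = seq$senseFactor,
               voxelMm = phantom@voxelMm, zMm = phantom@zMm[slices],
               refCorrected = FALSE, demodulated = FALSE)
  kspace <- new("KSpaceData", data = data, lines = ln, meta = meta)
  reference <- new("KSpaceData", data = ref, lines = ln, meta = meta)
  refLines <- NULL
  if (!is.null(seq$ghost))
    refLines <- data.frame(slice = seq_len(nSlice),
                           const = seq$ghost$const, slope = seq$ghost$slope)
  list(kspace = kspace, reference = reference, truthField = f0True,
       eventTimes = eventTimes, refLines = refLines)
}

#' Oracle predicted field from a simulation result
#'
#' Wraps the simulator's ground-truth field into a
#' \linkS4class{PredictedField}, for exactness tests of the demodulation.
#'
#' @param sim result of \code{\link{simulateAcquisition}}
#' @param zMm slice positions of the simulated container
#' @export
truthPredictedField <- function(sim, zMm = NULL) {
  if (is.null(zMm)) zMm <- sim$kspace@meta$zMm
  new("PredictedField", f0Hat = sim$truthField,
      eventTimes = sim$eventTimes, zMm = zMm)
}

#' Smooth Gaussian coil sensitivity maps
#'
#' \code{nCoil} coils placed around the FOV with broad Gaussian profiles and
#' mild linear phase; RSS over coils is bounded away from zero everywhere.
#'
#' @param nx,ny grid size
#' @param nCoil number of coils (default 4)
#' @return a \linkS4class{CoilSensitivities}
#' @export
makeCoilSensitivities <- function(nx, ny, nCoil = 4L) {
  sens <- array(0 + 0i, c(nx, ny, nCoil))
  # start on the y (phase-encode) axis so even 2 coils separate points
  # aliased along ky
  ang <- 2 * pi * (seq_len(nCoil) - 1) / nCoil + pi / 2
  x <- matrix(seq_len(nx) / nx - 0.5, nx, ny)
  y <- matrix(seq_len(ny) / ny - 0.5, nx, ny, byrow = TRUE)
  for (c in seq_len(nCoil)) {
    cx <- 0.45 * cos(ang[c]); cy <- 0.45 * sin(ang[c])
    mag <- 0.3 + exp(-((x - cx)^2 + (y - cy)^2) / (2 * 0.35^2))
    ph <- 0.5 * (x * cos(ang[c]) + y * sin(ang[c]))
    sens[, , c] <- mag * exp(1i * ph)
  }
  new("CoilSensitivities", sens = sens, support = matrix(TRUE, nx, ny))
}
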