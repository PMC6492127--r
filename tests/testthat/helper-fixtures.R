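# Shared fixture builders; everything is generated in code at test time.

# Small raw trace with a trigger at a chosen sample.
toyTrace <- function(n = 50, dt = 0.02, trigAt = integer(), value = NULL) {
  tt <- (seq_len(n) - 1) * dt
  if (is.null(value)) value <- 50 + sin(2 * pi * tt / 4.5)
  trig <- logical(n); trig[trigAt] <- TRUE
  new("RespTrace", time = tt, value = value, trigger = trig, synced = FALSE)
}

# PhaseSeries from an explicit [nz, nx, nt] phase array.
toyPhaseSeries <- function(phase, te = 0.00408, mag = NULL, zMm = NULL,
                           frameTimes = NULL, unwrapped = FALSE) {
  d <- dim(phase)
  if (is.null(mag)) mag <- array(1, d)
  if (is.null(zMm)) zMm <- (seq_len(d[1]) - 1) * 3
  if (is.null(frameTimes)) frameTimes <- (seq_len(d[3]) - 1) * 0.344
  new("PhaseSeries", magnitude = mag, phase = phase, te = te,
      frameTimes = frameTimes, zMm = zMm, unwrapped = unwrapped)
}

toyProfile <- function(f0, frameTimes = NULL, zMm = NULL) {
  if (is.null(frameTimes)) frameTimes <- (seq_len(ncol(f0)) - 1) * 0.344
  if (is.null(zMm)) zMm <- (seq_len(nrow(f0)) - 1) * 3
  new("FieldProfileSeries", zMm = zMm, f0 = f0, frameTimes = frameTimes,
      dropped = integer())
}

# Default study phantom + synced trace + linear breathing model.
studySetup <- function(seed = 3, nz = 8, traceS = 75, periodSdS = 0.4,
                       couplingPeakHz = NULL) {
  ph <- makePhantom(nz = nz)
  tr <- syncTrace(makeTrace(traceS, periodSdS = periodSdS, seed = seed))
  cp <- makeCouplingProfile(zMm(ph))
  if (!is.null(couplingPeakHz)) cp <- cp * couplingPeakHz / max(cp)
  list(phantom = ph, trace = tr, coupling = cp,
       model = makeBreathingModel(cp))
}
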