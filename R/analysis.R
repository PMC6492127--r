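## Quantitative outputs: T2* maps, tSNR maps, ghost metric, ROI summaries.

#' Voxel-wise monoexponential T2* fit
#'
#' Fits \eqn{S(TE) = S_0 \exp(-TE/T_2^*)} to the echo magnitudes of every
#' in-mask voxel by nonlinear least squares (Levenberg-Marquardt),
#' initialised from the log-linear regression, with bounds
#' \eqn{T_2^* \in (0.1, 500]} ms. The fit is on magnitudes with no constant
#' offset; the Rician noise-floor bias is accepted and measured, not
#' corrected. Voxels with no positive signal (or fewer than 2 positive
#' echoes) are marked invalid.
#'
#' @param echoMags numeric array [nx, ny, nSlice, nEcho] (or [nx, ny, nEcho]
#'   for a single slice) of echo magnitudes
#' @param tesMs echo times, ms, strictly increasing, length >= 3
#' @param mask logical [nx, ny, nSlice] (default: all voxels)
#' @return a \linkS4class{T2StarMap}
#' @export
fitT2Star <- function(echoMags, tesMs, mask = NULL) {
  if (length(dim(echoMags)) == 3L)
    dim(echoMags) <- c(dim(echoMags)[1:2], 1L, dim(echoMags)[3L])
  d <- dim(echoMags)
  if (length(tesMs) < 3L)
    .bfStop("bf_parameter_error", "T2* fitting needs at least 3 echoes")
  if (any(diff(tesMs) <= 0))
    .bfStop("bf_parameter_error", "echo times must be strictly increasing")
  if (d[4L] != length(tesMs))
    .bfStop("bf_consistency_error", "echo dimension must match the TE list")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  stopifnot(identical(dim(mask), d[1:3]))
  t2s <- array(NA_real_, d[1:3]); s0 <- t2s; rmse <- t2s
  valid <- array(FALSE, d[1:3])
  idx <- which(mask)
  nVox <- prod(d[1:3])
  for (v in idx) {
    y <- echoMags[v + (seq_len(d[4L]) - 1L) * nVox]
    pos <- y > 0
    if (sum(pos) < 2L) next
    # log-linear init (exact on noiseless monoexponential data)
    fitLin <- stats::lm.fit(cbind(1, tesMs[pos]), log(y[pos]))
    slope <- unname(fitLin$coefficients[2L])
    t2Init <- if (is.finite(slope) && slope < 0) min(max(-1 / slope, 0.11), 500) else 50
    s0Init <- unname(exp(fitLin$coefficients[1L]))
    df <- data.frame(te = tesMs, y = y)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ s0 * exp(-te / t2), data = df,
                        start = list(s0 = s0Init, t2 = t2Init),
                        lower = c(0, 0.1), upper = c(Inf, 500),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) {
      if (t2Init <= 0.1 || t2Init > 500) next
      t2s[v] <- t2Init; s0[v] <- s0Init
      rmse[v] <- sqrt(mean((y - s0Init * exp(-tesMs / t2Init))^2))
    } else {
      cf <- stats::coef(fit)
      t2s[v] <- cf[["t2"]]; s0[v] <- cf[["s0"]]
      rmse[v] <- sqrt(mean(stats::residuals(fit)^2))
    }
    valid[v] <- TRUE
  }
  new("T2StarMap", t2sMs = t2s, s0 = s0, rmse = rmse, valid = valid)
}

#' Temporal signal-to-noise ratio map
#'
#' Voxel-wise ratio of the temporal mean to the temporal standard deviation
#' (sample SD, N-1) of an image time series. Voxels with zero SD are
#' flagged undefined (NA), never infinite. An optional linear detrend
#' (default off) removes a per-voxel linear drift before the SD; the mean
#' is always taken from the raw series.
#'
#' @param series numeric array [nx, ny, nSlice, nt] (or [nx, ny, nt]); >= 3
#'   time points
#' @param mask optional logical [nx, ny, nSlice] restricting the map
#' @param detrend remove a per-voxel linear trend before the SD
#' @return a \linkS4class{TSNRMap}
#' @export
tsnrMap <- function(series, mask = NULL, detrend = FALSE) {
  if (length(dim(series)) == 3L)
    dim(series) <- c(dim(series)[1:2], 1L, dim(series)[3L])
  d <- dim(series)
  nt <- d[4L]
  if (nt < 3L) .bfStop("bf_parameter_error", "tSNR needs at least 3 time points")
  flat <- matrix(series, prod(d[1:3]), nt)
  mu <- rowMeans(flat)
  if (detrend) {
    tt <- seq_len(nt) - (nt + 1) / 2
    beta <- (flat %*% tt) / sum(tt^2)
    flat <- flat - beta %*% t(tt)
  }
  sdv <- sqrt(rowSums((flat - rowMeans(flat))^2) / (nt - 1))
  tsnr <- ifelse(sdv > 0, mu / sdv, NA_real_)
  valid <- sdv > 0
  if (!is.null(mask)) {
    if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
    valid <- valid & as.vector(mask)
    tsnr[!valid] <- NA_real_
  }
  new("TSNRMap", tsnr = array(tsnr, d[1:3]), mean = array(mu, d[1:3]),
      sd = array(sdv, d[1:3]), valid = array(valid, d[1:3]))
}

#' Ghosting metric of a reconstructed image
#'
#' Mean magnitude outside the object mask (dilated by \code{dilateVox}
#' voxels to avoid edge ringing) divided by the mean magnitude inside the
#' cord mask. Scale-invariant; near zero for an artifact-free noiseless
#' reconstruction.
#'
#' @param image numeric or complex matrix [nx, ny]
#' @param objectMask logical [nx, ny], full object support (strictly inside
#'   the FOV with a guard band)
#' @param cordMaskSl logical [nx, ny], cord mask (default: the object mask)
#' @param dilateVox dilation radius in voxels (default 2)
#' @return dimensionless scalar
#' @export
ghostMetric <- function(image, objectMask, cordMaskSl = objectMask,
                        dilateVox = 2L) {
  stopifnot(identical(dim(image), dim(objectMask)))
  outside <- !.dilate2(objectMask, dilateVox)
  if (!any(outside))
    .bfStop("bf_parameter_error", "dilated object mask fills the FOV; no outside region")
  if (!any(cordMaskSl)) .bfStop("bf_parameter_error", "empty cord mask")
  mean(Mod(image[outside])) / mean(Mod(image[cordMaskSl]))
}

#' ROI summary statistics
#'
#' Median, 5/25/75/95th percentiles (linear interpolation between order
#' statistics) and mean of the in-mask voxels of a map.
#'
#' @param map numeric array
#' @param mask logical array of the same shape
#' @return named list: median, p5, p25, p75, p95, mean, n
#' @export
summarizeRoi <- function(map, mask) {
  stopifnot(identical(dim(map), dim(mask)))
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) .bfStop("bf_parameter_error", "empty mask (or no finite values)")
  q <- stats::quantile(vals, c(0.05, 0.25, 0.75, 0.95), type = 7, names = FALSE)
  list(median = stats::median(vals), p5 = q[1], p25 = q[2], p75 = q[3],
       p95 = q[4], mean = mean(vals), n = length(vals))
}
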