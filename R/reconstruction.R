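## Cartesian multi-shot reconstruction. The DFT is fixed to the centered
## unitary convention (see fft.R), pinned by a Parseval test. Phase encoding
## runs along the second image dimension (ky columns); each k-space line is
## a full readout (all kx) at one ky.

# Grid the acquired lines of one (slice, coil, echo[, line subset]) into an
# [nKx, nKy] matrix, accumulating duplicates; returns the matrix and the
# per-column acquisition count.
.gridLines <- function(set, slice, coil, lineIdx) {
  nKx <- set@meta$matrix[1L]; nKy <- set@meta$matrix[2L]
  K <- matrix(0 + 0i, nKx, nKy)
  cnt <- integer(nKy)
  kcol <- set@lines$kIndex[lineIdx] + 1L
  for (j in seq_along(lineIdx)) {
    K[, kcol[j]] <- K[, kcol[j]] + set@data[, lineIdx[j], coil, slice]
    cnt[kcol[j]] <- cnt[kcol[j]] + 1L
  }
  list(K = K, count = cnt)
}

#' Plain FFT reconstruction of fully sampled data
#'
#' Centered unitary inverse 2-D DFT per slice and echo for one coil.
#' Requires every phase-encode index to be filled exactly once per
#' (slice, echo).
#'
#' @param set a \linkS4class{KSpaceData}
#' @param coil coil index (default 1)
#' @param echoes echo indices to reconstruct (default: all present)
#' @return a complex \linkS4class{ImageVolume} [nx, ny, nSlice, nEcho]
#' @export
fftRecon <- function(set, coil = 1L, echoes = NULL) {
  stopifnot(is(set, "KSpaceData"))
  if (is.null(echoes)) echoes <- sort(unique(set@lines$echo))
  nKx <- set@meta$matrix[1L]; nKy <- set@meta$matrix[2L]
  nSlice <- dim(set@data)[4L]
  out <- array(0 + 0i, c(nKx, nKy, nSlice, length(echoes)))
  for (ei in seq_along(echoes)) {
    lineIdx <- which(set@lines$echo == echoes[ei])
    tab <- tabulate(set@lines$kIndex[lineIdx] + 1L, nbins = nKy)
    if (any(tab != 1L))
      .bfStop("bf_completeness_error",
              sprintf("echo %d: every k index must be filled exactly once (missing %d, duplicated %d)",
                      echoes[ei], sum(tab == 0L), sum(tab > 1L)))
    for (s in seq_len(nSlice)) {
      g <- .gridLines(set, s, coil, lineIdx)
      out[, , s, ei] <- ift2c(g$K)
    }
  }
  teMs <- if (!is.null(set@meta$teMs)) set@meta$teMs[echoes] else rep(NA_real_, length(echoes))
  new("ImageVolume", data = out,
      voxelMm = set@meta$voxelMm %||% c(1, 1, 1), teMs = teMs, info = list())
}

#' CG-SENSE reconstruction
#'
#' Solves the coil-sensitivity-encoded least-squares problem
#' \eqn{\min_x \|E x - s\|^2} by a conjugate-direction (conjugate-residual)
#' iteration on the normal equations \eqn{E^H E x = E^H s}, per slice and
#' echo; the variant is chosen so the tracked normal-equation residual norm
#' is non-increasing on consistent data. E maps an image to the
#' acquired k-space lines through coil-sensitivity weighting and the
#' centered unitary DFT; lines acquired more than once are weighted by
#' their multiplicity. Iteration stops at \code{nIter}, or when the relative
#' residual drops below \code{tol}; a residual increasing for 3 consecutive
#' iterations raises a numeric error with diagnostics.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param sens a \linkS4class{CoilSensitivities} with one map per coil in
#'   the container
#' @param nIter maximum CG iterations (default 30)
#' @param tol relative-residual stopping tolerance (default 1e-9; use ~1e-6
#'   for noisy data)
#' @param echoes echo indices to reconstruct (default: all)
#' @return a complex \linkS4class{ImageVolume}; \code{@info$iterations} and
#'   \code{@info$relres} hold per-(slice, echo) diagnostics
#' @export
cgSense <- function(set, sens, nIter = 30L, tol = 1e-9, echoes = NULL) {
  stopifnot(is(set, "KSpaceData"), is(sens, "CoilSensitivities"))
  nCoil <- dim(set@data)[3L]
  if (dim(sens@sens)[3L] != nCoil)
    .bfStop("bf_consistency_error", "sensitivity map count must match the coil count")
  if (is.null(echoes)) echoes <- sort(unique(set@lines$echo))
  nKx <- set@meta$matrix[1L]; nKy <- set@meta$matrix[2L]
  nSlice <- dim(set@data)[4L]
  S <- sens@sens
  out <- array(0 + 0i, c(nKx, nKy, nSlice, length(echoes)))
  iters <- matrix(0L, nSlice, length(echoes))
  relres <- matrix(0, nSlice, length(echoes))
  for (ei in seq_along(echoes)) {
    lineIdx <- which(set@lines$echo == echoes[ei])
    for (s in seq_len(nSlice)) {
      # right-hand side b = E^H s and sampling weights
      b <- matrix(0 + 0i, nKx, nKy)
      cnt <- NULL
      for (c in seq_len(nCoil)) {
        g <- .gridLines(set, s, c, lineIdx)
        cnt <- g$count
        b <- b + Conj(S[, , c]) * ift2c(g$K)
      }
      W <- matrix(rep(cnt, each = nKx), nKx, nKy)
      normOp <- function(x) {
        acc <- matrix(0 + 0i, nKx, nKy)
        for (c in seq_len(nCoil)) {
          k <- ft2c(S[, , c] * x) * W
          acc <- acc + Conj(S[, , c]) * ift2c(k)
        }
        acc
      }
      bn <- sqrt(sum(Mod(b)^2))
      if (bn == 0) { out[, , s, ei] <- 0 + 0i; next }  # all-zero data: zero image
      # Jacobi (intensity) preconditioning with the coil-sensitivity RSS:
      # the normal operator's image-space diagonal is ~ sum_c |S_c|^2
      dd <- apply(Mod(S)^2, c(1, 2), sum)
      P <- 1 / sqrt(pmax(dd, 1e-6 * max(dd)))
      normOpP <- function(y) P * normOp(P * y)
      b <- P * b
      bn <- sqrt(sum(Mod(b)^2))
      # conjugate-residual iteration on the (Hermitian PD) preconditioned
      # normal operator: minimizes the tracked residual norm over the Krylov
      # space, so it is non-increasing up to roundoff
      x <- matrix(0 + 0i, nKx, nKy)
      r <- b; p <- r
      Ar <- normOpP(r); Ap <- Ar
      rAr <- Re(sum(Conj(r) * Ar))
      lastRel <- Inf; nUp <- 0L; it <- 0L
      while (it < nIter) {
        it <- it + 1L
        alpha <- rAr / sum(Mod(Ap)^2)
        x <- x + alpha * p
        r <- r - alpha * Ap
        rel <- sqrt(sum(Mod(r)^2)) / bn
        if (rel > lastRel * 1.01) nUp <- nUp + 1L else nUp <- 0L
        if (nUp >= 3L)
          .bfStop("bf_numeric_error",
                  sprintf("CG-SENSE diverging at iteration %d (slice %d, echo %d): relative residual %.3e rising for 3 iterations",
                          it, s, echoes[ei], rel))
        lastRel <- rel
        if (rel < tol) break
        Ar <- normOpP(r)
        rArNew <- Re(sum(Conj(r) * Ar))
        beta <- rArNew / rAr
        p <- r + beta * p
        Ap <- Ar + beta * Ap
        rAr <- rArNew
      }
      out[, , s, ei] <- P * x  # undo the preconditioning change of variables
      iters[s, ei] <- it
      relres[s, ei] <- if (is.finite(lastRel)) lastRel else 0
    }
  }
  teMs <- if (!is.null(set@meta$teMs)) set@meta$teMs[echoes] else rep(NA_real_, length(echoes))
  new("ImageVolume", data = out, voxelMm = set@meta$voxelMm %||% c(1, 1, 1),
      teMs = teMs, info = list(iterations = iters, relres = relres))
}

#' EPI odd/even reference-line phase correction
#'
#' Removes the constant + linear phase discrepancy of reversed-polarity
#' (odd) echo-train lines in hybrid (x, ky) space, using reference
#' coefficients measured separately (e.g. on a phantom): each polarity -1
#' line is transformed along the readout, multiplied by
#' \eqn{\exp(-i(a + b (x - x_c)))} with \eqn{x_c = \lfloor N/2 \rfloor}
#' (0-based), and transformed back. The correction is not idempotent, so a
#' \code{refCorrected} flag in the container meta guards double application.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param refLines data.frame with columns \code{slice}, \code{const}
#'   (radians) and \code{slope} (radians/sample); one row per slice, or a
#'   single row applied to all slices
#' @return the corrected \linkS4class{KSpaceData} with
#'   \code{meta$refCorrected = TRUE}
#' @export
epiReferenceCorrect <- function(set, refLines) {
  stopifnot(is(set, "KSpaceData"))
  if (isTRUE(set@meta$refCorrected))
    .bfStop("bf_configuration_error",
            "container is already reference-corrected; refusing to apply twice")
  if (is.null(refLines) || !all(c("const", "slope") %in% names(refLines)))
    .bfStop("bf_configuration_error",
            "EPI data need reference-line coefficients (const, slope per slice)")
  nSlice <- dim(set@data)[4L]
  if (!"slice" %in% names(refLines)) refLines$slice <- 1L
  odd <- which(set@lines$polarity < 0)
  nKx <- dim(set@data)[1L]
  xs <- (seq_len(nKx) - 1L) - floor(nKx / 2)
  for (s in seq_len(nSlice)) {
    row <- refLines[match(s, refLines$slice), ]
    if (any(is.na(row$const))) row <- refLines[1L, ]
    corr <- exp(-1i * (row$const + row$slope * xs))
    if (!length(odd)) next
    for (c in seq_len(dim(set@data)[3L])) {
      h <- ift1c(set@data[, odd, c, s, drop = TRUE])
      h <- h * corr  # corr recycles down the rows (x dimension)
      set@data[, odd, c, s] <- ft1c(h)
    }
  }
  set@meta$refCorrected <- TRUE
  set
}

#' Root-sum-of-squares combination of echo images
#'
#' Voxelwise \eqn{\sqrt{\sum_e |I_e|^2}} across the echo dimension;
#' invariant to per-echo global phase.
#'
#' @param echoImages an \linkS4class{ImageVolume} with one or more echoes,
#'   or a list of single-echo \linkS4class{ImageVolume}s on a common grid
#' @return a magnitude \linkS4class{ImageVolume} with a single (combined)
#'   echo dimension
#' @export
rssCombine <- function(echoImages) {
  if (is.list(echoImages) && !is(echoImages, "ImageVolume")) {
    dims <- lapply(echoImages, function(v) dim(v@data))
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
      .bfStop("bf_consistency_error", "echo images must share geometry")
    arr <- array(0 + 0i, c(dims[[1]][1:3], length(echoImages)))
    for (e in seq_along(echoImages)) arr[, , , e] <- echoImages[[e]]@data[, , , 1L]
    vox <- echoImages[[1]]@voxelMm
  } else {
    stopifnot(is(echoImages, "ImageVolume"))
    arr <- echoImages@data
    vox <- echoImages@voxelMm
  }
  if (dim(arr)[4L] < 1L) .bfStop("bf_consistency_error", "need at least one echo")
  rss <- sqrt(apply(Mod(arr)^2, c(1, 2, 3), sum))
  new("ImageVolume", data = array(rss, c(dim(rss), 1L)), voxelMm = vox,
      teMs = NA_real_, info = list())
}

#' Sensitivity-weighted least-squares coil combination
#'
#' \eqn{\sum_c \bar S_c I_c / \sum_c |S_c|^2}: the closed-form solution of
#' the fully sampled SENSE problem, used as an independent reference for
#' \code{\link{cgSense}} at unit undersampling.
#'
#' @param coilImages complex array [nx, ny, nCoil]
#' @param sens a \linkS4class{CoilSensitivities}
#' @export
sensCombine <- function(coilImages, sens) {
  S <- sens@sens
  stopifnot(identical(dim(coilImages), dim(S)))
  num <- matrix(0 + 0i, dim(S)[1L], dim(S)[2L])
  den <- matrix(0, dim(S)[1L], dim(S)[2L])
  for (c in seq_len(dim(S)[3L])) {
    num <- num + Conj(S[, , c]) * coilImages[, , c]
    den <- den + Mod(S[, , c])^2
  }
  out <- num
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[den == 0] <- 0 + 0i
  out
}

#' Subset a k-space container to a set of excitations
#'
#' Keeps the lines whose excitation id is in \code{exc}; used to pull single
#' EPI volumes out of a time series.
#'
#' @param set a \linkS4class{KSpaceData}
#' @param exc excitation ids to keep
#' @export
subsetExcitations <- function(set, exc) {
  stopifnot(is(set, "KSpaceData"))
  keep <- which(set@lines$exc %in% exc)
  if (!length(keep)) .bfStop("bf_consistency_error", "no lines match the requested excitations")
  set@data <- set@data[, keep, , , drop = FALSE]
  set@lines <- set@lines[keep, , drop = FALSE]
  rownames(set@lines) <- NULL
  set
}

#' Reconstruct an EPI time series volume by volume
#'
#' Groups excitations into volumes (\code{shots} consecutive excitations per
#' volume), runs \code{\link{cgSense}} on each, and returns the magnitude
#' time series.
#'
#' @param set a \linkS4class{KSpaceData} of type EPI4
#' @param sens a \linkS4class{CoilSensitivities}
#' @param nIter,tol CG-SENSE settings (default 30, 1e-6)
#' @return numeric array [nx, ny, nSlice, nVolume] of magnitudes
#' @export
reconTimeSeries <- function(set, sens, nIter = 30L, tol = 1e-6) {
  stopifnot(is(set, "KSpaceData"))
  shots <- set@meta$shots %||% 4L
  exc <- sort(unique(set@lines$exc))
  nVol <- length(exc) %/% shots
  nKx <- set@meta$matrix[1L]; nKy <- set@meta$matrix[2L]
  nSlice <- dim(set@data)[4L]
  out <- array(0, c(nKx, nKy, nSlice, nVol))
  for (v in seq_len(nVol)) {
    sub <- subsetExcitations(set, exc[((v - 1L) * shots + 1L):(v * shots)])
    img <- cgSense(sub, sens, nIter = nIter, tol = tol)
    out[, , , v] <- Mod(img@data[, , , 1L])
  }
  out
}
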