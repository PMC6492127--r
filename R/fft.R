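# Centered unitary discrete Fourier transforms.
#
# Convention (pinned by a Parseval test): the DC component of k-space sits at
# 0-based index floor(N/2) along every transformed dimension, and both
# directions carry 1/sqrt(N) so that image energy equals k-space energy.

.roll <- function(x, k) {
  n <- length(x)
  if (n == 0L || k %% n == 0L) return(x)
  k <- k %% n
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}

# fftshift: move index 0 (1-based 1) to floor(n/2) (1-based floor(n/2)+1).
.shiftIdx <- function(n) .roll(seq_len(n), floor(n / 2))
.ishiftIdx <- function(n) .roll(seq_len(n), -floor(n / 2))

fftShift2 <- function(x) x[.shiftIdx(nrow(x)), .shiftIdx(ncol(x)), drop = FALSE]
ifftShift2 <- function(x) x[.ishiftIdx(nrow(x)), .ishiftIdx(ncol(x)), drop = FALSE]

# 2-D centered unitary forward DFT (image -> k-space).
ft2c <- function(x) fftShift2(stats::fft(ifftShift2(x))) / sqrt(length(x))

# 2-D centered unitary inverse DFT (k-space -> image).
ift2c <- function(k) fftShift2(stats::fft(ifftShift2(k), inverse = TRUE)) / sqrt(length(k))

# 1-D centered unitary transforms along the first dimension (columns are
# independent signals); used for hybrid (x, ky)-space EPI phase correction.
ft1c <- function(x) {
  x <- as.matrix(x)
  fftShift2c1(stats::mvfft(x[.ishiftIdx(nrow(x)), , drop = FALSE])) / sqrt(nrow(x))
}
ift1c <- function(k) {
  k <- as.matrix(k)
  fftShift2c1(stats::mvfft(k[.ishiftIdx(nrow(k)), , drop = FALSE], inverse = TRUE)) /
    sqrt(nrow(k))
}
fftShift2c1 <- function(x) x[.shiftIdx(nrow(x)), , drop = FALSE]
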