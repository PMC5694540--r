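#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann windows and 50% overlap. Returns
#' a one-sided density so that integrating over frequency recovers the
#' signal's average power (Parseval, up to windowing bias).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length in seconds (default 1).
#' @param overlap Fractional overlap between windows (default 0.5).
#' @return A data frame with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nw <- max(8L, as.integer(round(window_s * fs)))
  n <- length(x)
  if (n < nw) nw <- n
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))  # Hann
  scale <- fs * sum(w^2)
  nf <- nw %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when nw even)
    mult <- rep(2, nf)
    mult[1L] <- 1
    if (nw %% 2L == 0L) mult[nf] <- 1
    acc <- acc + p * mult
  }
  data.frame(freq = (seq_len(nf) - 1L) * fs / nw, psd = acc / length(starts))
}

#' Integrated band power from a PSD
#'
#' Trapezoidal integration of the spectral density over `[band[1], band[2]]`.
#'
#' @param psd A data frame as returned by [welch_psd()].
#' @param band Length-2 frequency band (Hz).
#' @return Integrated power within the band.
#' @export
band_power <- function(psd, band) {
  stopifnot(length(band) == 2L, band[2L] > band[1L])
  idx <- which(psd$freq >= band[1L] & psd$freq <= band[2L])
  if (length(idx) < 2L) stopf("band too narrow for the PSD frequency grid")
  f <- psd$freq[idx]
  p <- psd$psd[idx]
  sum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}
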