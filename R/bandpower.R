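#' Canonical EEG frequency bands
#'
#' The five rhythms used throughout the pipeline: delta 1-4, theta 4-8,
#' alpha 8-14, beta 14-31, gamma 31-50 Hz.
#'
#' @return Data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 14, 31),
             hi = c(4, 8, 14, 31, 50))
}

check_band <- function(band) {
  stopifnot(is.list(band) || is.data.frame(band))
  if (!(band$lo > 0 && band$hi > band$lo))
    stop("band definition requires 0 < lo < hi")
  invisible(band)
}

# Welch PSD estimate: Hann windows of `nperseg` samples, 50% overlap,
# one-sided, normalised by fs * sum(w^2) so that summing bins * df
# approximates mean signal power. Returns list(freq, psd) with psd a
# channels x bins matrix.
welch_psd <- function(x, fs, nperseg = round(fs)) {
  n <- ncol(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / nperseg)  # Hann (periodic)
  norm <- fs * sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- matrix(0, nrow(x), nf)
  for (s in starts) {
    seg <- x[, s:(s + nperseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)                       # detrend (mean removal)
    ft <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
    p <- (Mod(ft[seq_len(nf), , drop = FALSE])^2) / norm
    # one-sided: double all interior bins
    if (nf > 2L) p[2:(nf - 1L), ] <- 2 * p[2:(nf - 1L), ]
    acc <- acc + t(p)
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

#' Per-electrode band power of a segment
#'
#' Computes one nonnegative power value per channel for a frequency band,
#' either as the mean of Welch periodogram bins whose frequency falls in
#' `[lo, hi)` (`method = "welch"`, 1-s Hann windows, 50% overlap), or as the
#' mean squared amplitude of the band-pass-filtered signal
#' (`method = "mean_square"`, the literal expectation-of-x-squared
#' definition of PSD on the band-limited signal, 4th-order Butterworth).
#'
#' @param segment A [raw_recording()] (typically a 4-s segment).
#' @param band A row of [eeg_bands()] or a `list(name=, lo=, hi=)`.
#' @param method `"welch"` or `"mean_square"`.
#' @return Numeric vector of length `nrow(segment$samples)`, all `>= 0`.
#' @export
#' @examples
#' seg <- raw_recording(matrix(sin(2 * pi * 10 * (1:800) / 200), 1), "CZ", fs = 200)
#' band_power(seg, list(name = "alpha", lo = 8, hi = 14))  # ~0.5
band_power <- function(segment, band, method = c("welch", "mean_square")) {
  method <- match.arg(method)
  check_band(band)
  fs <- segment$fs
  x <- segment$samples
  if (band$hi >= fs / 2)
    stop("band_power: band upper edge ", band$hi,
         " Hz violates the Nyquist limit (fs/2 = ", fs / 2, " Hz)")
  if (ncol(x) < fs / band$lo)
    stop("band_power: segment shorter than one cycle of the band lower edge")
  if (method == "welch") {
    est <- welch_psd(x, fs)
    sel <- est$freq >= band$lo & est$freq < band$hi
    if (!any(sel))
      stop("band_power: no periodogram bin falls inside [", band$lo, ", ",
           band$hi, ") Hz (frequency-resolution error)")
    p <- rowMeans(est$psd[, sel, drop = FALSE])
  } else {
    bf <- signal::butter(4, c(band$lo, band$hi) / (fs / 2), type = "pass")
    p <- apply(x, 1L, function(ch) mean(signal::filtfilt(bf, ch)^2))
  }
  pmax(p, 0)
}

#' Band-power table of a segment over a band set
#'
#' @param segment A [raw_recording()].
#' @param bands Data frame of band definitions (default [eeg_bands()]).
#' @inheritParams band_power
#' @return Nonnegative matrix, electrodes x bands, with dimnames.
#' @export
band_power_table <- function(segment, bands = eeg_bands(),
                             method = c("welch", "mean_square")) {
  method <- match.arg(method)
  if (method == "welch") {
    # one shared PSD estimate for all bands
    fs <- segment$fs
    if (any(bands$hi >= fs / 2))
      stop("band_power_table: band upper edge violates the Nyquist limit")
    est <- welch_psd(segment$samples, fs)
    out <- vapply(seq_len(nrow(bands)), function(b) {
      sel <- est$freq >= bands$lo[b] & est$freq < bands$hi[b]
      if (!any(sel))
        stop("band_power_table: no periodogram bin inside [", bands$lo[b],
             ", ", bands$hi[b], ") Hz (frequency-resolution error)")
      pmax(rowMeans(est$psd[, sel, drop = FALSE]), 0)
    }, numeric(nrow(segment$samples)))
  } else {
    out <- vapply(seq_len(nrow(bands)), function(b)
      band_power(segment, bands[b, ], method = method),
      numeric(nrow(segment$samples)))
  }
  out <- matrix(out, nrow = nrow(segment$samples))
  dimnames(out) <- list(segment$channel_labels, bands$name)
  out
}
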