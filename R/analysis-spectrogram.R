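# Short-time Fourier spectrogram for analog signals (LFP). Windowed FFTs are
# delegated to signal::specgram; this layer fixes the scaling so each column
# is a one-sided power spectral density: summing psd * df over frequencies
# recovers the windowed signal variance (Parseval).

#' Spectrogram of an analog signal
#'
#' Splits the signal into (optionally overlapping) tapered windows and
#' returns the magnitude-squared short-time Fourier transform, scaled as a
#' one-sided power spectral density (unit^2/Hz). Frequency resolution is
#' `sampling_rate / window_length`.
#'
#' @param sig an analog signal.
#' @param window_length window size in samples (`<=` signal length).
#' @param overlap fraction of a window shared by consecutive windows,
#'   in `[0, 1)`.
#' @param window taper: `"hann"` or `"rectangular"`.
#' @return A `spectrogram_result`: `times` (`qty` s, window centers),
#'   `frequencies` (`qty` Hz, spanning 0 to the Nyquist frequency), `power`
#'   (frequency x time matrix), `window_length`, `overlap`.
#' @export
spectrogram <- function(sig, window_length = 256L, overlap = 0.5,
                        window = c("hann", "rectangular")) {
  stopifnot(inherits(sig, "AnalogSignal"))
  window <- match.arg(window)
  x <- q_mag(sig$samples)
  nl <- as.integer(window_length)
  if (nl > length(x))
    stop("spectrogram: window_length exceeds the signal length", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("spectrogram: overlap must be in [0, 1)", call. = FALSE)
  fs <- .hz(sig$sampling_rate)
  win <- if (window == "hann") signal::hanning(nl) else rep(1, nl)
  sp <- signal::specgram(x, n = nl, Fs = fs, window = win,
                         overlap = floor(overlap * nl))
  pw <- Mod(sp$S)^2 / (fs * sum(win^2)) # two-sided PSD, positive freqs only
  # one-sided scaling: double every non-DC bin (the Nyquist bin is not
  # returned for real input)
  nf <- length(sp$f)
  pw <- pw * c(1, rep(2, nf - 1L))
  structure(list(times = qty(as.numeric(sp$t) + .secs(sig$t_start), "s"),
                 frequencies = qty(as.numeric(sp$f), "Hz"),
                 power = pw,
                 window_length = nl, overlap = overlap, taper = window),
            class = "spectrogram_result")
}
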