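#' Design the respiratory bandpass filter
#'
#' Windowed-FIR (Hamming) linear-phase bandpass used to suppress heart sounds
#' and muscular noise below 75 Hz and out-of-band content above 1000 Hz.
#' Defaults reproduce the pipeline's 500th-order 75-1000 Hz filter.
#'
#' @param order Filter order (number of taps minus one). Default 500.
#' @param low_hz,high_hz Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `order + 1` symmetric taps.
#' @examples
#' h <- design_bandpass()
#' length(h)  # 501
#' @export
design_bandpass <- function(order = 500L, low_hz = 75, high_hz = 1000,
                            fs = 10000) {
  if (order < 2L || order %% 2L != 0L) {
    stop("'order' must be an even integer >= 2 (linear-phase type I)")
  }
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  as.numeric(signal::fir1(order, c(low_hz, high_hz) / (fs / 2), type = "pass"))
}

# Zero-phase-aligned FIR filtering: full convolution, then drop the
# (length(h)-1)/2 group-delay samples so output index n corresponds to input
# index n. The tail is implicitly zero-padded.
.filter_compensated <- function(x, h) {
  n <- length(x)
  delay <- (length(h) - 1L) %/% 2L
  y_full <- stats::convolve(x, rev(h), type = "open")
  y_full[(delay + 1L):(delay + n)]
}

#' Preprocess a raw recording for crackle detection
#'
#' Applies, in order: mean removal, 75-1000 Hz FIR bandpass filtering with
#' group-delay compensation (so event times are reported on the raw-signal
#' time base), and peak amplitude normalization into \[-1, 1\]. The result is
#' the filtered-and-normalized signal the TVAR detector models.
#'
#' @param rec A raw-stage [sound_recording()] at 10 kHz.
#' @param taps Optional filter taps; defaults to [design_bandpass()].
#' @return A normalized-stage [sound_recording()] of the same length.
#' @examples
#' raw <- sound_recording(rnorm(2000), fs = 1e4)
#' s_fn <- preprocess_recording(raw)
#' max(abs(s_fn$samples))  # 1
#' @export
preprocess_recording <- function(rec, taps = design_bandpass()) {
  stopifnot(inherits(rec, "sound_recording"))
  if (rec$stage != "raw") {
    stop("preprocess_recording() expects a raw-stage recording")
  }
  .check_fs_10k(rec$fs)
  x <- rec$samples - mean(rec$samples)
  y <- .filter_compensated(x, taps)
  peak <- max(abs(y))
  if (peak == 0) {
    stop("cannot normalize an all-zero (silent) signal")
  }
  sound_recording(y / peak, fs = rec$fs, label = rec$label,
                  stage = "normalized")
}

#' Peak-normalize a signal into \[-1, 1\]
#'
#' @param x Numeric vector, not all zero.
#' @return `x / max(abs(x))`.
#' @export
peak_normalize <- function(x) {
  peak <- max(abs(x))
  if (peak == 0) stop("cannot normalize an all-zero (silent) signal")
  x / peak
}
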