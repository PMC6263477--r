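#' Respiratory sound recording
#'
#' Lightweight container for a mono respiratory sound signal. The processing
#' pipeline tracks a `stage` attribute: `"raw"` straight off disk or the
#' simulator's mixer, `"filtered"` after mean removal and bandpass filtering,
#' and `"normalized"` once peak-scaled into \[-1, 1\] (the form the crackle
#' detector consumes).
#'
#' @param samples Numeric vector of finite sample amplitudes (dimensionless).
#' @param fs Sampling rate in Hz. The pipeline requires 10000 Hz.
#' @param label Optional auscultation-point code, e.g. `"LBe"` (left basal
#'   exterior) or `"T"` (trachea). Free metadata; validated only by
#'   [validate_auscultation_label()] when used for file naming.
#' @param stage Processing stage, one of `"raw"`, `"filtered"`, `"normalized"`.
#' @return An object of class `sound_recording`.
#' @examples
#' rec <- sound_recording(sin(2 * pi * 100 * (0:999) / 1e4), fs = 1e4)
#' rec
#' @export
sound_recording <- function(samples, fs, label = NULL, stage = "raw") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("'samples' must be a non-empty numeric vector")
  }
  if (!all(is.finite(samples))) {
    stop("'samples' contains non-finite values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  stage <- match.arg(stage, c("raw", "filtered", "normalized"))
  if (stage == "normalized") {
    peak <- max(abs(samples))
    if (peak > 1 + 1e-9) {
      stop("normalized-stage samples must lie in [-1, 1]")
    }
  }
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         label = label, stage = stage),
    class = "sound_recording"
  )
}

#' @export
print.sound_recording <- function(x, ...) {
  cat(sprintf("<sound_recording> %d samples @ %g Hz (%.3f s), stage: %s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$stage,
              if (!is.null(x$label)) paste0(", point: ", x$label) else ""))
  invisible(x)
}

#' @export
length.sound_recording <- function(x) length(x$samples)

#' Duration in seconds
#' @param rec A [sound_recording()] or [maneuver_template()].
#' @return Duration in seconds.
#' @export
duration <- function(rec) UseMethod("duration")

#' @export
duration.sound_recording <- function(rec) length(rec$samples) / rec$fs

# Coerce detector input: accept a normalized-stage recording or a bare
# numeric vector already scaled into [-1, 1].
.as_normalized_samples <- function(x, fs = NULL) {
  if (inherits(x, "sound_recording")) {
    if (x$stage != "normalized") {
      stop("recording is at stage '", x$stage,
           "'; run preprocess_recording() first")
    }
    list(samples = x$samples, fs = x$fs)
  } else if (is.numeric(x)) {
    if (is.null(fs)) stop("'fs' must be supplied with a bare numeric signal")
    if (max(abs(x)) > 1 + 1e-9) {
      stop("signal exceeds [-1, 1]; run preprocess_recording() first")
    }
    list(samples = as.numeric(x), fs = fs)
  } else {
    stop("expected a sound_recording or numeric vector")
  }
}

.check_fs_10k <- function(fs) {
  if (!isTRUE(all.equal(fs, 10000))) {
    stop("unsupported sampling rate ", fs,
         " Hz: the pipeline requires 10 kHz recordings")
  }
  invisible(fs)
}

#' Validate an auscultation-point label
#'
#' Thoracic recording points follow a 3 x 2 grid nomenclature: side `L`/`R`
#' (left/right), row `A`/`M`/`B` (apical/medial/basal), line `e`/`i`
#' (exterior/interior), e.g. `"LBe"`; the trachea is `"T"`.
#'
#' @param label Character label to check.
#' @return The label, invisibly, if valid; otherwise an error.
#' @export
validate_auscultation_label <- function(label) {
  if (!is.character(label) || length(label) != 1L) {
    stop("label must be a single string")
  }
  if (!grepl("^([LR][AMB][ei]|T)$", label)) {
    stop("invalid auscultation label '", label,
         "': expected [LR][AMB][ei] or 'T'")
  }
  invisible(label)
}
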