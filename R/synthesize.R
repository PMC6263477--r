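#' Synthetic crackle waveform
#'
#' Generates the classical two-parameter synthetic crackle: a unit-peak,
#' amplitude-modulated oscillation on normalized time \eqn{t \in [0, 1]}
#' whose instantaneous frequency decreases over time,
#' \deqn{x(t) = \sin^2(\pi t)\, \sin(4\pi\, t^{\gamma}), \qquad
#'       \gamma = \log(0.25) / \log(T_0),}
#' where \eqn{T_0} is the initial deflection width (IDW) as a fraction of the
#' total duration (the two-cycle duration, 2CD). Under this phase law the
#' carrier's first zero crossing falls exactly at the IDW
#' (\eqn{4\pi T_0^\gamma = \pi}) and the total phase at \eqn{t = 1} is
#' \eqn{4\pi}: exactly two cycles. The \eqn{\sin^2} envelope vanishes at both
#' endpoints.
#'
#' Presets: fine crackles have IDW 0.5 ms and 2CD 5 ms; coarse crackles have
#' IDW 1.2 ms and 2CD 9 ms.
#'
#' @param kind `"fine"` or `"coarse"` preset, or `NULL` to give the widths
#'   explicitly.
#' @param idw_ms Initial deflection width in ms.
#' @param two_cd_ms Two-cycle duration (total crackle duration) in ms.
#' @param fs Sampling rate in Hz (10 kHz).
#' @return Numeric waveform of `round(two_cd_ms * fs / 1000)` samples with
#'   peak absolute amplitude 1.
#' @examples
#' length(crackle_wave("fine"))    # 50 samples = 5 ms at 10 kHz
#' length(crackle_wave("coarse"))  # 90 samples = 9 ms
#' @export
crackle_wave <- function(kind = c("fine", "coarse"), idw_ms = NULL,
                         two_cd_ms = NULL, fs = 10000) {
  if (is.null(idw_ms) || is.null(two_cd_ms)) {
    kind <- match.arg(kind)
    preset <- crackle_presets()[[kind]]
    idw_ms <- preset$idw_ms
    two_cd_ms <- preset$two_cd_ms
  }
  if (idw_ms <= 0 || idw_ms >= two_cd_ms) {
    stop("'idw_ms' must satisfy 0 < idw_ms < two_cd_ms")
  }
  .check_fs_10k(fs)
  n <- as.integer(round(two_cd_ms * fs / 1000))
  t <- seq(0, 1, length.out = n)
  gamma <- log(0.25) / log(idw_ms / two_cd_ms)
  x <- sin(pi * t)^2 * sin(4 * pi * t^gamma)
  x / max(abs(x))
}

#' Fine and coarse crackle presets (IDW / 2CD in ms)
#' @return Named list with `fine` and `coarse` parameter lists.
#' @export
crackle_presets <- function() {
  list(fine = list(idw_ms = 0.5, two_cd_ms = 5),
       coarse = list(idw_ms = 1.2, two_cd_ms = 9))
}

#' Surrogate basal respiratory sound
#'
#' Generates a fully synthetic stand-in for a maneuver-guided basal breath
#' sound recording. Each phase segment is seeded Gaussian noise shaped by a
#' cascade of identical one-pole low-pass filters — giving the steep
#' (roughly 30 dB/octave with the default five poles) power decay above the
#' shaping corner that chest-wall breath sounds show — plus a small
#' broadband component standing in for sensor and airflow noise, passed
#' through the 75-1000 Hz respiratory bandpass and amplitude-modulated by
#' half-sine envelopes over each inspiration and expiration. Inspiration is
#' both louder and broader-band than expiration (higher shaping corner),
#' and apnea segments carry only a small noise floor. The output is
#' normalized-stage and ready for [detect_crackles()].
#'
#' This surrogate emulates the spectral band, the steep low-frequency power
#' concentration, and the phase-locked amplitude modulation of real basal
#' sounds; it does not reproduce heart-sound residue, turbulence bursts, or
#' between-subject spectral variability.
#'
#' @param maneuver A [maneuver_template()].
#' @param fs Sampling rate in Hz (10 kHz).
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @param insp_peak,exp_peak Peak envelope amplitudes of inspiration and
#'   expiration (defaults 1 and 0.5).
#' @param apnea_level Apnea noise floor relative to `insp_peak` (default
#'   0.015).
#' @param insp_pole_hz,exp_pole_hz Shaping corner frequencies of the
#'   low-pass cascade for inspiratory and expiratory/apneic noise (defaults
#'   250 and 180 Hz; inspiration broader-band).
#' @param n_poles Number of cascaded one-pole sections (default 5).
#' @param broadband_floor Relative amplitude of the white (pre-bandpass)
#'   noise component added to the shaped noise (default 0.03).
#' @param taps Bandpass taps, defaults to [design_bandpass()].
#' @return A normalized-stage [sound_recording()].
#' @export
basal_surrogate <- function(maneuver = maneuver_template(), fs = 10000,
                            seed = NULL, insp_peak = 1, exp_peak = 0.5,
                            apnea_level = 0.015, insp_pole_hz = 250,
                            exp_pole_hz = 180, n_poles = 5L,
                            broadband_floor = 0.03,
                            taps = design_bandpass()) {
  .check_fs_10k(fs)
  if (!is.null(seed)) set.seed(seed)
  seg <- maneuver_segments(maneuver, fs = fs)
  n_total <- as.integer(round(duration(maneuver) * fs))
  x <- numeric(n_total)
  pole <- function(f_c) exp(-2 * pi * f_c / fs)
  for (i in seq_len(nrow(seg))) {
    lo <- seg$start_sample[i]
    hi <- seg$end_sample[i] - 1L
    m <- hi - lo + 1L
    f_c <- if (seg$phase[i] == "inspiration") insp_pole_hz else exp_pole_hz
    shaped <- stats::rnorm(m)
    for (p in seq_len(n_poles)) {
      shaped <- as.numeric(stats::filter(shaped, pole(f_c), "recursive"))
    }
    shaped <- shaped / stats::sd(shaped) + broadband_floor * stats::rnorm(m)
    if (seg$phase[i] == "apnea") {
      env <- rep(apnea_level * insp_peak, m)
    } else {
      peak <- if (seg$phase[i] == "inspiration") insp_peak else exp_peak
      u <- (seq_len(m) - 0.5) / m
      env <- apnea_level * insp_peak + (peak - apnea_level * insp_peak) *
        sin(pi * u)
    }
    x[lo:hi] <- env * shaped / stats::sd(shaped)
  }
  y <- .filter_compensated(x, taps)
  sound_recording(peak_normalize(y), fs = fs, stage = "normalized")
}

# Table of the six insertion scenarios: which crackle kind goes where.
# region "late" = final 25% of the phase segment.
.scenario_components <- function(scenario, n_per_segment) {
  n <- n_per_segment
  comp <- function(kind, phase, region, n)
    list(kind = kind, phase = phase, region = region, n = n)
  switch(as.character(scenario),
    "1" = list(comp("fine", "inspiration", "full", n)),
    "2" = list(comp("fine", "inspiration", "late", n)),
    "3" = list(comp("coarse", "inspiration", "late", n)),
    "4" = list(comp("fine", "inspiration", "full", ceiling(n / 2)),
               comp("coarse", "inspiration", "full", floor(n / 2))),
    "5" = list(comp("coarse", "expiration", "full", n)),
    "6" = list(comp("fine", "inspiration", "full", n),
               comp("coarse", "expiration", "full", n)),
    stop("scenario must be an integer in 1..6")
  )
}

#' Scenario descriptions
#' @return Character vector describing insertion scenarios 1-6.
#' @export
scenario_descriptions <- function() {
  c("fine crackles along each inspiration",
    "fine crackles at the end of each inspiration",
    "coarse crackles at the end of each inspiration",
    "fine and coarse crackles (half each) along each inspiration",
    "coarse crackles along each expiration",
    "fine crackles along each inspiration plus coarse along each expiration")
}

# Rejection-sample non-overlapping onsets for one segment. Each entry of
# `durs` is an insertion's support length; the gap between two supports must
# be at least the longer of the two durations.
.draw_onsets <- function(seg_start, seg_end, durs, max_tries = 2000L) {
  onsets <- integer(0)
  placed_durs <- integer(0)
  for (dur in durs) {
    hi <- seg_end - dur  # support must end inside the segment
    if (hi < seg_start) stop("segment too short for a crackle insertion")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- seg_start + sample.int(hi - seg_start + 1L, 1L) - 1L
      gap_ok <- TRUE
      for (j in seq_along(onsets)) {
        a <- min(cand, onsets[j]); b <- max(cand, onsets[j])
        da <- if (cand <= onsets[j]) dur else placed_durs[j]
        gap <- b - (a + da)
        if (gap < max(dur, placed_durs[j])) { gap_ok <- FALSE; break }
      }
      if (gap_ok) {
        onsets <- c(onsets, cand)
        placed_durs <- c(placed_durs, dur)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("capacity error: could not place ", length(durs),
           " non-overlapping crackles in a segment of ",
           seg_end - seg_start, " samples")
    }
  }
  list(onsets = onsets, durs = placed_durs)
}

#' Build a simulated crackle-insertion scenario with ground truth
#'
#' Draws a surrogate basal recording, then inserts synthetic crackles at
#' random non-overlapping locations according to one of six scenarios (see
#' [scenario_descriptions()]). Each crackle is scaled so that its variance
#' over its own support equals `gain` times the variance of the basal sound
#' over that support (`scaling = "variance"`; `gain` of g corresponds to a
#' local SNR of \eqn{10 \log_{10} g} dB), or so that its peak equals
#' `gain` times the local basal peak (`scaling = "peak"`). The mixture is
#' re-peak-normalized; onsets are unaffected by that pure rescale.
#'
#' @param scenario Integer 1-6.
#' @param gain Gain factor (1.5, 2.5 or 3.5 in the evaluation study).
#' @param seed Integer seed; drives both the surrogate and the placement.
#' @param maneuver A [maneuver_template()].
#' @param fs Sampling rate (10 kHz).
#' @param n_per_segment Insertions per designated phase segment (default 10;
#'   scenario 4 splits this between fine and coarse).
#' @param scaling `"variance"` (default) or `"peak"`.
#' @param basal Optional pre-built normalized basal [sound_recording()]
#'   (skips the surrogate; placement still uses the RNG).
#' @param ... Passed to [basal_surrogate()].
#' @return An object of class `crackle_scenario`: list with `recording`
#'   (normalized-stage [sound_recording()]), `truth` (data frame:
#'   `onset_sample`, `onset_s`, `kind`, `gain`, `phase`, `cycle`), and
#'   `spec` (scenario parameters incl. seed).
#' @examples
#' sc <- simulate_scenario(1, gain = 3.5, seed = 7)
#' nrow(sc$truth)  # 40 insertions: 10 per inspiration x 4 cycles
#' @export
simulate_scenario <- function(scenario, gain, seed = NULL,
                              maneuver = maneuver_template(), fs = 10000,
                              n_per_segment = 10L,
                              scaling = c("variance", "peak"),
                              basal = NULL, ...) {
  scaling <- match.arg(scaling)
  if (gain <= 0) stop("'gain' must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(basal)) {
    basal <- basal_surrogate(maneuver, fs = fs, seed = NULL, ...)
  }
  stopifnot(inherits(basal, "sound_recording"), basal$stage == "normalized")
  comps <- .scenario_components(scenario, n_per_segment)
  seg <- maneuver_segments(maneuver, fs = fs)
  waves <- list(fine = crackle_wave("fine", fs = fs),
                coarse = crackle_wave("coarse", fs = fs))

  x <- basal$samples
  truth <- list()
  for (i in seq_len(nrow(seg))) {
    here <- Filter(function(cm) cm$phase == seg$phase[i], comps)
    if (length(here) == 0) next
    kinds <- unlist(lapply(here, function(cm) rep(cm$kind, cm$n)))
    region <- here[[1]]$region
    lo <- seg$start_sample[i]
    hi <- seg$end_sample[i]
    if (region == "late") lo <- lo + as.integer(floor(0.75 * (hi - lo)))
    durs <- vapply(waves[kinds], length, integer(1))
    drawn <- .draw_onsets(lo, hi, durs)
    for (j in seq_along(drawn$onsets)) {
      on <- drawn$onsets[j]
      wav <- waves[[kinds[j]]]
      supp <- on:(on + length(wav) - 1L)
      base_seg <- basal$samples[supp]
      scale <- if (scaling == "variance") {
        sqrt(gain * stats::var(base_seg) / stats::var(wav))
      } else {
        gain * max(abs(base_seg))
      }
      x[supp] <- x[supp] + scale * wav
      truth[[length(truth) + 1L]] <- data.frame(
        onset_sample = on, onset_s = (on - 1) / fs, kind = kinds[j],
        gain = gain, phase = seg$phase[i], cycle = seg$cycle[i])
    }
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$onset_sample), ]
  rownames(truth) <- NULL
  structure(
    list(recording = sound_recording(peak_normalize(x), fs = fs,
                                     stage = "normalized"),
         truth = truth,
         spec = list(scenario = scenario, gain = gain, seed = seed,
                     n_per_segment = n_per_segment, scaling = scaling,
                     fs = fs)),
    class = "crackle_scenario"
  )
}

#' @export
print.crackle_scenario <- function(x, ...) {
  cat(sprintf("<crackle_scenario %d> gain %g, %d insertions, %.1f s recording\n",
              x$spec$scenario, x$spec$gain, nrow(x$truth),
              duration(x$recording)))
  invisible(x)
}

#' Write a scenario's ground truth as CSV
#' @param scenario A [simulate_scenario()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(scenario, path) {
  utils::write.csv(scenario$truth, path, row.names = FALSE)
  invisible(path)
}
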