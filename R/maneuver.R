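#' Guided respiratory maneuver template
#'
#' The acquisition protocol guides the subject through a fixed breathing
#' maneuver so that respiratory phase can be inferred from time alone:
#' an initial apnea, `n_cycles` equal respiratory cycles split between
#' inspiration and expiration by the I:E ratio, and a final apnea. Defaults
#' give the standard 20 s maneuver: 2 s apnea, four 4 s cycles at I:E = 2:3
#' (1.6 s inspiration, 2.4 s expiration), 2 s final apnea.
#'
#' @param initial_apnea_s,final_apnea_s Apnea durations in seconds.
#' @param n_cycles Number of respiratory cycles.
#' @param cycle_s Duration of one cycle in seconds.
#' @param ie_ratio Length-2 integer vector, inspiration:expiration.
#' @return An object of class `maneuver_template`.
#' @examples
#' m <- maneuver_template()
#' duration(m)  # 20
#' @export
maneuver_template <- function(initial_apnea_s = 2, n_cycles = 4L, cycle_s = 4,
                              ie_ratio = c(2L, 3L), final_apnea_s = 2) {
  stopifnot(initial_apnea_s >= 0, final_apnea_s >= 0,
            n_cycles >= 1L, cycle_s > 0,
            length(ie_ratio) == 2L, all(ie_ratio > 0))
  structure(
    list(initial_apnea_s = initial_apnea_s, n_cycles = as.integer(n_cycles),
         cycle_s = cycle_s, ie_ratio = as.integer(ie_ratio),
         final_apnea_s = final_apnea_s),
    class = "maneuver_template"
  )
}

#' @export
print.maneuver_template <- function(x, ...) {
  cat(sprintf(
    "<maneuver_template> %g s apnea + %d x %g s cycles (I:E = %d:%d) + %g s apnea = %g s\n",
    x$initial_apnea_s, x$n_cycles, x$cycle_s, x$ie_ratio[1], x$ie_ratio[2],
    x$final_apnea_s, duration(x)))
  invisible(x)
}

#' @export
duration.maneuver_template <- function(rec) {
  rec$initial_apnea_s + rec$n_cycles * rec$cycle_s + rec$final_apnea_s
}

.insp_duration <- function(m) m$cycle_s * m$ie_ratio[1] / sum(m$ie_ratio)

#' Phase segment table of a maneuver
#'
#' @param maneuver A [maneuver_template()].
#' @param fs Optional sampling rate; if given, 1-based sample columns
#'   `start_sample`/`end_sample` are added (end exclusive).
#' @return Data frame with columns `phase` ("apnea"/"inspiration"/
#'   "expiration"), `cycle` (1-based, `NA` for apnea), `start_s`, `end_s`.
#' @export
maneuver_segments <- function(maneuver, fs = NULL) {
  m <- maneuver
  insp <- .insp_duration(m)
  rows <- list(data.frame(phase = "apnea", cycle = NA_integer_,
                          start_s = 0, end_s = m$initial_apnea_s))
  for (c in seq_len(m$n_cycles)) {
    t0 <- m$initial_apnea_s + (c - 1) * m$cycle_s
    rows <- c(rows, list(
      data.frame(phase = "inspiration", cycle = c, start_s = t0,
                 end_s = t0 + insp),
      data.frame(phase = "expiration", cycle = c, start_s = t0 + insp,
                 end_s = t0 + m$cycle_s)
    ))
  }
  tot <- duration(m)
  rows <- c(rows, list(data.frame(phase = "apnea", cycle = NA_integer_,
                                  start_s = tot - m$final_apnea_s,
                                  end_s = tot)))
  seg <- do.call(rbind, rows)
  if (!is.null(fs)) {
    seg$start_sample <- as.integer(round(seg$start_s * fs)) + 1L
    seg$end_sample <- as.integer(round(seg$end_s * fs)) + 1L
  }
  seg
}

#' Assign a respiratory phase to an event time
#'
#' @param onset_s Event time in seconds (vectorized).
#' @param maneuver A [maneuver_template()].
#' @return Data frame with columns `phase` and `cycle` (1-based cycle index,
#'   `NA` during apnea). Times outside the maneuver span are an error.
#' @examples
#' assign_phase(c(1, 2.5, 4, 19.5), maneuver_template())
#' @export
assign_phase <- function(onset_s, maneuver) {
  stopifnot(inherits(maneuver, "maneuver_template"))
  tot <- duration(maneuver)
  if (any(onset_s < 0 | onset_s > tot)) {
    stop("onset time outside the maneuver span [0, ", tot, "]")
  }
  insp <- .insp_duration(maneuver)
  t_rel <- onset_s - maneuver$initial_apnea_s
  cyc <- floor(round(t_rel / maneuver$cycle_s, 9)) + 1
  # round away float fuzz so exact phase boundaries classify deterministically
  within <- round(t_rel - (cyc - 1) * maneuver$cycle_s, 9)
  phase <- ifelse(onset_s < maneuver$initial_apnea_s |
                    onset_s >= tot - maneuver$final_apnea_s, "apnea",
                  ifelse(within < insp, "inspiration", "expiration"))
  cycle <- ifelse(phase == "apnea", NA_integer_, as.integer(cyc))
  data.frame(phase = phase, cycle = cycle)
}
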