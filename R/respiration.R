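#' Simulate a respiratory trace and segmented-acquisition timetable
#'
#' Emulates an end-expiration-triggered segmented Look-Locker acquisition
#' monitored by a digital data-logger. Each respiratory cycle ends in a
#' quiescent (end-expiration) plateau occupying `quiescent_fraction` of the
#' cycle; cycle durations jitter around the phantom's `resp_period_s`.
#' Segments of `lines_per_segment` k-space lines are triggered at the start
#' of a quiescent window; one inversion is played per segment and all
#' readouts follow at their inversion times, so the readout train
#' (n_readouts x TI spacing, about 5.5 s at the defaults) spans several
#' breaths and many lines inevitably fall outside quiescent windows --
#' exactly the lines retrospective gating must find.
#'
#' @param phantom a [phantom_spec()] (respiratory parameters).
#' @param protocol a [fair_protocol()].
#' @param seed integer seed for cycle-duration jitter.
#' @param quiescent_fraction override of the phantom's quiescent fraction;
#'   may be 1 (the entire trace is quiescent, e.g. breath-hold limit).
#' @param jitter_sd lognormal SD of cycle-duration jitter (0 = metronomic).
#' @return list with `resp` (class `resp_trace`: data.frame of quiescent
#'   `windows`, cycle boundaries, period) and `timetable` (class
#'   `acq_timetable`: one row per k-space line with `ti_index`,
#'   `kspace_row`, `segment`, `time_s`).
#' @export
simulate_respiration_and_timetable <- function(phantom,
                                               protocol = fair_protocol(
                                                 matrix_size = phantom$grid_shape[1],
                                                 fov_mm = phantom$fov_mm),
                                               seed = phantom$seed,
                                               quiescent_fraction =
                                                 phantom$quiescent_fraction,
                                               jitter_sd = 0.05) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (quiescent_fraction <= 0 || quiescent_fraction > 1) {
    stop("quiescent_fraction must lie in (0, 1]", call. = FALSE)
  }
  n_seg <- protocol$matrix_size %/% protocol$lines_per_segment
  tis_s <- protocol_tis(protocol) / 1000
  seg_span <- max(tis_s) + (protocol$lines_per_segment - 1) *
    protocol$tr_rf_ms / 1000
  total_s <- n_seg * max(protocol$tr_inversion_s, seg_span) +
    10 * phantom$resp_period_s

  n_cyc <- ceiling(total_s / phantom$resp_period_s) + 20
  durations <- with_seed(seed, {
    phantom$resp_period_s * exp(stats::rnorm(n_cyc, 0, jitter_sd))
  })
  boundaries <- c(0, cumsum(durations))
  win_start <- boundaries[-length(boundaries)] +
    (1 - quiescent_fraction) * durations
  win_end <- boundaries[-1]
  resp <- structure(list(
    windows = data.frame(start = win_start, end = win_end),
    cycle_boundaries = boundaries,
    period_s = phantom$resp_period_s,
    quiescent_fraction = quiescent_fraction
  ), class = "resp_trace")

  # trigger each segment at the first quiescent-window start that is at
  # least one inversion repetition time after the previous trigger
  triggers <- numeric(n_seg)
  t_prev <- -Inf
  for (s in seq_len(n_seg)) {
    k <- which(win_start >= (if (is.finite(t_prev))
      t_prev + protocol$tr_inversion_s else 0))[1]
    if (is.na(k)) stop("respiratory trace too short for the schedule",
                       call. = FALSE)
    triggers[s] <- win_start[k]
    t_prev <- triggers[s]
  }

  lps <- protocol$lines_per_segment
  seg <- rep(seq_len(n_seg), each = protocol$n_readouts * lps)
  ti_index <- rep(rep(seq_len(protocol$n_readouts), each = lps), n_seg)
  line_in_seg <- rep(rep(seq_len(lps), protocol$n_readouts), n_seg)
  kspace_row <- (seg - 1L) * lps + line_in_seg
  time_s <- triggers[seg] + tis_s[ti_index] +
    (line_in_seg - 1) * protocol$tr_rf_ms / 1000
  timetable <- structure(
    data.frame(ti_index = ti_index, kspace_row = kspace_row,
               segment = seg, time_s = time_s),
    class = c("acq_timetable", "data.frame"))
  list(resp = resp, timetable = timetable)
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("Respiratory trace: %d cycles, period %.2f s, quiescent %.0f%%\n",
              nrow(x$windows), x$period_s, 100 * x$quiescent_fraction))
  invisible(x)
}

# liver displacement (pixels along the row axis) at times t: zero inside
# quiescent windows, a half-sine excursion across each non-quiescent span
respiratory_displacement <- function(time_s, resp, amplitude_px) {
  b <- resp$cycle_boundaries
  idx <- findInterval(time_s, b)
  idx[idx < 1] <- 1
  idx[idx > nrow(resp$windows)] <- nrow(resp$windows)
  cyc_start <- b[idx]
  ws <- resp$windows$start[idx]
  quiescent <- time_s >= ws & time_s <= resp$windows$end[idx]
  span <- pmax(ws - cyc_start, .Machine$double.eps)
  u <- (time_s - cyc_start) / span
  d <- amplitude_px * sin(pi * pmin(pmax(u, 0), 1))
  d[quiescent] <- 0
  d
}
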