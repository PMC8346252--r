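# Spike-wave-discharge (SWD) detection: dynamic-threshold spike picking
# followed by rule-based train assembly. The criteria mirror the standard
# rodent screening settings: dynamic threshold 3-20x baseline, spike width
# 1-200 ms, inter-spike interval 0.05-0.6 s, train duration >= 0.5 s, trains
# closer than 1 s joined, minimum four spikes per train.

#' Spike-wave discharge detection parameters
#'
#' @param threshold_multiplier dynamic threshold as a multiple of baseline
#'   amplitude; must lie in the 3-20 screening range (default 6, chosen for
#'   sensitivity).
#' @param spike_duration_ms admissible supra-threshold excursion width, ms.
#' @param inter_spike_interval_s admissible gap between consecutive spikes of
#'   one train, seconds.
#' @param train_min_duration_s minimum train duration (first to last spike).
#' @param join_interval_s adjacent trains separated by less than this gap are
#'   merged into one event.
#' @param min_spikes minimum spikes per reported train.
#' @param baseline_window_s window of the rolling-median baseline estimator.
#' @return A list of class `swd_params`.
#' @export
swd_params <- function(threshold_multiplier = 6,
                       spike_duration_ms = c(1, 200),
                       inter_spike_interval_s = c(0.05, 0.6),
                       train_min_duration_s = 0.5,
                       join_interval_s = 1.0,
                       min_spikes = 4,
                       baseline_window_s = 60) {
  check_scalar_number(threshold_multiplier, "threshold_multiplier",
                      lower = 3, upper = 20)
  if (spike_duration_ms[1] > spike_duration_ms[2] ||
      inter_spike_interval_s[1] > inter_spike_interval_s[2])
    stop_invalid("interval bounds must be ordered")
  check_scalar_number(min_spikes, "min_spikes", lower = 1)
  structure(list(
    threshold_multiplier = threshold_multiplier,
    spike_duration_ms = spike_duration_ms,
    inter_spike_interval_s = inter_spike_interval_s,
    train_min_duration_s = train_min_duration_s,
    join_interval_s = join_interval_s,
    min_spikes = min_spikes,
    baseline_window_s = baseline_window_s
  ), class = "swd_params")
}

# Rolling-median-absolute-amplitude baseline, one value per second, expanded
# back to per-sample resolution. Floored at 1 uV so a flat signal cannot
# produce a zero threshold.
swd_baseline <- function(eeg, fs, window_s, eps = 1) {
  n_sec <- max(1L, floor(length(eeg) / fs))
  sec_med <- vapply(seq_len(n_sec), function(s) {
    median(abs(eeg[((s - 1) * fs + 1):min(s * fs, length(eeg))]))
  }, numeric(1))
  k <- min(2 * floor(window_s / 2) + 1, 2 * floor((n_sec - 1) / 2) + 1)
  roll <- if (k >= 3) as.numeric(stats::runmed(sec_med, k, endrule = "constant"))
          else sec_med
  per_sample <- roll[pmin(floor(seq_along(eeg) / fs) + 1L, n_sec)]
  pmax(per_sample, eps)
}

#' Detect candidate spike-wave spikes
#'
#' Baseline amplitude is the rolling median absolute amplitude over
#' `baseline_window_s` (epsilon-floored at 1 uV). Contiguous excursions of
#' |EEG| above `threshold_multiplier * baseline` are found, and excursions
#' separated by less than the minimum inter-spike interval are merged into a
#' single spike complex (the lobes of one biphasic spike cannot be distinct
#' spikes). A candidate spike is a complex whose total width falls inside
#' the admissible spike-duration window; its time is the absolute-amplitude
#' peak of the complex.
#'
#' @param eeg filtered EEG vector in microvolts.
#' @param fs sampling rate in Hz.
#' @param params an `swd_params` object.
#' @return Sorted numeric vector of candidate spike times in seconds.
#' @export
detect_spikes <- function(eeg, fs, params = swd_params()) {
  if (params$baseline_window_s >= length(eeg) / fs)
    stop_invalid("baseline window must be shorter than the recording")
  baseline <- swd_baseline(eeg, fs, params$baseline_window_s)
  over <- abs(eeg) > params$threshold_multiplier * baseline
  if (!any(over)) return(numeric(0))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  # merge excursions closer than the minimum inter-spike interval
  min_gap <- params$inter_spike_interval_s[1] * fs
  s <- starts[keep]; e <- ends[keep]
  if (length(s) > 1) {
    new_complex <- c(TRUE, s[-1] - e[-length(e)] >= min_gap)
    cid <- cumsum(new_complex)
    s <- as.numeric(tapply(s, cid, min))
    e <- as.numeric(tapply(e, cid, max))
  }
  width_ms <- (e - s + 1) / fs * 1000
  ok <- width_ms >= params$spike_duration_ms[1] &
    width_ms <= params$spike_duration_ms[2]
  s <- s[ok]; e <- e[ok]
  if (!length(s)) return(numeric(0))
  times <- vapply(seq_along(s), function(i) {
    idx <- s[i]:e[i]
    (idx[which.max(abs(eeg[idx]))] - 1) / fs
  }, numeric(1))
  sort(times)
}

#' Assemble spike trains into spike-wave-discharge events
#'
#' Greedy left-to-right grouping: consecutive spikes whose gap lies within
#' the inter-spike-interval window stay in one group; groups whose boundary
#' gap is below the join interval are then merged into a single event.
#' Events are reported only if they span at least the minimum train duration
#' (first to last spike) and contain at least `min_spikes` spikes.
#'
#' @param spike_times sorted numeric vector of spike times in seconds.
#' @param params an `swd_params` object.
#' @return A data.frame with one row per event: `start_s`, `end_s`,
#'   `n_spikes`, `duration_s`; the member spike times are kept in the
#'   list-column `spike_times`.
#' @export
assemble_trains <- function(spike_times, params = swd_params()) {
  if (is.unsorted(spike_times)) stop_invalid("spike times must be sorted")
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), duration_s = numeric(0))
  empty$spike_times <- list()
  if (length(spike_times) == 0) return(empty)
  gaps <- diff(spike_times)
  in_window <- gaps >= params$inter_spike_interval_s[1] &
    gaps <= params$inter_spike_interval_s[2]
  group <- cumsum(c(0L, !in_window)) + 1L
  # merge adjacent groups whose boundary gap is below the join interval
  n_groups <- max(group)
  if (n_groups > 1) {
    firsts <- tapply(spike_times, group, min)
    lasts <- tapply(spike_times, group, max)
    boundary <- firsts[-1] - lasts[-n_groups]
    event_of_group <- cumsum(c(1L, as.integer(boundary >= params$join_interval_s)))
    event <- event_of_group[group]
  } else event <- group
  rows <- lapply(split(spike_times, event), function(ts) {
    list(start_s = min(ts), end_s = max(ts), n_spikes = length(ts),
         duration_s = max(ts) - min(ts), spike_times = ts)
  })
  out <- data.frame(
    start_s = vapply(rows, `[[`, numeric(1), "start_s"),
    end_s = vapply(rows, `[[`, numeric(1), "end_s"),
    n_spikes = vapply(rows, `[[`, integer(1), "n_spikes"),
    duration_s = vapply(rows, `[[`, numeric(1), "duration_s")
  )
  out$spike_times <- lapply(rows, `[[`, "spike_times")
  keep <- out$duration_s >= params$train_min_duration_s &
    out$n_spikes >= params$min_spikes
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spike-wave-discharge events in a recording
#'
#' Convenience wrapper: preprocess, detect candidate spikes, assemble trains.
#'
#' @param rec a `fad_recording`.
#' @param params an `swd_params` object.
#' @param preprocess apply the standard filters first (default TRUE).
#' @return A data.frame of events as in \code{\link{assemble_trains}}.
#' @export
detect_swd <- function(rec, params = swd_params(), preprocess = TRUE) {
  if (preprocess) rec <- preprocess_recording(rec)
  spikes <- detect_spikes(rec$eeg, rec$sample_rate_hz, params)
  assemble_trains(spikes, params)
}
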