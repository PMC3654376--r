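#' Multichannel scalp EEG recording with spike events
#'
#' @param data channels x samples matrix of scalp potentials (microvolt).
#' @param fs sampling rate in Hz (> 0).
#' @param spike_times numeric vector of spike *peak* times in seconds,
#'   within `[0, duration)`.
#' @param channels optional character channel names.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, fs, spike_times = numeric(0),
                             channels = NULL) {
  data <- as.matrix(data)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  dur <- ncol(data) / fs
  if (any(spike_times < 0 | spike_times >= dur)) {
    stop("spike_times must lie within [0, ", round(dur, 3), ") s")
  }
  if (is.null(channels)) channels <- sprintf("E%03d", seq_len(nrow(data)))
  structure(
    list(data = data, fs = fs, spike_times = sort(as.numeric(spike_times)),
         channels = channels),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("Sensor recording: %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat(sprintf("  %d spike events\n", length(x$spike_times)))
  invisible(x)
}

#' Spike-centred segmentation of a recording
#'
#' Cuts one segment per spike, spanning `[t - pre_s, t + post_s)` around each
#' spike peak time `t` (default 1.5 s on each side). Spikes too close to the
#' recording edges are dropped with a warning. Sample indices are computed as
#' `round(fs * t)` with half-open `[start, end)` windows, so every segment
#' has exactly `round(fs * (pre_s + post_s))` samples.
#'
#' @param rec a [sensor_recording()], or a plain channels x samples matrix
#'   (then `fs` and `spike_times` must be given).
#' @param pre_s,post_s seconds before/after the spike peak (defaults 1.5).
#' @param fs,spike_times used only when `rec` is a bare matrix.
#' @return A 3-d array, channels x samples x spikes, with attributes
#'   `fs`, `spike_times` (the retained spikes), `offset_s = -pre_s` (time of
#'   the first sample relative to the peak).
#' @export
segment_spikes <- function(rec, pre_s = 1.5, post_s = 1.5, fs = NULL,
                           spike_times = NULL) {
  if (inherits(rec, "sensor_recording")) {
    data <- rec$data
    fs <- rec$fs
    spike_times <- rec$spike_times
  } else {
    data <- as.matrix(rec)
    if (is.null(fs) || is.null(spike_times)) {
      stop("`fs` and `spike_times` are required for a bare matrix")
    }
  }
  stopifnot(pre_s > 0, post_s > 0)
  n <- ncol(data)
  len <- as.integer(round(fs * (pre_s + post_s)))
  start <- as.integer(round(fs * (spike_times - pre_s)))  # 0-based
  ok <- start >= 0L & (start + len) <= n
  if (any(!ok)) {
    warning(sum(!ok), " spike(s) closer than the window to a recording ",
            "edge were dropped")
  }
  if (!any(ok)) stop("no usable spikes: all are too close to the edges")
  start <- start[ok]
  out <- array(0, dim = c(nrow(data), len, sum(ok)))
  for (k in seq_along(start)) {
    out[, , k] <- data[, (start[k] + 1L):(start[k] + len), drop = FALSE]
  }
  attr(out, "fs") <- fs
  attr(out, "spike_times") <- spike_times[ok]
  attr(out, "offset_s") <- -pre_s
  out
}

#' Carve a spike segment into pre-spike / spike / post-spike 1-s intervals
#'
#' Splits the central 3 s of a spike-centred segment into the three
#' contiguous analysis intervals: 1 s before the spike (`[t-1.5, t-0.5)`),
#' 1 s centred on the spike (`[t-0.5, t+0.5)`), and 1 s after
#' (`[t+0.5, t+1.5)`). Each interval has exactly `round(fs)` samples; when
#' `fs` is not an integer the epoch length is `floor(fs)` samples with a
#' warning (the spectral bin spacing then deviates from exactly 1 Hz and is
#' reported by [cross_spectra()]).
#'
#' @param segment channels x samples matrix, or channels x samples x spikes
#'   array from [segment_spikes()]; the spike peak is assumed at the centre
#'   sample.
#' @param fs sampling rate in Hz (taken from the segment attribute when
#'   present).
#' @param interval_s interval duration in seconds (default 1).
#' @return A named list `pre`, `spike`, `post` of arrays with the same
#'   leading dimensions as the input and `round(fs * interval_s)` samples,
#'   plus attribute `fs`.
#' @export
carve_intervals <- function(segment, fs = attr(segment, "fs"),
                            interval_s = 1) {
  if (is.null(fs)) stop("`fs` is required")
  dm <- dim(segment)
  if (is.null(dm)) segment <- matrix(segment, nrow = 1L)
  if (length(dim(segment)) == 2L) {
    segment <- array(segment, dim = c(dim(segment), 1L))
  }
  ns <- dim(segment)[2L]
  ep <- fs * interval_s
  if (abs(ep - round(ep)) > 1e-9) {
    warning("fs * interval length is not an integer; using floor(), the ",
            "frequency resolution will deviate from ", 1 / interval_s, " Hz")
    ep <- floor(ep)
  } else {
    ep <- as.integer(round(ep))
  }
  if (ns < 3L * ep) {
    stop("segment too short: need at least ", 3L * ep, " samples (3 ",
         "intervals), got ", ns)
  }
  # spike peak sits at the centre sample; boundaries at peak -1.5/-0.5/+0.5
  # interval lengths, half-open [start, end)
  centre <- ns %/% 2L
  starts <- centre - (3L * ep) %/% 2L + ep * (0:2)
  if (starts[1L] < 0L) starts <- starts - starts[1L]
  out <- lapply(starts, function(s0) {
    segment[, (s0 + 1L):(s0 + ep), , drop = FALSE]
  })
  names(out) <- c("pre", "spike", "post")
  for (i in seq_along(out)) attr(out[[i]], "fs") <- fs
  attr(out, "fs") <- fs
  out
}

#' Time at 50% of the spike peak on the rising phase
#'
#' Finds the spike peak (the extremum of the chosen polarity) and returns the
#' time, linearly interpolated between samples, at which the absolute
#' amplitude crosses half the peak amplitude on the rising phase toward the
#' peak (the crossing immediately preceding the peak). This earlier
#' timepoint is commonly preferred over the peak itself for localisation,
#' because by the peak the discharge has typically propagated.
#'
#' @param waveform numeric vector.
#' @param fs sampling rate in Hz.
#' @param polarity `"auto"` (extremum of largest absolute value), `"pos"`, or
#'   `"neg"`.
#' @return Time of the half-peak crossing in seconds (first sample = 0 s).
#' @export
half_peak_time <- function(waveform, fs, polarity = c("auto", "pos", "neg")) {
  polarity <- match.arg(polarity)
  w <- as.numeric(waveform)
  if (length(w) < 2L || diff(range(w)) == 0) {
    stop("flat or trivial waveform: no peak")
  }
  sgn <- switch(polarity,
    auto = if (abs(max(w)) >= abs(min(w))) 1 else -1,
    pos = 1,
    neg = -1
  )
  v <- sgn * w
  ipk <- which.max(v)
  if (ipk == 1L) stop("peak at the first sample: no rising phase")
  half <- v[ipk] / 2
  below <- which(v[seq_len(ipk - 1L)] < half)
  if (!length(below)) {
    stop("waveform never falls below half the peak before the peak")
  }
  i0 <- max(below)                     # last sample below half before peak
  frac <- (half - v[i0]) / (v[i0 + 1L] - v[i0])
  (i0 - 1L + frac) / fs
}

#' Read and write spike event tables
#'
#' Events are stored as TSV with columns `onset_s` (numeric seconds) and
#' `label`.
#'
#' @param path file path.
#' @param onset_s numeric onsets in seconds.
#' @param label event labels (recycled).
#' @return `read_events()` returns a data.frame with `onset_s`, `label`.
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(ev))) {
    stop("event table must have columns onset_s and label: ", path)
  }
  onset <- suppressWarnings(as.numeric(ev$onset_s))
  if (anyNA(onset)) {
    bad <- which(is.na(onset))[1L]
    stop("non-numeric onset_s in event table row ", bad, ": '",
         ev$onset_s[bad], "'")
  }
  data.frame(onset_s = onset, label = as.character(ev$label))
}

#' @rdname read_events
#' @export
write_events <- function(onset_s, label = "spike", path) {
  write.table(data.frame(onset_s = onset_s, label = label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
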