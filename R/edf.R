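# Minimal European Data Format (EDF) I/O: continuous 16-bit recordings with
# identical sampling rate on every channel, 1-s data records. This covers
# the interchange need of the pipeline (scalp EEG in, scalp EEG out); EDF+
# annotations are not handled -- spike events travel in a TSV sidecar.

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16 bits over the per-channel physical range, the
#' format's native precision (worst-case error is one quantisation step,
#' i.e. `range / 65534`). The recording is padded with zeros to a whole
#' number of 1-s data records.
#'
#' @param rec a [sensor_recording()].
#' @param path output path.
#' @param physical_dim physical dimension string (default `"uV"`).
#' @return The path, invisibly.
#' @export
write_edf <- function(rec, path, physical_dim = "uV") {
  stopifnot(inherits(rec, "sensor_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate per 1-s record")
  }
  fs <- as.integer(round(fs))
  data <- rec$data
  nch <- nrow(data)
  n <- ncol(data)
  nrec <- as.integer(ceiling(n / fs))
  if (nrec * fs > n) {
    data <- cbind(data, matrix(0, nch, nrec * fs - n))
  }
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate 01-JAN-2000 X X X", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256L * (1L + nch), 8)
  wr("", 44)
  wr(nrec, 8)
  wr(1L, 8)                      # record duration, seconds
  wr(nch, 4)
  for (f in list(
    list(rec$channels, 16), list(rep("", nch), 80),
    list(rep(physical_dim, nch), 8),
    list(formatC(pmin_, format = "g", digits = 7), 8),
    list(formatC(pmax_, format = "g", digits = 7), 8),
    list(rep(dmin, nch), 8), list(rep(dmax, nch), 8),
    list(rep("", nch), 80), list(rep(fs, nch), 8), list(rep("", nch), 32)
  )) {
    for (v in f[[1L]]) wr(v, f[[2L]])
  }
  # re-read the header's printed physical range so scaling matches exactly
  pmin_h <- as.numeric(formatC(pmin_, format = "g", digits = 7))
  pmax_h <- as.numeric(formatC(pmax_, format = "g", digits = 7))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((data[ch, idx] - pmin_h[ch]) / gain[ch]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param spike_times optional spike event times (s) to attach; see
#'   [read_events()].
#' @return A [sensor_recording()] (spike times empty unless supplied).
#' @export
read_edf <- function(path, spike_times = numeric(0)) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file (version '", version, "'): ", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  field <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- field(16)
  field(80)
  field(8)                                # physical dimension
  pmin_ <- as.numeric(field(8))
  pmax_ <- as.numeric(field(8))
  dmin <- as.numeric(field(8))
  dmax <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))             # samples per record
  field(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF reader requires identical sampling rate on all channels")
  }
  fs <- spr[1L] / recdur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, nch, nrec * spr[1L])
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = nch * spr[1L], size = 2L,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1L], ncol = nch)
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    data[, idx] <- t((block - matrix(dmin, spr[1L], nch, byrow = TRUE)) *
                       matrix(gain, spr[1L], nch, byrow = TRUE) +
                       matrix(pmin_, spr[1L], nch, byrow = TRUE))
  }
  sensor_recording(data, fs, spike_times = spike_times, channels = labels)
}
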