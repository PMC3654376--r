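#' Classical EEG frequency bands over integer 1-70 Hz bins
#'
#' The band table maps each integer frequency bin to one of delta, theta,
#' alpha, beta, gamma. Shared boundary frequencies (4, 8, 13, 30 Hz) belong
#' to the upper band (half-open lower bands); delta starts at 1 Hz because
#' the analysis range is 1-70 Hz, and gamma's top (70 Hz) is included.
#'
#' @return A data.frame with columns `band`, `fmin`, `fmax` (inclusive bin
#'   range in Hz).
#' @export
band_table <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    fmin = c(1, 4, 8, 13, 30),
    fmax = c(3, 7, 12, 29, 70)
  )
}

band_of_freq <- function(freqs, bands = band_table()) {
  out <- rep(NA_character_, length(freqs))
  for (i in seq_len(nrow(bands))) {
    out[freqs >= bands$fmin[i] & freqs <= bands$fmax[i]] <- bands$band[i]
  }
  factor(out, levels = bands$band)
}

#' Number of unordered signal pairs
#'
#' `(n^2 - n) / 2` -- the number of distinct coherence comparisons among n
#' signals (e.g. 2,878,800 for 2400 cortical patches, 3160 for 80 parcels).
#'
#' @param n number of signals (>= 1).
#' @return Integer-valued numeric count.
#' @export
pair_count <- function(n) {
  stopifnot(all(n >= 1))
  (n^2 - n) / 2
}

#' Average source waveforms within parcels
#'
#' Parcel waveforms are the arithmetic mean of the *signed* member-patch
#' waveforms at every sample. Note the documented hazard: patches whose
#' oriented waveforms are in antiphase (e.g. opposite walls of a sulcus)
#' cancel in the mean.
#'
#' @param J patches x samples matrix, or patches x samples x epochs array.
#' @param parcel_map a data.frame with columns `patch_id`, `parcel`,
#'   `hemisphere`, or a character vector of parcel labels indexed by patch.
#' @return parcels x samples matrix (or x epochs array) with rownames the
#'   parcel labels and attribute `hemisphere` (named by parcel). Parcels not
#'   backed by any patch are dropped with a warning.
#' @export
average_by_parcel <- function(J, parcel_map) {
  pm <- normalize_parcel_map(parcel_map)
  was_matrix <- length(dim(J)) == 2L
  if (was_matrix) J <- array(J, dim = c(dim(J), 1L))
  np <- dim(J)[1L]
  if (nrow(pm) != np) {
    stop("parcel map covers ", nrow(pm), " patches but J has ", np)
  }
  labs <- levels(factor(pm$parcel))
  present <- labs[labs %in% pm$parcel]
  if (length(present) < length(labs)) {
    warning("empty parcel(s) excluded: ",
            paste(setdiff(labs, present), collapse = ", "))
  }
  idx <- split(seq_len(np), pm$parcel)
  flat <- matrix(J, np)                       # patches x (samples * epochs)
  sums <- rowsum(flat, group = pm$parcel)     # ordered by parcel label
  means <- sums / lengths(idx)[rownames(sums)]
  out <- array(means[names(idx), , drop = FALSE],
               dim = c(length(idx), dim(J)[2L], dim(J)[3L]),
               dimnames = list(names(idx), NULL, NULL))
  hemi <- vapply(idx, function(rows) pm$hemisphere[rows[1L]], "")
  attr(out, "hemisphere") <- hemi
  if (was_matrix) {
    m <- out[, , 1L, drop = FALSE]
    dim(m) <- dim(out)[1:2]
    rownames(m) <- names(idx)
    attr(m, "hemisphere") <- hemi
    return(m)
  }
  out
}

normalize_parcel_map <- function(parcel_map) {
  if (is.character(parcel_map) || is.factor(parcel_map)) {
    parcel_map <- data.frame(
      patch_id = seq_along(parcel_map),
      parcel = as.character(parcel_map),
      hemisphere = ifelse(grepl("_R$", parcel_map), "right", "left")
    )
  }
  need <- c("patch_id", "parcel", "hemisphere")
  if (!all(need %in% names(parcel_map))) {
    stop("parcel map needs columns ", paste(need, collapse = ", "))
  }
  parcel_map <- parcel_map[order(parcel_map$patch_id), , drop = FALSE]
  if (!identical(as.integer(parcel_map$patch_id),
                 seq_len(nrow(parcel_map)))) {
    stop("parcel map must cover every patch id 1..n exactly once")
  }
  parcel_map
}

# FFT of demeaned epochs restricted to the analysis bins.
# x: samples x epochs. Returns complex bins x epochs plus the bin frequencies.
epoch_fft <- function(x, fs, fmin = 1, fmax = 70) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("epoch shorter than 2 samples")
  df <- fs / n
  nyq <- fs / 2
  if (fmax > nyq) {
    stop("requested bins up to ", fmax, " Hz exceed the Nyquist frequency (",
         nyq, " Hz)")
  }
  target <- seq(fmin, fmax, by = 1)
  bins <- round(target / df) + 1L
  bins <- pmin(pmax(bins, 2L), n)
  freqs <- (bins - 1L) * df
  x <- sweep(x, 2L, colMeans(x), "-")
  X <- mvfft(x)
  list(X = X[bins, , drop = FALSE], freq = freqs, df = df)
}

#' Cross-spectral densities on the integer-Hz grid
#'
#' Per epoch the signals are demeaned and Fourier transformed (rectangular
#' window, so a 1-s epoch gives exactly 1 Hz bin spacing); the raw cross-
#' periodograms `X(f) conj(Y(f))` are then averaged across epochs. Bins are
#' restricted to `fmin`-`fmax` Hz (default 1-70).
#'
#' @param x,y samples x epochs matrices (equal dimensions); vectors are
#'   treated as single epochs.
#' @param fs sampling rate in Hz.
#' @param fmin,fmax analysis frequency range (Hz).
#' @return List with `freq` (Hz), `Sxx`, `Syy` (real), `Sxy` (complex), and
#'   `n_epochs`.
#' @export
cross_spectra <- function(x, y, fs, fmin = 1, fmax = 70) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("x and y must have identical dimensions")
  fx <- epoch_fft(x, fs, fmin, fmax)
  fy <- epoch_fft(y, fs, fmin, fmax)
  M <- ncol(x)
  list(
    freq = fx$freq,
    Sxx = rowMeans(Mod(fx$X)^2),
    Syy = rowMeans(Mod(fy$X)^2),
    Sxy = rowMeans(fx$X * Conj(fy$X)),
    n_epochs = M
  )
}

#' Magnitude coherence from cross-spectral densities
#'
#' `|S_XY(f)| / sqrt(S_XX(f) S_YY(f))`: the standardised cross-spectral
#' density, i.e. the frequency-domain analogue of a correlation coefficient,
#' in `[0, 1]`. Bins whose power product falls below `tol` (relative to the
#' largest product) are undefined and returned as `NA`. With a single epoch
#' the estimator is identically 1 at every defined bin; a warning reminds
#' that at least two epochs are needed for a meaningful estimate.
#'
#' @param Sxx,Syy,Sxy spectra as from [cross_spectra()], or a list with those
#'   elements as the first argument.
#' @param n_epochs number of epochs averaged (for the single-epoch warning;
#'   taken from the list input when present).
#' @param tol relative power tolerance for defined bins (default `1e-14`).
#' @return Numeric vector of coherences in `[0, 1]` (NA = undefined bin).
#' @export
coherence <- function(Sxx, Syy = NULL, Sxy = NULL, n_epochs = NULL,
                      tol = 1e-14) {
  if (is.list(Sxx)) {
    sl <- Sxx
    Sxx <- sl$Sxx
    Syy <- sl$Syy
    Sxy <- sl$Sxy
    if (is.null(n_epochs)) n_epochs <- sl$n_epochs
  }
  if (any(Sxx < 0, na.rm = TRUE) || any(Syy < 0, na.rm = TRUE)) {
    stop("autospectra must be non-negative")
  }
  if (!is.null(n_epochs) && n_epochs < 2L) {
    warning("coherence from a single epoch is identically 1; use >= 2 ",
            "epochs for a meaningful estimate")
  }
  prod <- Sxx * Syy
  defined <- is.finite(prod) & prod > tol * max(prod, na.rm = TRUE)
  out <- rep(NA_real_, length(Sxx))
  out[defined] <- Mod(Sxy[defined]) / sqrt(prod[defined])
  # clip harmless floating-point overshoot
  over <- which(out > 1)
  if (length(over)) {
    if (any(out[over] > 1 + 1e-12)) {
      warning("coherence exceeded 1 beyond floating-point tolerance")
    }
    out[over] <- 1
  }
  out
}

#' Band-average coherence
#'
#' Unweighted mean of the per-bin coherence over the member bins of each
#' band in [band_table()]. Bands with no defined bin are `NA`.
#'
#' @param coh numeric coherence per bin.
#' @param freq bin frequencies in Hz (same length).
#' @param bands a band table as from [band_table()].
#' @return Named numeric vector, one value per band.
#' @export
band_average <- function(coh, freq, bands = band_table()) {
  stopifnot(length(coh) == length(freq))
  b <- band_of_freq(freq, bands)
  out <- setNames(rep(NA_real_, nrow(bands)), bands$band)
  for (bb in bands$band) {
    v <- coh[!is.na(b) & b == bb]
    if (any(!is.na(v))) out[bb] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Coherence matrices among parcel waveforms
#'
#' Estimates the full symmetric parcel x parcel magnitude-coherence matrix
#' per integer frequency bin (1-70 Hz by default) and per classical band,
#' for each analysis interval. Cross-spectra are averaged across the spike
#' epochs of the cluster; the magnitude of the complex mean cross-spectrum
#' is then standardised by the mean autospectra.
#'
#' Parcel ordering follows the conventional quadrant layout: all
#' right-hemisphere parcels first (sorted by label), then left, so the
#' intra-right block occupies the upper-left quadrant of the matrix.
#'
#' @param parcel_epochs either a list with elements `pre`, `spike`, `post`,
#'   each a parcels x samples x epochs array (as produced by
#'   [average_by_parcel()] on [carve_intervals()] output), or a single such
#'   array (treated as one unnamed interval).
#' @param fs sampling rate in Hz.
#' @param hemisphere named character vector (by parcel label); defaults to
#'   the `hemisphere` attribute of the arrays.
#' @param fmin,fmax frequency range in Hz.
#' @param bands band definition table.
#' @return An object of class `coherence_result`: list with `parcels`
#'   (ordered labels), `hemisphere`, `freq`, `intervals` (a named list; per
#'   interval `coh` is parcels x parcels x freq, `band` parcels x parcels x
#'   5, `n_epochs`), and `bands`.
#' @export
coherence_matrix <- function(parcel_epochs, fs, hemisphere = NULL,
                             fmin = 1, fmax = 70, bands = band_table()) {
  if (is.array(parcel_epochs) || length(dim(parcel_epochs)) == 3L) {
    parcel_epochs <- list(all = parcel_epochs)
  }
  first <- parcel_epochs[[1L]]
  if (is.null(hemisphere)) hemisphere <- attr(first, "hemisphere")
  labs <- dimnames(first)[[1L]]
  if (is.null(labs)) labs <- sprintf("P%02d", seq_len(dim(first)[1L]))
  if (is.null(hemisphere)) {
    hemisphere <- setNames(ifelse(grepl("_R$", labs), "right", "left"), labs)
  }
  if (dim(first)[1L] < 2L) stop("need at least 2 parcels")
  ord <- order(match(hemisphere[labs], c("right", "left")), labs)
  labs_o <- labs[ord]

  intervals <- lapply(parcel_epochs, function(arr) {
    if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
    P <- dim(arr)[1L]
    M <- dim(arr)[3L]
    if (P != length(labs)) stop("mismatched parcel count across intervals")
    if (M < 2L) {
      warning("coherence from ", M, " epoch(s) is degenerate (identically ",
              "1); use >= 2 epochs")
    }
    arr <- arr[ord, , , drop = FALSE]
    n <- dim(arr)[2L]
    # bins x parcels x epochs complex spectrum
    flat <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = n)
    ft <- epoch_fft(flat, fs, fmin, fmax)
    nf <- length(ft$freq)
    Z <- array(ft$X, dim = c(nf, P, M))
    coh <- array(NA_real_, dim = c(P, P, nf),
                 dimnames = list(labs_o, labs_o, NULL))
    for (f in seq_len(nf)) {
      Zf <- matrix(Z[f, , ], P, M)
      S <- (Zf %*% Conj(t(Zf))) / M
      pw <- Re(diag(S))
      den <- sqrt(outer(pw, pw))
      cm <- Mod(S) / den
      bad <- outer(pw, pw) <= 1e-14 * max(pw)^2
      cm[bad] <- NA_real_
      cm[cm > 1] <- 1
      diag(cm) <- 1
      coh[, , f] <- cm
    }
    bnd <- array(NA_real_, dim = c(P, P, nrow(bands)),
                 dimnames = list(labs_o, labs_o, bands$band))
    bf <- band_of_freq(ft$freq, bands)
    for (bi in seq_len(nrow(bands))) {
      sel <- which(!is.na(bf) & bf == bands$band[bi])
      if (length(sel)) {
        bnd[, , bi] <- apply(coh[, , sel, drop = FALSE], c(1L, 2L),
                             mean, na.rm = TRUE)
      }
    }
    list(coh = coh, band = bnd, n_epochs = M, freq = ft$freq, df = ft$df)
  })

  structure(
    list(parcels = labs_o,
         hemisphere = hemisphere[labs_o],
         freq = intervals[[1L]]$freq,
         intervals = intervals,
         bands = bands),
    class = "coherence_result"
  )
}

#' Extract the K strongest coherence edges
#'
#' Selects the k largest off-diagonal (upper-triangle) entries of the band
#' coherence matrices, by default separately within each band (`per_band =
#' TRUE`), sorted in descending order. Ties are broken deterministically by
#' band order, then parcel indices. If fewer than k pairs exist, all are
#' returned.
#'
#' @param result a [coherence_matrix()] result.
#' @param k number of edges (default 100).
#' @param interval interval name (default the first).
#' @param per_band select top-k within each band (default) or pooled across
#'   bands.
#' @return A data.frame `(interval, band, parcel_a, parcel_b, coherence)`.
#' @export
top_k_edges <- function(result, k = 100, interval = NULL, per_band = TRUE) {
  stopifnot(inherits(result, "coherence_result"), k >= 1)
  if (is.null(interval)) interval <- names(result$intervals)[1L]
  iv <- result$intervals[[interval]]
  if (is.null(iv)) stop("unknown interval: ", interval)
  P <- length(result$parcels)
  ut <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  rows <- do.call(rbind, lapply(seq_len(dim(iv$band)[3L]), function(bi) {
    data.frame(
      interval = interval,
      band = dimnames(iv$band)[[3L]][bi],
      band_order = bi,
      a = ut[, 1L], b = ut[, 2L],
      coherence = iv$band[cbind(ut, bi)]
    )
  }))
  rows <- rows[!is.na(rows$coherence), , drop = FALSE]
  rows <- rows[order(-rows$coherence, rows$band_order, rows$a, rows$b), ,
               drop = FALSE]
  if (per_band) {
    rows <- do.call(rbind, lapply(split(rows, rows$band_order), function(d) {
      head(d, k)
    }))
    rows <- rows[order(rows$band_order, -rows$coherence, rows$a, rows$b), ,
                 drop = FALSE]
  } else {
    rows <- head(rows, k)
  }
  data.frame(
    interval = rows$interval,
    band = rows$band,
    parcel_a = result$parcels[rows$a],
    parcel_b = result$parcels[rows$b],
    coherence = rows$coherence,
    row.names = NULL
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("Parcel coherence result\n")
  cat(sprintf("  %d parcels (%d right / %d left), %d frequency bins (%.3g-",
              length(x$parcels), sum(x$hemisphere == "right"),
              sum(x$hemisphere == "left"), length(x$freq), min(x$freq)))
  cat(sprintf("%.3g Hz, spacing %.3g Hz)\n", max(x$freq),
              x$intervals[[1L]]$df))
  for (nm in names(x$intervals)) {
    iv <- x$intervals[[nm]]
    off <- iv$band[upper.tri(iv$band[, , 1L])]
    cat(sprintf("  %-6s: %d epochs, mean band coherence %.3f\n",
                nm, iv$n_epochs,
                mean(as.numeric(iv$band), na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.coherence_result <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$intervals), function(nm) {
    iv <- object$intervals[[nm]]
    P <- dim(iv$band)[1L]
    ut <- upper.tri(matrix(0, P, P))
    vals <- apply(iv$band, 3L, function(m) mean(m[ut], na.rm = TRUE))
    data.frame(interval = nm, band = names(vals),
               mean_offdiag = as.numeric(vals), n_epochs = iv$n_epochs)
  }))
  class(tab) <- c("summary.coherence_result", "data.frame")
  tab
}

#' Heatmap of a band coherence matrix
#'
#' Plots one interval x band slice as an image with the quadrant layout
#' (right hemisphere upper-left), hemisphere separators and a sequential
#' palette.
#'
#' @param x a `coherence_result`.
#' @param interval interval name (default first).
#' @param band band name (default `"alpha"`).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.coherence_result <- function(x, interval = NULL, band = "alpha", ...) {
  if (is.null(interval)) interval <- names(x$intervals)[1L]
  m <- x$intervals[[interval]]$band[, , band]
  P <- nrow(m)
  pal <- hcl.colors(64, "YlOrRd", rev = TRUE)
  # row 1 at the top so the first (right-hemisphere) parcels are upper-left
  image(seq_len(P), seq_len(P), t(m[P:1, , drop = FALSE]),
        col = pal, zlim = c(0, 1), axes = FALSE,
        xlab = "", ylab = "", ...)
  title(sprintf("%s interval, %s band", interval, band))
  nR <- sum(x$hemisphere == "right")
  if (nR > 0 && nR < P) {
    abline(v = nR + 0.5, h = P - nR + 0.5, lwd = 2)
  }
  axis(1L, at = seq_len(P), labels = x$parcels, las = 2, cex.axis = 0.5)
  axis(2L, at = seq_len(P), labels = rev(x$parcels), las = 2, cex.axis = 0.5)
  box()
  invisible(m)
}

#' Write coherence matrices and edge lists to TSV
#'
#' Writes one TSV per interval x band (`<stem>_<interval>_<band>.tsv`,
#' parcel labels as header), the band mapping table
#' (`<stem>_bands.tsv`), and the top-k edge list (`<stem>_edges.tsv`).
#'
#' @param result a `coherence_result`.
#' @param stem output path stem.
#' @param k top-k edges per band and interval.
#' @return Invisibly, the files written.
#' @export
write_coherence <- function(result, stem, k = 100) {
  files <- character(0)
  for (nm in names(result$intervals)) {
    iv <- result$intervals[[nm]]
    for (bb in dimnames(iv$band)[[3L]]) {
      f <- sprintf("%s_%s_%s.tsv", stem, nm, bb)
      m <- iv$band[, , bb]
      write.table(cbind(parcel = rownames(m), as.data.frame(m)),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
  }
  fb <- paste0(stem, "_bands.tsv")
  write.table(result$bands, fb, sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- do.call(rbind, lapply(names(result$intervals), function(nm) {
    top_k_edges(result, k = k, interval = nm)
  }))
  fe <- paste0(stem, "_edges.tsv")
  write.table(edges, fe, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, fb, fe))
}
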