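#' Construct an epoch set
#'
#' Container for fixed-length multichannel signal epochs: a 3-D array
#' `[epoch, channel, sample]` plus sampling rate, montage and band label.
#' One-second stationary epochs are the unit on which pairwise mutual
#' information is estimated.
#'
#' @param data numeric array `epochs x channels x samples` (microvolts).
#' @param fs sampling frequency in Hz.
#' @param montage montage data.frame; channel order must match `dim(data)[2]`.
#' @param band band label (`"broadband"`, `"delta"`, ..., `"gamma"`).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, montage = montage_1020(), band = "broadband") {
  if (length(dim(data)) != 3L) stop_arg("data must be a 3-D array [epoch, channel, sample]")
  if (dim(data)[2] != nrow(montage)) {
    stop_arg("channel count (", dim(data)[2], ") does not match montage (",
             nrow(montage), ")")
  }
  structure(list(data = data, fs = fs, montage = montage, band = band),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz [%s]\n",
              d[1], d[2], d[3], x$fs, x$band))
  invisible(x)
}

n_epochs <- function(e) dim(e$data)[1]

#' Canonical frequency band definitions
#'
#' Broadband 1-70 Hz and the five named bands: delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-32) and gamma (32-70 Hz).
#'
#' @return named list of `c(low, high)` in Hz.
#' @export
band_definitions <- function() {
  list(broadband = c(1, 70), delta = c(1, 4), theta = c(4, 8),
       alpha = c(8, 13), beta = c(13, 32), gamma = c(32, 70))
}

#' Broadband filter a continuous recording
#'
#' Zero-phase band-pass (windowed-sinc FIR, applied forward-backward) from
#' `low` to `high` Hz, followed by a zero-phase Butterworth notch around
#' `notch` Hz to remove line noise, then per-channel mean removal. Zero-phase
#' filtering is deliberate: phase-randomization surrogates assume no filter
#' phase distortion.
#'
#' The channels are reflection-padded so the filters reach steady state
#' inside the recording; a residual transient of roughly one filter length
#' (`fir_order` samples, about one second) at each recording edge is
#' unavoidable for the narrow notch, so epochs should be drawn away from the
#' recording edges.
#'
#' @param raw numeric matrix `channels x samples`.
#' @param fs sampling frequency (Hz), default 200.
#' @param low,high band edges in Hz (default 1 and 70).
#' @param notch line frequency (Hz, default 60); `NA` disables the notch.
#' @param fir_order FIR order (default 200, i.e. one second at 200 Hz).
#' @return filtered matrix of the same dimensions.
#' @export
broadband_filter <- function(raw, fs = 200, low = 1, high = 70, notch = 60,
                             fir_order = 200) {
  raw <- as.matrix(raw)
  if (high >= fs / 2) {
    stop_arg("sampling rate ", fs, " Hz too low for a ", high, " Hz band edge")
  }
  if (ncol(raw) < 3 * (fir_order + 1)) {
    stop_arg("recording too short for filter warm-up (need >= ",
             3 * (fir_order + 1), " samples, got ", ncol(raw), ")")
  }
  # filtfilt zero-pads, which leaves large transients at the recording
  # edges; reflect-pad each channel (even reflection: no spurious DC) with
  # two filter lengths so the zero-append transient cannot reach the kept
  # samples, and trim the pad after filtering. A transient of roughly one
  # filter length (~1 s) at each recording edge remains unavoidable for the
  # narrow notch and is documented; epochs are drawn from the interior.
  pad <- 2 * (fir_order + 1)
  reflect_filt <- function(x, f) {
    n <- length(x)
    xp <- c(rev(x[seq_len(pad) + 1]), x, x[n - seq_len(pad)])
    signal::filtfilt(f, xp)[pad + seq_len(n)]
  }
  h <- signal::fir1(fir_order, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(raw, 1, reflect_filt, f = h))
  if (!is.na(notch)) {
    bs <- signal::butter(2, c(notch - 2, notch + 2) / (fs / 2), type = "stop")
    out <- t(apply(out, 1, reflect_filt, f = bs))
  }
  out - rowMeans(out)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' channel mean is zero at each time point. Idempotent; rejects any signal
#' component common to all channels.
#'
#' @param x `epoch_set` or a `channels x samples` matrix.
#' @return object of the same type, average-referenced.
#' @export
average_rereference <- function(x) {
  if (inherits(x, "epoch_set")) {
    d <- x$data
    ch_mean <- apply(d, c(1, 3), mean)          # epochs x samples
    for (c in seq_len(dim(d)[2])) d[, c, ] <- d[, c, ] - ch_mean
    x$data <- d
    x
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 2) stop_arg("average reference needs >= 2 channels")
    sweep(x, 2, colMeans(x))
  }
}

#' Segment a recording into artifact-free epochs
#'
#' Cuts the recording into non-overlapping windows of `epoch_seconds`, drops
#' windows whose peak absolute deviation from the channel median exceeds
#' `reject_z` robust standard deviations (MAD) on any channel, and selects
#' `n_epochs` survivors uniformly at random under `seed`. This automated
#' amplitude rule stands in for visual artifact screening; a manual keep-list
#' can be supplied via `keep`.
#'
#' @param raw numeric matrix `channels x samples`.
#' @param fs sampling frequency in Hz.
#' @param n_epochs number of epochs to select (study default 300).
#' @param reject_z robust-amplitude rejection threshold in MADs (default 6).
#' @param seed RNG seed for the random selection.
#' @param epoch_seconds epoch duration (default 1 s).
#' @param montage montage for the resulting epoch set.
#' @param band band label carried on the result.
#' @param keep optional integer vector of window indices to restrict to
#'   (bypasses the amplitude rule).
#' @return an [epoch_set()]; attribute `windows` holds the selected window
#'   indices.
#' @export
segment_and_select <- function(raw, fs, n_epochs, reject_z = 6, seed = 1,
                               epoch_seconds = 1, montage = montage_1020(),
                               band = "broadband", keep = NULL) {
  raw <- as.matrix(raw)
  wlen <- round(fs * epoch_seconds)
  n_win <- floor(ncol(raw) / wlen)
  if (n_win < 1) stop_arg("recording shorter than one epoch")
  if (is.null(keep)) {
    med <- apply(raw, 1, median)
    rsd <- apply(raw, 1, mad)
    rsd[rsd == 0] <- .Machine$double.eps
    ok <- vapply(seq_len(n_win), function(w) {
      seg <- raw[, ((w - 1) * wlen + 1):(w * wlen), drop = FALSE]
      peaks <- apply(abs(seg - med), 1, max)
      all(peaks <= reject_z * rsd)
    }, logical(1))
    survivors <- which(ok)
  } else {
    survivors <- intersect(keep, seq_len(n_win))
  }
  if (length(survivors) < n_epochs) {
    stop_arg("only ", length(survivors), " artifact-free epochs available, ",
             n_epochs, " requested")
  }
  sel <- sort(with_seed(seed, sample(survivors, n_epochs)))
  arr <- array(0, dim = c(n_epochs, nrow(raw), wlen))
  for (k in seq_along(sel)) {
    arr[k, , ] <- raw[, ((sel[k] - 1) * wlen + 1):(sel[k] * wlen)]
  }
  es <- epoch_set(arr, fs = fs, montage = montage, band = band)
  attr(es, "windows") <- sel
  es
}

#' Band-filter an epoch set
#'
#' Decomposes 1-second epochs into a named frequency band by zero-phase
#' spectral masking (FFT bins outside `[low, high]` Hz zeroed, DC removed).
#' Spectral masking is used instead of an FIR because a one-second epoch is
#' too short for a windowed-sinc filter with a delta-band transition width.
#'
#' @param epochs an [epoch_set()].
#' @param band band name from [band_definitions()] or a `list(name, low, high)`.
#' @return band-labelled `epoch_set`.
#' @export
band_filter <- function(epochs, band) {
  if (is.character(band)) {
    defs <- band_definitions()
    if (!band %in% names(defs)) stop_arg("unknown band: ", band)
    spec <- list(name = band, low = defs[[band]][1], high = defs[[band]][2])
  } else {
    spec <- band
  }
  if (spec$low >= spec$high) stop_arg("band low must be < high")
  bb <- band_definitions()$broadband
  if (spec$low < bb[1] || spec$high > bb[2]) {
    stop_arg("band ", spec$low, "-", spec$high,
             " Hz outside the broadband range ", bb[1], "-", bb[2], " Hz")
  }
  d <- epochs$data
  ns <- dim(d)[3]
  freqs <- (seq_len(ns) - 1) * epochs$fs / ns
  freqs <- pmin(freqs, epochs$fs - freqs)   # two-sided
  mask <- freqs >= spec$low & freqs <= spec$high
  flat <- matrix(aperm(d, c(3, 1, 2)), nrow = ns)  # samples x (epochs*channels)
  ft <- stats::mvfft(flat)
  ft[!mask, ] <- 0
  flat2 <- Re(stats::mvfft(ft, inverse = TRUE)) / ns
  d2 <- aperm(array(flat2, dim = c(ns, dim(d)[1], dim(d)[2])), c(2, 3, 1))
  out <- epochs
  out$data <- d2
  out$band <- spec$name
  out
}
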