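# Minimal European Data Format (EDF) support: enough of the standard to
# round-trip multichannel EEG matrices (16-bit samples, 1-second data
# records, one scaling per channel). Not a general-purpose EDF library: no
# annotations, no discontinuous records.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a signal matrix as an EDF file
#'
#' Samples are scaled per channel to the 16-bit digital range, so values
#' round-trip to within about `(max - min) / 65535` per channel.
#'
#' @param mat numeric matrix `channels x samples` (microvolts).
#' @param path output file.
#' @param fs sampling frequency (Hz); must divide the sample count.
#' @param channel_names channel labels (default from rownames or montage).
#' @param patient_id,recording_id free-text header fields.
#' @export
write_edf <- function(mat, path, fs, channel_names = rownames(mat),
                      patient_id = "X", recording_id = "synthetic") {
  mat <- as.matrix(mat)
  nc <- nrow(mat)
  if (is.null(channel_names)) channel_names <- montage_1020()$channel[seq_len(nc)]
  n_rec <- floor(ncol(mat) / fs)
  if (n_rec < 1) stop_arg("recording shorter than one 1-second record")
  mat <- mat[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(mat, 1, min)
  pmax_ <- apply(mat, 1, max)
  pmax_[pmax_ == pmin_] <- pmin_[pmax_ == pmin_] + 1
  dmin <- -32768; dmax <- 32767
  header_bytes <- 256 + 256 * nc
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(x, width) writeChar(paste0(vapply(x, edf_pad, "", width),
                                             collapse = ""), con,
                                      eos = NULL)
  put("0", 8); put(patient_id, 80); put(recording_id, 80)
  put("01.01.20", 8); put("00.00.00", 8)
  put(header_bytes, 8); put("", 44); put(n_rec, 8); put("1", 8); put(nc, 4)
  put(channel_names, 16)
  put(rep("", nc), 80)                       # transducer
  put(rep("uV", nc), 8)                      # physical dimension
  put(sprintf("%.6g", pmin_), 8); put(sprintf("%.6g", pmax_), 8)
  put(rep(dmin, nc), 8); put(rep(dmax, nc), 8)
  put(rep("", nc), 80)                       # prefiltering
  put(rep(fs, nc), 8)                        # samples per record
  put(rep("", nc), 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (c in seq_len(nc)) {
      dig <- round((mat[c, cols] - pmin_[c]) / gain[c] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @return `read_edf`: list with `data` (channels x samples matrix, labelled),
#'   `fs`, `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  grab <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  grab(8); grab(80); grab(80); grab(8); grab(8)
  grab(8)  # header bytes
  grab(44)
  n_rec <- as.integer(grab(8))
  rec_dur <- as.numeric(grab(8))
  nc <- as.integer(grab(4))
  labels <- vapply(seq_len(nc), function(i) grab(16), "")
  for (i in seq_len(nc)) grab(80)
  for (i in seq_len(nc)) grab(8)
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(grab(8)), 0)
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(grab(8)), 0)
  dmin <- vapply(seq_len(nc), function(i) as.numeric(grab(8)), 0)
  dmax <- vapply(seq_len(nc), function(i) as.numeric(grab(8)), 0)
  for (i in seq_len(nc)) grab(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(grab(8)), 0L)
  for (i in seq_len(nc)) grab(32)
  out <- matrix(0, nc, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (c in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[c], size = 2, signed = TRUE,
                     endian = "little")
      out[c, ((r - 1) * spr[c] + 1):(r * spr[c])] <-
        (dig - dmin[c]) * gain[c] + pmin_[c]
    }
  }
  rownames(out) <- labels
  list(data = out, fs = spr[1] / rec_dur, channel_names = labels)
}
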