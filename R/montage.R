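#' Standard 19-channel 10-20 scalp montage
#'
#' Returns the 19-electrode international 10-20 layout used throughout the
#' package, with schematic 2-D head coordinates (head radius 1), a
#' paramedian/lateral region class per channel, and hemisphere labels.
#'
#' The paramedian class covers the midline electrodes (Fz, Cz, Pz) and their
#' immediate parasagittal neighbours (F3/F4, C3/C4, P3/P4); the remaining ten
#' electrodes (frontopolar, inferior frontal, temporal and occipital) are
#' lateral. Hub-shift summaries count hubs by this dichotomy.
#'
#' @return data.frame with columns `channel`, `x`, `y`, `region`
#'   (`"paramedian"`/`"lateral"`), `hemisphere` (`"left"`/`"midline"`/`"right"`).
#' @export
#' @examples
#' m <- montage_1020()
#' table(m$region)
montage_1020 <- function() {
  ch <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
          "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  x <- c(-0.31, 0.31, -0.81, -0.40, 0, 0.40, 0.81, -1, -0.5, 0,
         0.5, 1, -0.81, -0.40, 0, 0.40, 0.81, -0.31, 0.31)
  y <- c(0.95, 0.95, 0.59, 0.52, 0.50, 0.52, 0.59, 0, 0, 0,
         0, 0, -0.59, -0.52, -0.50, -0.52, -0.59, -0.95, -0.95)
  paramedian <- c("Fz", "Cz", "Pz", "F3", "F4", "C3", "C4", "P3", "P4")
  region <- ifelse(ch %in% paramedian, "paramedian", "lateral")
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", ch)))
  hemisphere <- ifelse(grepl("z$", ch), "midline",
                       ifelse(num %% 2 == 1, "left", "right"))
  data.frame(channel = ch, x = x, y = y, region = region,
             hemisphere = hemisphere, stringsAsFactors = FALSE)
}

#' @rdname montage_1020
#' @export
paramedian_channels <- function() {
  m <- montage_1020()
  m$channel[m$region == "paramedian"]
}

#' @rdname montage_1020
#' @export
lateral_channels <- function() {
  m <- montage_1020()
  m$channel[m$region == "lateral"]
}

#' Homologous interhemispheric lateral channel pairs
#'
#' Left/right mirror pairs among the lateral electrodes (Fp1-Fp2, F7-F8,
#' T3-T4, T5-T6, O1-O2). These are the interhemispheric connections whose
#' post-operative strengthening the difference networks are inspected for.
#'
#' @return two-column character matrix of channel names.
#' @export
homologous_lateral_pairs <- function() {
  cbind(c("Fp1", "F7", "T3", "T5", "O1"),
        c("Fp2", "F8", "T4", "T6", "O2"))
}

# Alternative electrode nomenclature accepted on input.
channel_aliases <- function() {
  c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
}

#' Match channel labels to the montage order
#'
#' Case-insensitive matching with the common modified-combinatorial aliases
#' (T7->T3, T8->T4, P7->T5, P8->T6). Errors naming any label that cannot be
#' matched.
#'
#' @param labels character vector of channel labels from a recording.
#' @param montage montage data.frame (default [montage_1020()]).
#' @return integer index such that `labels[idx]` is in montage order.
#' @export
match_channels <- function(labels, montage = montage_1020()) {
  canon <- function(v) toupper(trimws(v))
  lab <- canon(labels)
  al <- channel_aliases()
  hit <- match(lab, canon(names(al)))
  lab[!is.na(hit)] <- canon(al[hit[!is.na(hit)]])
  idx <- match(canon(montage$channel), lab)
  if (anyNA(idx)) {
    stop_arg("channels absent from input: ",
             paste(montage$channel[is.na(idx)], collapse = ", "))
  }
  idx
}
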