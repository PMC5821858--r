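#' Write an adjacency matrix as CSV
#'
#' Square matrix with a channel-name header row and a leading channel column.
#'
#' @param adj adjacency matrix with channel dimnames.
#' @param path output file.
#' @export
write_adjacency_csv <- function(adj, path) {
  w <- unclass(as.matrix(adj))
  df <- data.frame(channel = rownames(w), w, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @param level,session,band metadata attached to the matrix read back.
#' @export
read_adjacency_csv <- function(path, level = "patient",
                               session = NA_character_, band = "broadband") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  storage.mode(w) <- "double"
  adjacency_matrix(w, level = level, session = session, band = band)
}

#' Write a network in Pajek .net format
#'
#' Undirected weighted network: a `*Vertices` block with channel names and
#' 2-D montage coordinates, then a `*Edges` block with one weighted edge per
#' nonzero channel pair. Weights are printed with 10 significant digits so a
#' write-read-write round trip is byte-identical.
#'
#' @param adj adjacency matrix with channel dimnames.
#' @param path output file.
#' @param montage montage supplying the coordinates.
#' @export
write_pajek <- function(adj, path, montage = montage_1020()) {
  w <- unclass(as.matrix(adj))
  n <- nrow(w)
  nm <- rownames(w) %||% as.character(seq_len(n))
  mi <- match(nm, montage$channel)
  lines <- c(sprintf("*Vertices %d", n),
             sprintf("%d \"%s\" %.6f %.6f", seq_len(n), nm,
                     ifelse(is.na(mi), 0, montage$x[mi]),
                     ifelse(is.na(mi), 0, montage$y[mi])),
             "*Edges")
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    lines <- c(lines, sprintf("%d %d %.10g", idx[, 1], idx[, 2],
                              w[idx]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pajek
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  vstart <- grep("^\\*Vertices", lines)
  estart <- grep("^\\*Edges", lines)
  if (!length(vstart) || !length(estart)) stop_arg("not a Pajek .net file")
  nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[vstart[1]]))
  vlines <- lines[(vstart[1] + 1):(vstart[1] + nv)]
  nm <- sub('^\\s*\\d+\\s+"([^"]*)".*$', "\\1", vlines)
  coords <- t(vapply(vlines, function(l) {
    parts <- strsplit(sub('^\\s*\\d+\\s+"[^"]*"\\s*', "", l), "\\s+")[[1]]
    as.numeric(parts[1:2])
  }, numeric(2)))
  w <- matrix(0, nv, nv, dimnames = list(nm, nm))
  elines <- lines[-seq_len(estart[1])]
  elines <- elines[nzchar(trimws(elines))]
  for (l in elines) {
    parts <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    w[parts[1], parts[2]] <- parts[3]
    w[parts[2], parts[1]] <- parts[3]
  }
  adj <- adjacency_matrix(w)
  attr(adj, "coords") <- coords
  adj
}
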