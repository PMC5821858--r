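#' Mutual information between two series (bits)
#'
#' Plug-in estimate from the joint 2-D histogram with rank-based equiprobable
#' marginal bins. Equiprobable binning makes each marginal (near-)uniform, so
#' the estimate is invariant to monotone transforms of either series and for
#' `x == y` equals `log2(n_bins)` exactly when `n_bins` divides the length.
#' The estimator is positively biased at finite sample size — the reason the
#' pipeline corrects it against a phase-randomization surrogate null.
#'
#' @param x,y numeric vectors of equal length (>= 50 recommended).
#' @param n_bins number of marginal bins (default 8).
#' @return mutual information in bits (nonnegative, symmetric in x/y).
#' @export
#' @examples
#' z <- rnorm(200)
#' mutual_information(z, z)      # = 3 bits with 8 bins
mutual_information <- function(x, y, n_bins = 8) {
  if (length(x) != length(y)) stop_arg("x and y must have equal length")
  if (max(x) == min(x) || max(y) == min(y)) {
    warning("constant series: mutual information defined as 0")
    return(0)
  }
  mi_bits_cpp(as.numeric(x), as.numeric(y), as.integer(n_bins))
}

#' Phase-randomization surrogate of a series
#'
#' Replaces the phases of all non-DC, non-Nyquist Fourier bins by i.i.d.
#' uniform draws (with conjugate symmetry), leaving the amplitude spectrum —
#' and hence the autocorrelation — untouched. The mean (DC bin) is preserved.
#' Surrogates destroy any cross-channel dependence while matching each
#' channel's linear structure, giving the null distribution for the MI test.
#'
#' @param x numeric vector, length >= 4.
#' @param seed optional RNG seed.
#' @return real-valued surrogate series of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 4) stop_arg("series too short for phase randomization")
  run <- function() {
    ft <- fft(x)
    free <- 2:(if (n %% 2 == 0) n / 2 else (n + 1) / 2)
    phi <- runif(length(free), 0, 2 * pi)
    ft[free] <- Mod(ft[free]) * exp(1i * phi)
    ft[n + 2 - free] <- Conj(ft[free])
    Re(fft(ft, inverse = TRUE)) / n
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Randomize every column of a samples x channels matrix with independent
# phases. RNG state of the caller is consumed (no internal seeding).
phase_randomize_mat <- function(sig) {
  n <- nrow(sig)
  ft <- stats::mvfft(sig)
  free <- 2:(if (n %% 2 == 0) n / 2 else (n + 1) / 2)
  phi <- matrix(runif(length(free) * ncol(sig), 0, 2 * pi), nrow = length(free))
  ft[free, ] <- Mod(ft[free, , drop = FALSE]) * exp(1i * phi)
  ft[n + 2 - free, ] <- Conj(ft[free, , drop = FALSE])
  Re(stats::mvfft(ft, inverse = TRUE)) / n
}

# Order-statistic index for the empirical (1 - alpha) null quantile: with k =
# ceiling((1 - alpha) * (S + 1)) the exceedance probability of a fresh null
# draw over the k-th order statistic is (S + 1 - k)/(S + 1) ~= alpha (the
# exact permutation-test convention).
surrogate_threshold_index <- function(n_surrogates, alpha) {
  if (n_surrogates < 1 / alpha) {
    warning("n_surrogates < 1/alpha: surrogate quantile unreliable")
  }
  min(n_surrogates, ceiling((1 - alpha) * (n_surrogates + 1)))
}

#' Surrogate-corrected mutual information for one pair
#'
#' Estimates MI(x, y), builds an empirical null from `n_surrogates`
#' phase-randomized copies of `x` paired with the original `y`, and masks the
#' estimate at the null's (1 - alpha) quantile: the observed MI is returned
#' if significant, otherwise 0 (`mode = "threshold"`, the default).
#' `mode = "subtract"` instead returns the observed MI minus the null mean,
#' floored at 0.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_surrogates surrogate count (default 1000).
#' @param alpha significance level (default 0.05).
#' @param n_bins histogram bins for the MI estimate.
#' @param seed RNG seed for the surrogate phases.
#' @param mode `"threshold"` or `"subtract"`.
#' @return corrected MI in bits; attribute `threshold` holds the null quantile.
#' @export
surrogate_corrected_mi <- function(x, y, n_surrogates = 1000, alpha = 0.05,
                                   n_bins = 8, seed = 1,
                                   mode = c("threshold", "subtract")) {
  mode <- match.arg(mode)
  obs <- mutual_information(x, y, n_bins)
  null <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      mutual_information(phase_randomize(x), y, n_bins)
    }, numeric(1))
  })
  k <- surrogate_threshold_index(n_surrogates, alpha)
  thr <- sort(null)[k]
  out <- switch(mode,
                threshold = if (obs > thr) obs else 0,
                subtract = max(obs - mean(null), 0))
  attr(out, "threshold") <- thr
  out
}

#' Wrap a weight matrix as an adjacency object
#'
#' Validates symmetry, nonnegativity and zero diagonal, and attaches
#' level/session/band metadata. Plain matrices are accepted by all metric
#' functions; this wrapper is for bookkeeping across the pipeline.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal (bits).
#' @param level `"epoch"`, `"patient"` or `"group"`.
#' @param session session label (`"preop"`, `"m3"`, `"y1"`, `"y2"`).
#' @param band band label.
#' @return the matrix with class `adjacency_matrix` and metadata attributes.
#' @export
adjacency_matrix <- function(weights, level = "patient", session = NA_character_,
                             band = "broadband") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop_arg("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10) stop_arg("weights must be symmetric")
  if (any(weights < 0)) stop_arg("weights must be nonnegative")
  diag(weights) <- 0
  structure(weights, class = c("adjacency_matrix", "matrix"),
            level = level, session = session, band = band)
}

adj_session <- function(a) attr(a, "session")

#' Patient-session adjacency matrix from an epoch set
#'
#' The core network-construction step: per epoch, pairwise MI over all channel
#' pairs; per pair, an empirical surrogate null; significance-masked MI values
#' averaged elementwise over epochs into one symmetric adjacency matrix.
#'
#' With `surrogates = "pooled"` (default) one null ensemble per pair is built
#' for the whole epoch set — each surrogate draw phase-randomizes all channels
#' of a randomly chosen epoch — and its per-pair (1 - alpha) quantile masks
#' every epoch's MI. `surrogates = "per_epoch"` rebuilds the null for each
#' epoch (slower; for validation).
#'
#' @param epochs an [epoch_set()].
#' @param n_surrogates surrogates per pair (default 1000).
#' @param alpha significance level (default 0.05).
#' @param n_bins histogram bins.
#' @param seed RNG seed.
#' @param surrogates `"pooled"` or `"per_epoch"`.
#' @param mode `"threshold"` or `"subtract"` correction.
#' @param session,band metadata carried onto the result.
#' @param details if `TRUE`, also return per-epoch observed MI and per-pair
#'   thresholds.
#' @return an [adjacency_matrix()] (level `"patient"`), or a list when
#'   `details = TRUE`.
#' @export
epoch_adjacency <- function(epochs, n_surrogates = 1000, alpha = 0.05,
                            n_bins = 8, seed = 1,
                            surrogates = c("pooled", "per_epoch"),
                            mode = c("threshold", "subtract"),
                            session = NA_character_, band = NULL,
                            details = FALSE) {
  surrogates <- match.arg(surrogates)
  mode <- match.arg(mode)
  ne <- n_epochs(epochs)
  if (ne < 1) stop_arg("need at least one epoch")
  nc <- dim(epochs$data)[2]
  obs <- array(0, dim = c(ne, nc, nc))
  for (e in seq_len(ne)) {
    sig <- t(epochs$data[e, , ])
    obs[e, , ] <- pairwise_mi_cpp(sig, n_bins)
  }
  k <- surrogate_threshold_index(n_surrogates, alpha)

  corrected <- with_seed(seed, {
    if (surrogates == "pooled") {
      null_arr <- array(0, dim = c(n_surrogates, nc, nc))
      src <- sample.int(ne, n_surrogates, replace = TRUE)
      for (s in seq_len(n_surrogates)) {
        sig <- phase_randomize_mat(t(epochs$data[src[s], , ]))
        null_arr[s, , ] <- pairwise_mi_cpp(sig, n_bins)
      }
      thr <- apply(null_arr, c(2, 3), function(v) sort(v)[k])
      nullmean <- apply(null_arr, c(2, 3), mean)
      corr <- array(0, dim = dim(obs))
      for (e in seq_len(ne)) {
        m <- obs[e, , ]
        corr[e, , ] <- switch(mode,
                              threshold = m * (m > thr),
                              subtract = pmax(m - nullmean, 0))
      }
      attr(corr, "threshold") <- thr
      corr
    } else {
      corr <- array(0, dim = dim(obs))
      thr_last <- NULL
      for (e in seq_len(ne)) {
        null_arr <- array(0, dim = c(n_surrogates, nc, nc))
        for (s in seq_len(n_surrogates)) {
          sig <- phase_randomize_mat(t(epochs$data[e, , ]))
          null_arr[s, , ] <- pairwise_mi_cpp(sig, n_bins)
        }
        thr_last <- apply(null_arr, c(2, 3), function(v) sort(v)[k])
        nullmean <- apply(null_arr, c(2, 3), mean)
        m <- obs[e, , ]
        corr[e, , ] <- switch(mode,
                              threshold = m * (m > thr_last),
                              subtract = pmax(m - nullmean, 0))
      }
      attr(corr, "threshold") <- thr_last
      corr
    }
  })

  w <- apply(corrected, c(2, 3), mean)
  w <- (w + t(w)) / 2
  dimnames(w) <- list(epochs$montage$channel, epochs$montage$channel)
  adj <- adjacency_matrix(w, level = "patient", session = session,
                          band = band %||% epochs$band)
  if (details) {
    list(adjacency = adj, observed = obs,
         threshold = attr(corrected, "threshold"))
  } else {
    adj
  }
}

#' Average patient matrices into a group matrix
#'
#' Elementwise mean of patient-level adjacency matrices from the same session
#' and band.
#'
#' @param matrices list of adjacency matrices.
#' @return group-level [adjacency_matrix()].
#' @export
group_adjacency <- function(matrices) {
  if (length(matrices) < 1) stop_arg("need at least one matrix")
  sess <- unique(vapply(matrices, function(m) as.character(adj_session(m) %||% NA),
                        character(1)))
  if (length(sess[!is.na(sess)]) > 1) {
    stop_arg("cannot average matrices from different sessions: ",
             paste(sess, collapse = ", "))
  }
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) > 1) stop_arg("matrix shapes differ")
  w <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  adjacency_matrix(w, level = "group", session = sess[1],
                   band = attr(matrices[[1]], "band") %||% "broadband")
}

#' Difference network (post minus pre)
#'
#' Signed elementwise difference: positive entries mark connections that
#' strengthened after surgery, negative entries connections that weakened.
#'
#' @param post,pre adjacency matrices of equal shape and level.
#' @return signed numeric matrix.
#' @export
difference_matrix <- function(post, pre) {
  if (!all(dim(post) == dim(pre))) stop_arg("matrix shapes differ")
  unclass(post) - unclass(pre)
}

#' Strongest edges of a network
#'
#' The `ceiling(fraction * n_pairs)` strongest channel pairs, for plotting and
#' export only — graph measures always use the full weighted matrix. Ties are
#' broken by channel-pair lexicographic order (row index, then column), so the
#' selection is deterministic.
#'
#' @param adj adjacency matrix with channel dimnames.
#' @param fraction fraction of pairs to keep, in (0, 1]; default 0.30.
#' @return data.frame `from`, `to`, `weight`, strongest first.
#' @export
top_fraction_edges <- function(adj, fraction = 0.30) {
  if (fraction <= 0 || fraction > 1) stop_arg("fraction must be in (0, 1]")
  w <- unclass(adj)
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  ed <- data.frame(i = idx[, 1], j = idx[, 2], weight = w[idx])
  ed <- ed[order(-ed$weight, ed$i, ed$j), ]
  keep <- ceiling(fraction * nrow(ed))
  ed <- ed[seq_len(keep), ]
  nm <- rownames(w) %||% as.character(seq_len(n))
  data.frame(from = nm[ed$i], to = nm[ed$j], weight = ed$weight,
             row.names = NULL, stringsAsFactors = FALSE)
}
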