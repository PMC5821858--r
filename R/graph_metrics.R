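as_weight_matrix <- function(adj) {
  w <- unclass(as.matrix(adj))
  if (any(w < 0)) stop_arg("weights must be nonnegative")
  diag(w) <- 0
  w
}

graph_from_weights <- function(w) {
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted betweenness centrality
#'
#' Exact shortest-path betweenness on the weighted graph with edge length
#' 1/weight (strong connections are short); zero-weight pairs are
#' non-adjacent. Multiple equal-length shortest paths share credit
#' fractionally (Brandes accounting). Values are normalized by
#' `(n-1)(n-2)/2`, the number of pairs that could route through a node, so a
#' star center scores 1.
#'
#' @param adj adjacency matrix (symmetric, nonnegative, zero diagonal).
#' @return named numeric vector of per-node betweenness in `[0, 1]`.
#' @export
weighted_betweenness <- function(adj) {
  w <- as_weight_matrix(adj)
  n <- nrow(w)
  g <- graph_from_weights(w)
  bc <- igraph::betweenness(g, directed = FALSE,
                            weights = 1 / igraph::E(g)$weight)
  out <- bc / ((n - 1) * (n - 2) / 2)
  names(out) <- rownames(w)
  out
}

#' Onnela weighted local clustering coefficient
#'
#' Weights are first scaled to `[0, 1]` by the matrix maximum; node `i`'s
#' coefficient is the sum over neighbour pairs `(j, k)` of the geometric mean
#' of the three scaled weights, divided by `k_i (k_i - 1)` where `k_i` counts
#' neighbours with nonzero weight. A fully connected uniform-weight network
#' scores exactly 1 at every node; nodes with fewer than two neighbours score
#' 0.
#'
#' @param adj adjacency matrix.
#' @return named numeric vector of per-node clustering in `[0, 1]`.
#' @export
local_clustering <- function(adj) {
  w <- as_weight_matrix(adj)
  mx <- max(w)
  if (mx == 0) {
    out <- rep(0, nrow(w)); names(out) <- rownames(w); return(out)
  }
  wh <- (w / mx)^(1 / 3)
  num <- diag(wh %*% wh %*% wh)
  k <- rowSums(w > 0)
  out <- ifelse(k < 2, 0, num / (k * (k - 1)))
  names(out) <- rownames(w)
  out
}

#' Characteristic path length
#'
#' Mean shortest-path distance (edge length 1/weight) over all node pairs.
#' Significance masking can disconnect a network; by default a disconnected
#' graph falls back to the harmonic mean of pairwise distances (the reciprocal
#' of global efficiency, infinite distances contributing zero) with a warning;
#' `disconnected = "error"` raises instead.
#'
#' @param adj adjacency matrix.
#' @param disconnected `"harmonic"` (default) or `"error"`.
#' @return scalar path length (1/bits units).
#' @export
characteristic_path_length <- function(adj, disconnected = c("harmonic", "error")) {
  disconnected <- match.arg(disconnected)
  w <- as_weight_matrix(adj)
  g <- graph_from_weights(w)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  off <- d[upper.tri(d)]
  if (any(!is.finite(off))) {
    if (disconnected == "error") stop_arg("graph is disconnected")
    warning("disconnected graph: harmonic-mean characteristic path length used")
    eff <- mean(1 / off)   # 1/Inf = 0
    return(1 / eff)
  }
  mean(off)
}

# One degree-preserving random reference: Maslov-Sneppen edge rewiring that
# keeps the degree sequence, then random reassignment of the observed weight
# multiset to the rewired edges. Consumes the caller's RNG stream.
random_reference <- function(w) {
  g <- graph_from_weights(w)
  wt <- igraph::E(g)$weight
  g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  igraph::E(g2)$weight <- sample(wt)
  m <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  dimnames(m) <- dimnames(w)
  m
}

#' Global network metrics with null-model normalization
#'
#' Computes the raw characteristic path length (CPL) and global clustering
#' coefficient (GCC, the mean of the Onnela local coefficients), normalizes
#' each by its mean over an ensemble of `n_random` degree- and
#' weight-preserving random references, and reports small-worldness as the
#' ratio of normalized GCC to normalized CPL. A fully connected uniform-weight
#' network is a fixed point of the null model, so all normalized values equal
#' 1 exactly.
#'
#' @param adj adjacency matrix.
#' @param n_random random-reference ensemble size (default 100, minimum 20).
#' @param seed RNG seed for the ensemble.
#' @param disconnected disconnected-graph policy, see
#'   [characteristic_path_length()].
#' @return list of class `global_metrics`: `cpl_raw`, `gcc_raw`, `cpl_norm`,
#'   `gcc_norm`, `small_worldness`, `cpl_random_sd`, `gcc_random_sd`,
#'   `n_random`, `seed`.
#' @export
global_metrics <- function(adj, n_random = 100, seed = 1,
                           disconnected = "harmonic") {
  if (n_random < 20) warning("n_random < 20: normalization will be noisy")
  w <- as_weight_matrix(adj)
  cpl_raw <- characteristic_path_length(w, disconnected)
  gcc_raw <- mean(local_clustering(w))
  rnd <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      m <- random_reference(w)
      c(cpl = suppressWarnings(characteristic_path_length(m, disconnected)),
        gcc = mean(local_clustering(m)))
    }, numeric(2))
  })
  cpl_norm <- cpl_raw / mean(rnd["cpl", ])
  gcc_norm <- gcc_raw / mean(rnd["gcc", ])
  structure(list(cpl_raw = cpl_raw, gcc_raw = gcc_raw,
                 cpl_norm = cpl_norm, gcc_norm = gcc_norm,
                 small_worldness = gcc_norm / cpl_norm,
                 cpl_random_sd = sd(rnd["cpl", ]),
                 gcc_random_sd = sd(rnd["gcc", ]),
                 n_random = n_random, seed = seed),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf(paste0("<global_metrics> CPL %.4f (norm %.4f)  GCC %.4f ",
                     "(norm %.4f)  small-worldness %.4f  [%d refs]\n"),
              x$cpl_raw, x$cpl_norm, x$gcc_raw, x$gcc_norm,
              x$small_worldness, x$n_random))
  invisible(x)
}

#' Extract network hubs
#'
#' The `k` channels with the largest betweenness centrality, in descending
#' order; ties are broken by channel (montage) order and flagged via the
#' `ties` attribute.
#'
#' @param adj adjacency matrix with channel dimnames (or a named bc vector).
#' @param k number of hubs (default 5).
#' @return character vector of channel names, attribute `bc` with their
#'   values and `ties` marking a tie at the cut.
#' @export
extract_hubs <- function(adj, k = 5) {
  bc <- if (is.matrix(adj) || inherits(adj, "adjacency_matrix")) {
    weighted_betweenness(adj)
  } else {
    adj
  }
  if (k > length(bc)) stop_arg("k exceeds node count")
  ord <- order(-bc, seq_along(bc))
  hubs <- names(bc)[ord[seq_len(k)]]
  tie <- k < length(bc) && bc[ord[k]] == bc[ord[k + 1]]
  structure(hubs, bc = bc[ord[seq_len(k)]], ties = tie)
}

#' Summarize a hub shift between two states
#'
#' Counts paramedian vs lateral hubs in each state and reports the signed
#' change in paramedian hub count (negative = hubs moved laterally, the
#' post-operative pattern in good-outcome groups).
#'
#' @param pre_hubs,post_hubs character vectors of hub channel names.
#' @param montage montage data.frame (default [montage_1020()]).
#' @return list: `pre_paramedian`, `pre_lateral`, `post_paramedian`,
#'   `post_lateral`, `shift` (post minus pre paramedian count).
#' @export
hub_shift <- function(pre_hubs, post_hubs, montage = montage_1020()) {
  reg <- function(h) montage$region[match(h, montage$channel)]
  if (anyNA(reg(pre_hubs)) || anyNA(reg(post_hubs))) {
    stop_arg("hub channel not found in montage")
  }
  pre_p <- sum(reg(pre_hubs) == "paramedian")
  post_p <- sum(reg(post_hubs) == "paramedian")
  list(pre_paramedian = pre_p, pre_lateral = length(pre_hubs) - pre_p,
       post_paramedian = post_p, post_lateral = length(post_hubs) - post_p,
       shift = post_p - pre_p)
}
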