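# Independent oracles used to validate the package's estimators.

# Plug-in MI with rank-equiprobable bins, coded independently via the entropy
# identity H(X) + H(Y) - H(X, Y). Identical partition to the package's C++
# binning when n_bins divides the length (both are stable-rank partitions).
mi_oracle <- function(x, y, n_bins = 8) {
  n <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  by <- ceiling(rank(y, ties.method = "first") * n_bins / n)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  px <- table(factor(bx, 1:n_bins)) / n
  py <- table(factor(by, 1:n_bins)) / n
  pxy <- table(factor(bx, 1:n_bins), factor(by, 1:n_bins)) / n
  H(px) + H(py) - H(pxy)
}

# Brute-force weighted shortest paths by exhaustive simple-path enumeration
# (feasible to ~7 nodes). Returns normalized betweenness (fractional credit
# over co-shortest paths) and the mean shortest-path length, NA if
# disconnected.
brute_path_metrics <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  bc <- numeric(n)
  best <- matrix(Inf, n, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    found <- list()
    dfs <- function(node, visited, len) {
      if (node == t) {
        found[[length(found) + 1]] <<- list(v = visited, len = len)
        return(invisible())
      }
      for (nb in which(is.finite(d[node, ]))) {
        if (!(nb %in% visited)) dfs(nb, c(visited, nb), len + d[node, nb])
      }
    }
    dfs(s, s, 0)
    if (!length(found)) next
    lens <- vapply(found, `[[`, numeric(1), "len")
    m <- min(lens)
    best[s, t] <- best[t, s] <- m
    sel <- found[lens - m < 1e-9]
    for (pth in sel) {
      interior <- pth$v[-c(1, length(pth$v))]
      bc[interior] <- bc[interior] + 1 / length(sel)
    }
  }
  off <- best[upper.tri(best)]
  list(bc = bc / ((n - 1) * (n - 2) / 2),
       cpl = if (all(is.finite(off))) mean(off) else NA_real_)
}

random_small_graph <- function(n, p_edge = 0.6, connected = TRUE) {
  repeat {
    w <- matrix(0, n, n)
    up <- which(upper.tri(w))
    on <- up[runif(length(up)) < p_edge]
    w[on] <- runif(length(on), 0.2, 1)
    w <- w + t(w)
    if (!connected) return(w)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::is_connected(g)) return(w)
  }
}

complete_uniform <- function(n = 19, weight = 0.5) {
  w <- matrix(weight, n, n)
  diag(w) <- 0
  if (n == 19) dimnames(w) <- list(montage_1020()$channel,
                                   montage_1020()$channel)
  w
}
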