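# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, for topology, the graph library) they check.

# adjacency matrix of an interactome, fixed node order
adj_matrix <- function(net) {
  nm <- nodes(net)
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  el <- igraph::as_edgelist(net$graph)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1L], el[i, 2L]] <- 1L
    A[el[i, 2L], el[i, 1L]] <- 1L
  }
  A
}

# all simple paths s -> t by DFS over the adjacency matrix
enumerate_paths <- function(A, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in which(A[last, ] == 1L)) {
      if (!nxt %in% path) walk(c(path, nxt))
    }
  }
  walk(s)
  out
}

# endpoint-excluding betweenness, normalized by (n-1)(n-2)/2, by exhaustive
# shortest-path enumeration
oracle_betweenness <- function(A) {
  n <- nrow(A)
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- enumerate_paths(A, s, t)
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1L)))
        btw[v] <- btw[v] + through / length(shortest)
      }
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

oracle_degree_centrality <- function(A) rowSums(A) / (nrow(A) - 1)

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(0)
    tri <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) tri <- tri + A[nb[i], nb[j]]
    }
    tri / (k * (k - 1) / 2)
  }, numeric(1L))
}

# hop distances by repeated frontier expansion on the adjacency matrix
oracle_bfs <- function(A, s) {
  n <- nrow(A)
  d <- rep(NA_integer_, n)
  d[s] <- 0L
  frontier <- s
  hop <- 0L
  while (length(frontier)) {
    hop <- hop + 1L
    nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE]) > 0), which(!is.na(d)))
    d[nxt] <- hop
    frontier <- nxt
  }
  d
}

# hypergeometric upper tail P(X >= ks) by direct summation of the pmf
oracle_hyper_tail <- function(ks, N, s0, k) {
  js <- ks:min(k, s0)
  sum(choose(s0, js) * choose(N - s0, k - js)) / choose(N, k)
}

# confusion-matrix metrics from first principles
oracle_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  npv <- if (tn + fn > 0) tn / (tn + fn) else 0
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  list(acc = (tp + tn) / total, prec = prec, rec = rec, mcc = mcc,
       npv = npv, ppv = prec)
}

# random Erdos-Renyi-ish interactome with at least one edge
random_test_graph <- function(n, p = 0.4, connected = FALSE) {
  repeat {
    pairs <- t(combn(sprintf("N%d", seq_len(n)), 2L))
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) next
    net <- suppressMessages(
      as_interactome(pairs[keep, , drop = FALSE],
                     largest_component = connected))
    if (!connected) return(net)
    if (igraph::vcount(net$graph) >= max(3L, n - 2L)) return(net)
  }
}
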