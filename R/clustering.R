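#' Diffusion state distance matrix
#'
#' Characterizes each node `u` by its expected-visit profile
#' `He(u) = sum_{t=0..walk_length} P^t [u, ]`, where `P` is the one-step
#' random-walk transition matrix, and defines the diffusion state distance
#' between two nodes as the L1 distance between their profiles. Nodes
#' embedded in the same network neighborhood have small DSD.
#'
#' @param net a connected `interactome` (error otherwise; load with
#'   `largest_component = TRUE`).
#' @param walk_length number of random-walk steps accumulated (finite-walk
#'   form; default 5).
#' @return object of class `dsd_matrix`: list with `node_order`, the
#'   symmetric zero-diagonal `values` matrix, and `walk_length`.
#' @export
dsd_matrix <- function(net, walk_length = 5L) {
  stopifnot(inherits(net, "interactome"))
  g <- net$graph
  if (igraph::components(g)$no > 1L) {
    stop("DSD requires a connected network; load with largest_component = TRUE")
  }
  nm <- igraph::V(g)$name
  n <- length(nm)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  P <- A / rowSums(A)
  He <- diag(n)     # t = 0 term
  Pt <- diag(n)
  for (t in seq_len(walk_length)) {
    Pt <- Pt %*% P
    He <- He + Pt
  }
  D <- as.matrix(stats::dist(He, method = "manhattan"))
  dimnames(D) <- list(nm, nm)
  structure(list(node_order = nm, values = D, walk_length = walk_length),
            class = "dsd_matrix")
}

.dense_partition <- function(membership, algorithm) {
  ids <- as.integer(factor(membership, levels = unique(membership))) - 1L
  names(ids) <- names(membership)
  structure(list(algorithm = algorithm, assignment = ids,
                 n_modules = length(unique(ids))),
            class = "module_partition")
}

#' Spectral partition of the DSD matrix
#'
#' Normalized spectral clustering on the affinity `exp(-d / sigma)` with
#' `sigma` the median off-diagonal DSD. This carries the "K1-style"
#' module-membership feature: ADR-associated proteins are expected to share
#' few modules.
#'
#' @param dsd a `dsd_matrix`.
#' @param k number of modules, `1 <= k <= n`. Defaults to `round(n / 15)`
#'   (at least 2) when `NULL`.
#' @param rng_seed integer seed making the k-means step deterministic.
#' @return a `module_partition` with algorithm tag `"K1DSD"`.
#' @export
spectral_partition <- function(dsd, k = NULL, rng_seed = 1L) {
  stopifnot(inherits(dsd, "dsd_matrix"))
  n <- length(dsd$node_order)
  if (is.null(k)) k <- max(2L, round(n / 15))
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  nm <- dsd$node_order
  if (k == 1L) {
    return(.dense_partition(setNames(rep(0L, n), nm), "K1DSD"))
  }
  if (k == n) {
    return(.dense_partition(setNames(seq_len(n), nm), "K1DSD"))
  }
  d <- dsd$values
  sigma <- median(d[upper.tri(d)])
  if (sigma <= 0) sigma <- 1
  K <- exp(-d / sigma)
  dg <- rowSums(K)
  L <- K / sqrt(outer(dg, dg))
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / ifelse(rn > 0, rn, 1)
  km <- local({
    set.seed(rng_seed)
    if (nrow(unique(round(U, 12))) < k) {
      # fewer distinct embedded points than clusters: group identical rows
      list(cluster = as.integer(factor(apply(round(U, 12), 1L, paste, collapse = ","))))
    } else {
      stats::kmeans(U, centers = k, nstart = 10L, iter.max = 100L)
    }
  })
  .dense_partition(setNames(km$cluster, nm), "K1DSD")
}

#' Louvain modularity partition
#'
#' Greedy modularity optimization (iterative node reassignment and module
#' aggregation) on the interactome.
#'
#' @param net an `interactome`.
#' @param resolution modularity resolution parameter (1 = classic).
#' @param rng_seed integer seed; the result is deterministic given the seed.
#' @return a `module_partition` with algorithm tag `"LOUVAIN"`.
#' @export
louvain_partition <- function(net, resolution = 1.0, rng_seed = 1L) {
  stopifnot(inherits(net, "interactome"))
  set.seed(rng_seed)
  cl <- igraph::cluster_louvain(net$graph, resolution = resolution)
  .dense_partition(setNames(igraph::membership(cl), igraph::V(net$graph)$name),
                   "LOUVAIN")
}

#' Cluster-dispersion feature ("% of clusters")
#'
#' For each query protein, the percentage of distinct modules occupied by
#' the ADR seeds plus the protein, relative to the size of that set:
#' `100 * |modules(seeds + protein)| / |seeds + protein|`. Low values mean
#' the protein co-clusters with the ADR module; ADR-associated proteins are
#' expected to score lower than random ones.
#'
#' @param partition a `module_partition` covering every queried accession.
#' @param seeds a `seed_set`.
#' @param proteins character vector of query accessions.
#' @return named numeric vector of percentages in (0, 100].
#' @export
cluster_fraction <- function(partition, seeds, proteins) {
  stopifnot(inherits(partition, "module_partition"), inherits(seeds, "seed_set"))
  asg <- partition$assignment
  missing <- setdiff(c(seeds$accessions, proteins), names(asg))
  if (length(missing)) {
    stop("accession(s) not assigned in partition: ",
         paste(head(missing, 5L), collapse = ", "))
  }
  vapply(proteins, function(p) {
    members <- unique(c(seeds$accessions, p))
    100 * length(unique(asg[members])) / length(members)
  }, numeric(1L))
}

#' Export a module partition as TSV
#' @param partition a `module_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  write.table(data.frame(accession = names(partition$assignment),
                         module_id = unname(partition$assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
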