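#' @importFrom stats quantile median p.adjust phyper setNames sd predict
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Build an interactome object from an edge data frame
#'
#' Constructs the undirected protein-interaction network that every feature
#' in the package is computed on. Self-loops are dropped (with a warning) and
#' duplicate undirected edges are collapsed.
#'
#' @param edges two-column data frame (or matrix) of protein accessions, one
#'   interaction per row. Accessions are opaque, case-sensitive strings.
#' @param label free-text name for the network.
#' @param largest_component if `TRUE` (default) the network is restricted to
#'   its largest connected component; diffusion and panel-distance features
#'   are undefined across components.
#' @return an object of class `interactome` wrapping an [igraph] graph.
#' @export
as_interactome <- function(edges, label = "interactome", largest_component = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L || nrow(edges) < 1L) {
    stop("edge table must have at least two columns and one row")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  bad <- is.na(a) | is.na(b) | a == "" | b == ""
  if (any(bad)) {
    stop("malformed edge row(s): ", paste(which(bad), collapse = ", "))
  }
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
  }
  all_nodes <- sort(unique(c(a, b)))
  a2 <- a[!loops]; b2 <- b[!loops]
  # undirected dedup via canonical ordering
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[keep], to = hi[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  if (igraph::vcount(g) < 2L) stop("interactome needs at least 2 nodes")
  if (largest_component) {
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      keep_nodes <- names(comp$membership)[comp$membership == which.max(comp$csize)]
      dropped <- igraph::vcount(g) - length(keep_nodes)
      message("restricting to largest connected component: ",
              length(keep_nodes), " nodes kept, ", dropped, " dropped")
      g <- igraph::induced_subgraph(g, keep_nodes)
    }
  }
  structure(list(graph = g, label = label), class = "interactome")
}

#' Read an interactome from an edge-list file
#'
#' Accepts a two-column tab- or whitespace-separated edge list, or SIF
#' (`A relation B`; the relation column is ignored). A header line is
#' detected heuristically and skipped. Row order does not affect the result.
#'
#' @param path path to the edge-list file.
#' @param format `"auto"` (default), `"edge"` for 2-column TSV, or `"sif"`.
#' @inheritParams as_interactome
#' @return an `interactome` object.
#' @export
load_interactome <- function(path, format = c("auto", "edge", "sif"),
                             label = basename(path), largest_component = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty interactome file: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  nfield <- lengths(toks)
  if (format == "auto") {
    format <- if (median(nfield) >= 3) "sif" else "edge"
  }
  want <- if (format == "sif") 3L else 2L
  bad <- which(nfield < want)
  # header detection: first row whose tokens look like column names
  start <- 1L
  if (length(lines) > 1L) {
    first <- tolower(toks[[1L]])
    if (any(grepl("^(protein|node|source|target|interactor|from|to|acc)", first))) {
      start <- 2L
    }
  }
  bad <- bad[bad >= start]
  if (length(bad)) {
    stop("malformed row at line ", bad[1L], ": expected at least ",
         want, " fields, got ", nfield[bad[1L]])
  }
  idx <- start:length(toks)
  a <- vapply(toks[idx], `[[`, character(1L), 1L)
  b <- vapply(toks[idx], `[[`, character(1L), if (format == "sif") 3L else 2L)
  as_interactome(data.frame(a, b, stringsAsFactors = FALSE),
                 label = label, largest_component = largest_component)
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome '", x$label, "': ", igraph::vcount(x$graph), " proteins, ",
      igraph::ecount(x$graph), " interactions\n", sep = "")
  invisible(x)
}

#' Node accessions of an interactome
#' @param net an `interactome`.
#' @return character vector of protein accessions.
#' @export
nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::V(net$graph)$name
}

#' Node-level topology profile
#'
#' Computes the three topology features used by the classifier:
#' degree centrality (degree / (n-1)), betweenness centrality (Brandes
#' pair-dependencies, endpoints excluded, normalized by (n-1)(n-2)/2) and
#' the local clustering coefficient (triangles / possible triangles, 0 for
#' nodes of degree < 2).
#'
#' @param net an `interactome`.
#' @return list with named numeric vectors `degree_centrality`,
#'   `betweenness` and `clustering_coefficient`, each covering every node,
#'   all values in `[0, 1]`.
#' @export
topology_profile <- function(net) {
  stopifnot(inherits(net, "interactome"))
  g <- net$graph
  n <- igraph::vcount(g)
  deg <- igraph::degree(g) / (n - 1)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  list(degree_centrality = deg, betweenness = btw, clustering_coefficient = cc)
}

#' Breadth-first hop distances from one node
#'
#' @param net an `interactome`.
#' @param source accession of the source node (must be in the network).
#' @return named integer vector of minimal hop counts for every node
#'   reachable from `source` (including `source` itself at 0); unreachable
#'   nodes are absent.
#' @export
bfs_distances <- function(net, source) {
  stopifnot(inherits(net, "interactome"))
  if (!source %in% nodes(net)) stop("unknown source node: ", source)
  d <- igraph::distances(net$graph, v = source, algorithm = "unweighted")[1L, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}
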