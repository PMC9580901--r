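#' Construct an ADR seed set
#'
#' Validates a set of ADR-associated proteins against the working network.
#' Accessions missing from the network are dropped with a warning; if none
#' remain, an error is raised.
#'
#' @param accessions character vector of protein accessions.
#' @param net an `interactome` to validate against (optional; no validation
#'   if `NULL`).
#' @param adr_label free-text ADR (or SOC) label.
#' @return object of class `seed_set` with elements `adr_label`, `accessions`.
#' @export
seed_set <- function(accessions, net = NULL, adr_label = "ADR") {
  accessions <- unique(as.character(accessions))
  if (length(accessions) == 0L) stop("seed set is empty")
  if (!is.null(net)) {
    present <- accessions %in% nodes(net)
    if (!all(present)) {
      warning(sum(!present), " seed(s) absent from the network dropped: ",
              paste(head(accessions[!present], 5L), collapse = ", "))
    }
    accessions <- accessions[present]
    if (length(accessions) == 0L) {
      stop("no seed maps into the network for ", adr_label)
    }
  }
  structure(list(adr_label = adr_label, accessions = accessions),
            class = "seed_set")
}

#' Network diffusion score by random walk with restart
#'
#' Scores every protein by its diffusion proximity to an ADR seed set:
#' the fixed point of `s = alpha * W s + (1 - alpha) * e`, where `W` is the
#' column-normalized adjacency matrix and `e` is the restart vector, uniform
#' over the seeds. Higher scores mean the diffusion "message" from the seeds
#' reaches the protein faster; this is the guilt-by-association feature fed
#' to the classifiers.
#'
#' @param net an `interactome`.
#' @param seeds a `seed_set` (revalidated against `net`).
#' @param alpha restart-complement weight in (0, 1); the walker continues
#'   with probability `alpha` and restarts on a seed with `1 - alpha`.
#' @param tol convergence tolerance on the max absolute score change.
#' @param max_iter iteration cap; non-convergence yields a warning, not an
#'   error.
#' @return object of class `diffusion_scores`: list with `scores` (named
#'   numeric over all nodes), `alpha`, `iterations_run`, `converged`.
#' @export
propagate <- function(net, seeds, alpha = 0.5, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(net, "interactome"), inherits(seeds, "seed_set"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  seeds <- seed_set(seeds$accessions, net, seeds$adr_label)
  g <- net$graph
  nm <- igraph::V(g)$name
  n <- length(nm)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- Matrix::colSums(A)
  # column-normalize; zero-degree columns stay zero (those nodes only leak
  # mass back through the restart term)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- A %*% Matrix::Diagonal(x = inv)
  e <- setNames(numeric(n), nm)
  e[seeds$accessions] <- 1 / length(seeds$accessions)
  s <- e
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    s_new <- as.numeric(alpha * (W %*% s)) + (1 - alpha) * e
    delta <- max(abs(s_new - s))
    s <- setNames(s_new, nm)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("diffusion did not converge in ", max_iter, " iterations")
  structure(list(scores = s, alpha = alpha, iterations_run = it,
                 converged = converged, adr_label = seeds$adr_label),
            class = "diffusion_scores")
}

#' Top-ranked proteins by diffusion score
#'
#' @param scores a `diffusion_scores` object.
#' @param k number of proteins to return (all nodes if `k >= n`).
#' @return character vector of the `k` highest-scoring accessions in
#'   descending score order; ties broken lexicographically by accession.
#' @export
top_ranked <- function(scores, k) {
  stopifnot(inherits(scores, "diffusion_scores"))
  if (k < 1L) stop("k must be >= 1")
  s <- scores$scores
  ord <- order(-s, names(s))
  names(s)[ord[seq_len(min(k, length(s)))]]
}

#' Export diffusion scores as a two-column TSV
#'
#' @param scores a `diffusion_scores` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  s <- scores$scores
  ord <- order(-s, names(s))
  write.table(data.frame(accession = names(s)[ord], score = unname(s[ord])),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
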