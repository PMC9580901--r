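#' Read GO annotations
#'
#' Reads either a GAF 2.x file (comment lines starting with `!` skipped,
#' columns 2 and 5 used, rows whose qualifier contains `NOT` dropped) or a
#' plain two-column accession/GO-id TSV.
#'
#' @param path annotation file.
#' @param format `"auto"` (GAF detected by `!gaf-version` header or >= 15
#'   columns), `"gaf"` or `"tsv"`.
#' @return named list mapping accession to a character vector of GO ids
#'   (class `go_annotations`).
#' @export
read_go_annotations <- function(path, format = c("auto", "gaf", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    fields <- length(strsplit(lines[!startsWith(lines, "!")][1L], "\t", fixed = TRUE)[[1L]])
    format <- if (any(startsWith(lines, "!gaf")) || fields >= 15L) "gaf" else "tsv"
  }
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    keep <- !vapply(toks, function(x) grepl("\\bNOT\\b", x[4L]), logical(1L))
    toks <- toks[keep]
    acc <- vapply(toks, `[[`, character(1L), 2L)
    go <- vapply(toks, `[[`, character(1L), 5L)
  } else {
    # skip a header row (second field carries no GO prefix at all)
    if (length(toks) > 1L && !startsWith(toks[[1L]][2L], "GO:")) toks <- toks[-1L]
    acc <- vapply(toks, `[[`, character(1L), 1L)
    go <- vapply(toks, `[[`, character(1L), 2L)
  }
  bad <- !grepl("^GO:\\d{7}$", go)
  if (any(bad)) stop("invalid GO id(s), e.g. ", go[which(bad)[1L]])
  go_annotation_map(split(go, acc))
}

#' Construct a GO annotation map from a list
#' @param annotations named list, accession -> character vector of GO ids.
#' @return a `go_annotations` object.
#' @export
go_annotation_map <- function(annotations) {
  annotations <- lapply(annotations, function(x) unique(as.character(x)))
  ok <- vapply(annotations, function(x) all(grepl("^GO:\\d{7}$", x)), logical(1L))
  if (!all(ok)) stop("GO ids must match 'GO:' + 7 digits")
  structure(annotations, class = "go_annotations")
}

#' GO term enrichment by Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test for every GO term annotated on
#' at least one study protein, against the given background, with
#' Benjamini-Hochberg adjustment across the tested terms. Typically the
#' study set is the top-ranked proteins of a seed propagation
#' (see [top_ranked()]).
#'
#' @param ann a `go_annotations` map.
#' @param study character vector of study accessions (subset of background).
#' @param background character vector of background accessions (defaults to
#'   every annotated-or-not accession in `ann`).
#' @param alpha BH-adjusted significance level for retention.
#' @return object of class `enriched_terms`: data.frame `terms` with columns
#'   `go_id`, `p_value`, `adjusted_p` (sorted by ascending p, only rows with
#'   `adjusted_p <= alpha`), plus `alpha` and the full `tested` table.
#' @export
fisher_enrichment <- function(ann, study, background = names(ann), alpha = 0.05) {
  stopifnot(inherits(ann, "go_annotations"))
  study <- unique(study); background <- unique(background)
  if (length(study) == 0L) stop("study set is empty")
  if (!all(study %in% background)) stop("study must be a subset of background")
  N <- length(background)
  s <- length(study)
  study_ann <- ann[intersect(study, names(ann))]
  terms <- unique(unlist(study_ann, use.names = FALSE))
  if (length(terms) == 0L) {
    warning("no GO term annotated on any study protein")
    empty <- data.frame(go_id = character(), p_value = numeric(),
                        adjusted_p = numeric(), stringsAsFactors = FALSE)
    return(structure(list(terms = empty, alpha = alpha, tested = empty),
                     class = "enriched_terms"))
  }
  bg_ann <- ann[intersect(background, names(ann))]
  # per-term counts in study and background
  k_study <- table(factor(unlist(lapply(study_ann, intersect, terms),
                                 use.names = FALSE), levels = terms))
  K_bg <- table(factor(unlist(lapply(bg_ann, intersect, terms),
                              use.names = FALSE), levels = terms))
  p <- phyper(as.numeric(k_study) - 1L, as.numeric(K_bg),
              N - as.numeric(K_bg), s, lower.tail = FALSE)
  tested <- data.frame(go_id = terms, p_value = p,
                       adjusted_p = p.adjust(p, method = "BH"),
                       stringsAsFactors = FALSE)
  tested <- tested[order(tested$p_value, tested$go_id), , drop = FALSE]
  rownames(tested) <- NULL
  keep <- tested[tested$adjusted_p <= alpha, , drop = FALSE]
  structure(list(terms = keep, alpha = alpha, tested = tested),
            class = "enriched_terms")
}

#' Function conservation index
#'
#' Overlap between a protein's GO annotations and the set `E` of enriched
#' terms, expressed as `1 - Hamming(protein indicator, all-ones) / |E|`,
#' i.e. `|terms(protein) & E| / |E|`. A value of 1 indicates full overlap
#' with the enriched functions; 0 means no shared function. If no term is
#' enriched the index is 0 (with a warning).
#'
#' @param protein_terms character vector of the protein's GO ids.
#' @param enriched an `enriched_terms` object.
#' @return fraction in `[0, 1]`.
#' @export
function_index <- function(protein_terms, enriched) {
  stopifnot(inherits(enriched, "enriched_terms"))
  E <- enriched$terms$go_id
  if (length(E) == 0L) {
    warning("empty enriched-term set; function index defaults to 0")
    return(0)
  }
  length(intersect(unique(protein_terms), E)) / length(E)
}

#' Construct a safety-target panel
#'
#' A panel of established safety-pharmacology targets ("very important
#' targets"); network distance to the panel is one of the classifier
#' features. Members absent from the network are dropped with a warning.
#'
#' @param accessions panel accessions.
#' @param net an `interactome` to validate against (optional).
#' @param label panel name.
#' @return object of class `vit_panel`.
#' @export
vit_panel <- function(accessions, net = NULL, label = "VIT") {
  accessions <- unique(as.character(accessions))
  if (length(accessions) == 0L) stop("panel is empty")
  if (!is.null(net)) {
    present <- accessions %in% nodes(net)
    if (!all(present)) {
      warning(sum(!present), " panel member(s) absent from the network dropped")
    }
    accessions <- accessions[present]
    if (length(accessions) == 0L) stop("no panel member maps into the network")
  }
  structure(list(accessions = accessions, label = label), class = "vit_panel")
}

#' Read a panel from a plain-text accession list
#' @param path file with one accession per line (blank lines ignored).
#' @inheritParams vit_panel
#' @return a `vit_panel`.
#' @export
read_panel <- function(path, net = NULL, label = basename(path)) {
  acc <- trimws(readLines(path, warn = FALSE))
  vit_panel(acc[nzchar(acc)], net = net, label = label)
}

#' First-quartile hop distance to the safety panel
#'
#' For each query protein, collects BFS hop distances to every reachable
#' panel member (self-distance 0 if the protein is itself on the panel) and
#' returns the first quartile, computed with linear interpolation between
#' order statistics. If no panel member is reachable the node count of the
#' network is returned as an off-scale sentinel, with a warning.
#'
#' @param net an `interactome`.
#' @param proteins character vector of query accessions (must be in `net`).
#' @param panel a `vit_panel`.
#' @return named numeric vector of first-quartile distances.
#' @export
vit_q1_distance <- function(net, proteins, panel) {
  stopifnot(inherits(net, "interactome"), inherits(panel, "vit_panel"))
  unknown <- setdiff(proteins, nodes(net))
  if (length(unknown)) stop("unknown protein(s): ", paste(head(unknown, 5L), collapse = ", "))
  members <- unique(intersect(panel$accessions, nodes(net)))
  D <- igraph::distances(net$graph, v = members, to = proteins,
                         algorithm = "unweighted")
  res <- apply(D, 2L, function(col) {
    col <- col[is.finite(col)]
    if (length(col) == 0L) return(NA_real_)
    unname(quantile(col, probs = 0.25, type = 7))
  })
  if (anyNA(res)) {
    warning(sum(is.na(res)), " protein(s) cannot reach the panel; ",
            "sentinel distance = node count used")
    res[is.na(res)] <- igraph::vcount(net$graph)
  }
  setNames(res, proteins)
}

#' Assemble the 8-dimensional feature vectors
#'
#' Combines, per protein: the diffusion score, degree centrality,
#' betweenness, clustering coefficient, the two cluster-dispersion features
#' (DSD-spectral and Louvain partitions), the function conservation index
#' and the first-quartile panel distance — the fixed-order feature vector
#' consumed by the classifiers.
#'
#' @param net the `interactome` every input was computed on.
#' @param proteins accessions to featurize (must be nodes of `net`).
#' @param scores `diffusion_scores` from [propagate()].
#' @param k1 `module_partition` from [spectral_partition()].
#' @param ln `module_partition` from [louvain_partition()].
#' @param seeds the ADR `seed_set`.
#' @param ann `go_annotations`.
#' @param enriched `enriched_terms` from [fisher_enrichment()].
#' @param panel a `vit_panel`.
#' @param topology optional precomputed [topology_profile()] (recomputed if
#'   `NULL`).
#' @return data.frame, one row per protein (rownames = accession), with the
#'   8 numeric columns `guild_score`, `degree_centrality`, `betweenness`,
#'   `clustering_coefficient`, `pct_clusters_k1`, `pct_clusters_ln`,
#'   `function_index`, `vit_q1_distance`; all entries finite.
#' @export
assemble_features <- function(net, proteins, scores, k1, ln, seeds, ann,
                              enriched, panel, topology = NULL) {
  stopifnot(inherits(net, "interactome"))
  absent <- setdiff(proteins, nodes(net))
  if (length(absent)) {
    stop("protein(s) absent from the interactome: ",
         paste(head(absent, 5L), collapse = ", "))
  }
  if (is.null(topology)) topology <- topology_profile(net)
  for (p in proteins) {
    if (!p %in% names(scores$scores)) stop("protein ", p, " absent from diffusion scores")
  }
  fi <- vapply(proteins, function(p) {
    terms <- if (p %in% names(ann)) ann[[p]] else character()
    suppressWarnings(function_index(terms, enriched))
  }, numeric(1L))
  out <- data.frame(
    guild_score = unname(scores$scores[proteins]),
    degree_centrality = unname(topology$degree_centrality[proteins]),
    betweenness = unname(topology$betweenness[proteins]),
    clustering_coefficient = unname(topology$clustering_coefficient[proteins]),
    pct_clusters_k1 = unname(cluster_fraction(k1, seeds, proteins)),
    pct_clusters_ln = unname(cluster_fraction(ln, seeds, proteins)),
    function_index = unname(fi),
    vit_q1_distance = unname(suppressWarnings(vit_q1_distance(net, proteins, panel))),
    row.names = proteins
  )
  stopifnot(all(vapply(out, function(x) all(is.finite(x)), logical(1L))))
  out
}

#' Names of the 8 classifier features, in canonical order
#' @return character vector of length 8.
#' @export
feature_names <- function() {
  c("guild_score", "degree_centrality", "betweenness",
    "clustering_coefficient", "pct_clusters_k1", "pct_clusters_ln",
    "function_index", "vit_q1_distance")
}
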