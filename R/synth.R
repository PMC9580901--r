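#' Synthetic-fixture configuration
#'
#' Parameters of the generator that emulates the study conditions: a
#' scale-free interactome, an ADR module planted as a densified connected
#' neighborhood, GO terms enriched in that neighborhood, and a safety panel
#' placed preferentially near the module.
#'
#' @param n_nodes network size.
#' @param attachment_m edges added per node during preferential attachment.
#' @param module_size number of planted ADR-module proteins.
#' @param densify_prob probability of adding each absent within-module edge.
#' @param n_go_terms total number of GO terms.
#' @param module_term_count number of terms enriched on the module.
#' @param background_annotation_rate per-(node, term) background annotation
#'   probability.
#' @param planted_annotation_rate probability that a planted node carries a
#'   module term.
#' @param panel_size number of safety-panel proteins (default 48, the size
#'   of a typical preclinical safety screen panel).
#' @param rng_seed integer seed; fixtures are bit-reproducible per seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_nodes = 1000L, attachment_m = 3L, module_size = 30L,
                         densify_prob = 0.3, n_go_terms = 50L,
                         module_term_count = 5L,
                         background_annotation_rate = 0.1,
                         planted_annotation_rate = 0.8,
                         panel_size = 48L, rng_seed = 1L) {
  stopifnot(module_size < n_nodes, panel_size >= 1L,
            module_term_count <= n_go_terms,
            densify_prob >= 0, densify_prob <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment_m = as.integer(attachment_m),
                 module_size = as.integer(module_size),
                 densify_prob = densify_prob,
                 n_go_terms = as.integer(n_go_terms),
                 module_term_count = as.integer(module_term_count),
                 background_annotation_rate = background_annotation_rate,
                 planted_annotation_rate = planted_annotation_rate,
                 panel_size = as.integer(panel_size),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

#' Generate a scale-free interactome
#'
#' Preferential attachment with a pinned convention: the graph starts from
#' `m` unconnected nodes and each subsequent node attaches `m` edges to
#' distinct existing nodes drawn with probability proportional to
#' degree + 1, so the edge count is exactly `m * (n - m)`.
#'
#' @param n number of nodes (`n > m`).
#' @param m edges attached per incoming node (`m >= 1`).
#' @param rng_seed integer seed.
#' @return an `interactome` with synthetic accessions `P00001`...
#' @export
generate_interactome <- function(n, m, rng_seed = 1L) {
  if (!(n > m && m >= 1L)) stop("need n > m >= 1")
  set.seed(rng_seed)
  nm <- sprintf("P%05d", seq_len(n))
  deg <- integer(n)
  from <- character(m * (n - m)); to <- character(m * (n - m))
  e <- 0L
  for (i in (m + 1L):n) {
    existing <- seq_len(i - 1L)
    targets <- sample(existing, m, prob = deg[existing] + 1)
    for (t in targets) {
      e <- e + 1L
      from[e] <- nm[i]; to[e] <- nm[t]
      deg[t] <- deg[t] + 1L
    }
    deg[i] <- deg[i] + m
  }
  as_interactome(data.frame(from, to, stringsAsFactors = FALSE),
                 label = sprintf("synthetic scale-free n=%d m=%d", n, m),
                 largest_component = FALSE)
}

#' Plant an ADR module in a network
#'
#' Selects a connected subgraph of `module_size` nodes by seeded BFS from a
#' random anchor, densifies it by adding each absent internal edge with
#' probability `densify_prob`, and splits the planted nodes into an ADR seed
#' half (rounded up) and held-out positives — mimicking ADR-associated
#' proteins concentrating in a local network neighborhood.
#'
#' @param net an `interactome` (modified copy returned).
#' @param module_size number of planted nodes.
#' @param densify_prob probability per absent internal edge.
#' @param rng_seed integer seed.
#' @param adr_label label for the synthetic ADR.
#' @return list with `net` (densified network), `seeds` (a `seed_set`),
#'   `planted` (all planted accessions), `heldout` (planted non-seeds).
#' @export
plant_adr_module <- function(net, module_size = 30L, densify_prob = 0.3,
                             rng_seed = 1L, adr_label = "SYN_ADR") {
  stopifnot(inherits(net, "interactome"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (module_size > n) stop("module_size exceeds network size")
  set.seed(rng_seed)
  anchor <- sample(igraph::V(g)$name, 1L)
  ord <- igraph::bfs(g, root = anchor, order = TRUE)$order
  planted <- igraph::V(g)$name[as.integer(ord)[seq_len(module_size)]]
  pairs <- utils::combn(planted, 2L)
  have <- igraph::get_edge_ids(g, as.vector(pairs)) > 0
  absent <- which(!have)
  add <- absent[stats::runif(length(absent)) < densify_prob]
  if (length(add)) {
    g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
  }
  n_seed <- ceiling(module_size / 2)
  seed_acc <- sort(sample(planted, n_seed))
  net$graph <- g
  list(net = net,
       seeds = seed_set(seed_acc, net, adr_label),
       planted = planted,
       heldout = setdiff(planted, seed_acc))
}

#' Generate GO annotations and a safety panel for a fixture
#'
#' The first `module_term_count` GO terms are enriched on the planted
#' module (each planted node carries each of them with
#' `planted_annotation_rate`, background nodes with
#' `background_annotation_rate`); the remaining terms are annotated
#' uniformly at the background rate. The panel is sampled without
#' replacement with weight `0.5^d`, `d` the hop distance to the planted
#' module, placing it at a controllably short network distance.
#'
#' @param net an `interactome`.
#' @param planted planted accessions.
#' @param cfg a `synth_config`.
#' @return list with `annotations` (`go_annotations`), `panel`
#'   (`vit_panel`) and `module_terms` (the enriched GO ids).
#' @export
generate_annotations_and_panel <- function(net, planted, cfg) {
  stopifnot(inherits(net, "interactome"), inherits(cfg, "synth_config"))
  nm <- nodes(net)
  if (!all(planted %in% nm)) stop("planted nodes must be in the network")
  set.seed(cfg$rng_seed + 1L)
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  module_terms <- terms[seq_len(cfg$module_term_count)]
  is_planted <- nm %in% planted
  ann <- lapply(setNames(seq_along(nm), nm), function(i) {
    rate <- ifelse(rep(is_planted[i], cfg$n_go_terms) &
                     terms %in% module_terms,
                   cfg$planted_annotation_rate,
                   cfg$background_annotation_rate)
    terms[stats::runif(cfg$n_go_terms) < rate]
  })
  ann <- ann[lengths(ann) > 0L]
  d <- suppressWarnings(
    apply(igraph::distances(net$graph, v = planted, algorithm = "unweighted"),
          2L, min))
  d[!is.finite(d)] <- max(d[is.finite(d)]) + 1
  panel_acc <- sample(nm, cfg$panel_size, prob = 0.5^d)
  list(annotations = go_annotation_map(ann),
       panel = vit_panel(sort(panel_acc), net, "synthetic safety panel"),
       module_terms = module_terms)
}

#' Generate a complete synthetic fixture
#'
#' Composes the interactome, planted-module, annotation and panel
#' generators into a fixture whose files are drop-in inputs for the real
#' pipeline: one synthetic ADR whose associated proteins are the seed half
#' of the planted module, with ground-truth planted/background labels.
#'
#' @param cfg a `synth_config`.
#' @return object of class `synthetic_fixture`: `net`, `associations`,
#'   `annotations`, `panel`, `seeds`, `heldout`, `truth` (named vector,
#'   `"planted"`/`"background"`), `module_terms`, `cfg`.
#' @export
generate_fixture <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  net <- generate_interactome(cfg$n_nodes, cfg$attachment_m, cfg$rng_seed)
  mod <- plant_adr_module(net, cfg$module_size, cfg$densify_prob,
                          cfg$rng_seed + 2L)
  ap <- generate_annotations_and_panel(mod$net, mod$planted, cfg)
  truth <- setNames(ifelse(nodes(mod$net) %in% mod$planted,
                           "planted", "background"), nodes(mod$net))
  assoc <- adr_associations(data.frame(
    adr_label = mod$seeds$adr_label, soc_label = "SYN_SOC",
    accession = mod$seeds$accessions, stringsAsFactors = FALSE))
  structure(list(net = mod$net, associations = assoc,
                 annotations = ap$annotations, panel = ap$panel,
                 seeds = mod$seeds, heldout = mod$heldout, truth = truth,
                 module_terms = ap$module_terms, cfg = cfg),
            class = "synthetic_fixture")
}

#' Write a synthetic fixture to disk
#'
#' Writes `network.tsv` (edge list), `associations.tsv`, `annotations.tsv`,
#' `panel.txt` and `truth.tsv` in the formats the pipeline loaders read.
#'
#' @param fix a `synthetic_fixture`.
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  stopifnot(inherits(fix, "synthetic_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(network = file.path(dir, "network.tsv"),
             associations = file.path(dir, "associations.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             panel = file.path(dir, "panel.txt"),
             truth = file.path(dir, "truth.tsv"))
  el <- igraph::as_edgelist(fix$net$graph)
  write.table(el, paths["network"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fix$associations, paths["associations"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann_df <- data.frame(
    accession = rep(names(fix$annotations), lengths(fix$annotations)),
    go_id = unlist(fix$annotations, use.names = FALSE))
  write.table(ann_df, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(fix$panel$accessions, paths["panel"])
  write.table(data.frame(accession = names(fix$truth), status = fix$truth),
              paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
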