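#' Read a protein-ADR association table
#'
#' Expects a TSV with a header and columns `adr_label`, `soc_label`,
#' `accession` (one protein-ADR association per row, MedDRA preferred-term
#' and system-organ-class labels).
#'
#' @param path TSV file path.
#' @return an `adr_associations` data.frame.
#' @export
read_associations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("adr_label", "soc_label", "accession")
  if (!all(need %in% names(tab))) {
    stop("association table must have header columns: ",
         paste(need, collapse = ", "))
  }
  adr_associations(tab[need])
}

#' Construct an association table from a data frame
#' @param records data.frame with columns `adr_label`, `soc_label`,
#'   `accession`.
#' @return an `adr_associations` data.frame (duplicate (ADR, accession)
#'   pairs collapsed).
#' @export
adr_associations <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("adr_label", "soc_label", "accession") %in% names(records)))
  if (any(!nzchar(records$adr_label)) || any(!nzchar(records$accession))) {
    stop("empty adr_label or accession")
  }
  records <- records[!duplicated(records[c("adr_label", "accession")]), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("adr_associations", "data.frame")
  records
}

#' Filter associations for modelability
#'
#' Drops ADRs with too few associated proteins; SOCs left with fewer than
#' `min_adrs_per_soc` ADRs are flagged ineligible for SOC-level modeling
#' (their member ADRs are still modeled individually).
#'
#' @param tab an `adr_associations` table.
#' @param min_proteins_per_adr minimum proteins per retained ADR.
#' @param min_adrs_per_soc minimum retained ADRs for a SOC-level model.
#' @return the filtered `adr_associations` with attribute `eligible_socs`
#'   (character vector of SOC labels eligible for SOC-level models).
#' @export
filter_associations <- function(tab, min_proteins_per_adr = 10L,
                                min_adrs_per_soc = 5L) {
  stopifnot(inherits(tab, "adr_associations"))
  n_per_adr <- table(tab$adr_label)
  keep_adrs <- names(n_per_adr)[n_per_adr >= min_proteins_per_adr]
  out <- tab[tab$adr_label %in% keep_adrs, , drop = FALSE]
  if (nrow(out) == 0L) stop("no ADR passes min_proteins_per_adr = ", min_proteins_per_adr)
  message(length(keep_adrs), "/", length(n_per_adr), " ADRs retained")
  adrs_per_soc <- tapply(out$adr_label, out$soc_label,
                         function(x) length(unique(x)))
  eligible <- names(adrs_per_soc)[adrs_per_soc >= min_adrs_per_soc]
  rownames(out) <- NULL
  class(out) <- c("adr_associations", "data.frame")
  attr(out, "eligible_socs") <- eligible
  out
}

#' Merge ADR associations to SOC-level pseudo-ADRs
#'
#' Builds one pseudo-ADR per system organ class whose protein set is the
#' deduplicated union of its member ADRs' proteins, enabling SOC-level
#' models. If the table carries an `eligible_socs` attribute (from
#' [filter_associations()]) only those SOCs are merged.
#'
#' @param tab an `adr_associations` table.
#' @return an `adr_associations` table with one row per (SOC, accession);
#'   `adr_label` is set to the SOC label.
#' @export
merge_to_soc <- function(tab) {
  stopifnot(inherits(tab, "adr_associations"))
  eligible <- attr(tab, "eligible_socs")
  if (!is.null(eligible)) tab <- tab[tab$soc_label %in% eligible, , drop = FALSE]
  out <- unique(data.frame(adr_label = tab$soc_label,
                           soc_label = tab$soc_label,
                           accession = tab$accession,
                           stringsAsFactors = FALSE))
  adr_associations(out)
}

#' DIAMOnD module expansion
#'
#' Iteratively grows the ADR seed module: at each step every candidate with
#' at least one link into the current module (size `s0`) is scored by the
#' hypergeometric tail probability of its connectivity,
#' `p = P(X >= ks)` with `X ~ Hypergeom(N = node count, s0 successes,
#' draws = candidate degree)`, and the most significant candidate (lowest
#' `p`; ties broken by lower degree, then lexicographic accession) joins
#' the module. Each added protein carries a DIAMOnD score `1 - p`, so
#' scores near 1 mean tight connectivity to the ADR module.
#'
#' @param net an `interactome`.
#' @param seeds a `seed_set`.
#' @param max_steps maximum number of proteins to add.
#' @return object of class `diamond_ranking`: data.frame `steps` with
#'   columns `accession`, `step_index`, `p_hyper`, `score`.
#' @export
diamond_expand <- function(net, seeds, max_steps = 200L) {
  stopifnot(inherits(net, "interactome"), inherits(seeds, "seed_set"))
  seeds <- seed_set(seeds$accessions, net, seeds$adr_label)
  g <- net$graph
  nm <- igraph::V(g)$name
  N <- length(nm)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- nm
  deg <- lengths(adj)
  in_set <- setNames(logical(N), nm)
  in_set[seeds$accessions] <- TRUE
  # ks = links from each node into the current set
  ks <- setNames(integer(N), nm)
  for (s in seeds$accessions) ks[adj[[s]]] <- ks[adj[[s]]] + 1L
  steps <- vector("list", max_steps)
  n_added <- 0L
  for (step in seq_len(max_steps)) {
    cand <- nm[!in_set & ks >= 1L]
    if (length(cand) == 0L) {
      warning("DIAMOnD ranking truncated at step ", step - 1L,
              ": no connected candidate left")
      break
    }
    s0 <- sum(in_set)
    p <- phyper(ks[cand] - 1L, s0, N - s0, deg[cand], lower.tail = FALSE)
    ord <- order(p, deg[cand], cand)
    best <- cand[ord[1L]]
    n_added <- step
    steps[[step]] <- data.frame(accession = best, step_index = step,
                                p_hyper = unname(p[ord[1L]]),
                                score = 1 - unname(p[ord[1L]]),
                                stringsAsFactors = FALSE)
    in_set[best] <- TRUE
    ks[adj[[best]]] <- ks[adj[[best]]] + 1L
  }
  structure(list(steps = do.call(rbind, steps[seq_len(n_added)]),
                 adr_label = seeds$adr_label),
            class = "diamond_ranking")
}

#' Training-set configuration
#'
#' Pins a DIAMOnD score threshold, a negative:positive imbalance ratio and
#' a sampling seed. The menus mirror the tested grid (thresholds 0.6, 0.7,
#' 0.8, 0.9; ratios 1, 1.5, 3, 5); other values require `override = TRUE`.
#'
#' @param diamond_threshold minimum DIAMOnD score for augmented positives.
#' @param neg_ratio negatives per positive.
#' @param rng_seed integer seed for negative sampling.
#' @param override allow values outside the standard menus.
#' @return object of class `training_config`.
#' @export
training_config <- function(diamond_threshold = 0.9, neg_ratio = 1.0,
                            rng_seed = 1L, override = FALSE) {
  if (!override) {
    if (!diamond_threshold %in% c(0.6, 0.7, 0.8, 0.9)) {
      stop("diamond_threshold must be one of 0.6, 0.7, 0.8, 0.9 (or use override)")
    }
    if (!neg_ratio %in% c(1.0, 1.5, 3.0, 5.0)) {
      stop("neg_ratio must be one of 1, 1.5, 3, 5 (or use override)")
    }
  }
  structure(list(diamond_threshold = diamond_threshold, neg_ratio = neg_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "training_config")
}

#' Build a labeled per-ADR training set
#'
#' Positives are the ADR seeds plus every DIAMOnD-ranked protein whose score
#' reaches the configured threshold; negatives are drawn uniformly at random
#' (seeded) from the remaining network nodes whose DIAMOnD score (0 when
#' unranked) is below the threshold, at `round(neg_ratio * positives)`.
#'
#' @param net an `interactome`.
#' @param seeds the ADR `seed_set`.
#' @param ranking a `diamond_ranking` for those seeds.
#' @param features feature data.frame from [assemble_features()] covering
#'   every node of `net` (rownames = accession).
#' @param config a `training_config`.
#' @return object of class `labeled_dataset`: list with `data` (data.frame
#'   of accession, 8 features, `label` in {-1, +1}), `config`, `adr_label`.
#' @export
build_training_sets <- function(net, seeds, ranking, features, config) {
  stopifnot(inherits(net, "interactome"), inherits(seeds, "seed_set"),
            inherits(ranking, "diamond_ranking"),
            inherits(config, "training_config"))
  all_nodes <- nodes(net)
  miss <- setdiff(all_nodes, rownames(features))
  if (length(miss)) {
    stop("features missing for ", length(miss), " node(s), e.g. ", miss[1L])
  }
  score <- setNames(rep(0, length(all_nodes)), all_nodes)
  if (!is.null(ranking$steps)) {
    score[ranking$steps$accession] <- ranking$steps$score
  }
  positives <- union(seeds$accessions,
                     names(score)[score >= config$diamond_threshold])
  pool <- setdiff(all_nodes[score[all_nodes] < config$diamond_threshold],
                  positives)
  n_neg <- round(config$neg_ratio * length(positives))
  if (length(pool) < n_neg) {
    stop("negative pool too small: need ", n_neg, ", have ", length(pool))
  }
  negatives <- local({
    set.seed(config$rng_seed)
    sample(pool, n_neg)
  })
  acc <- c(positives, negatives)
  data <- cbind(data.frame(accession = acc, stringsAsFactors = FALSE),
                features[acc, feature_names(), drop = FALSE],
                label = c(rep(1L, length(positives)), rep(-1L, n_neg)))
  rownames(data) <- NULL
  structure(list(data = data, config = config, adr_label = seeds$adr_label),
            class = "labeled_dataset")
}

#' Write a labeled dataset as TSV
#' @param ds a `labeled_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_dataset <- function(ds, path) {
  write.table(ds$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
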