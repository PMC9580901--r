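#' Shared per-network context for featurization
#'
#' Computes the ADR-independent structures once per network: the topology
#' profile and the two module partitions (DSD + spectral, Louvain).
#'
#' @param net an `interactome`.
#' @param spectral_k number of DSD-spectral modules (`NULL` = `round(n/15)`).
#' @param walk_length DSD walk length.
#' @param resolution Louvain resolution.
#' @param rng_seed integer seed.
#' @return list of class `network_context` with `net`, `topology`, `k1`,
#'   `ln`.
#' @export
network_context <- function(net, spectral_k = NULL, walk_length = 5L,
                            resolution = 1.0, rng_seed = 1L) {
  stopifnot(inherits(net, "interactome"))
  d <- dsd_matrix(net, walk_length)
  structure(list(net = net,
                 topology = topology_profile(net),
                 k1 = spectral_partition(d, spectral_k, rng_seed),
                 ln = louvain_partition(net, resolution, rng_seed)),
            class = "network_context")
}

#' Per-ADR feature table for every network node
#'
#' Runs the ADR-specific stages (seed propagation, GO enrichment of the
#' top-ranked proteins) on top of a shared [network_context()] and
#' assembles the 8-feature vector for every node.
#'
#' @param ctx a `network_context`.
#' @param seeds the ADR `seed_set`.
#' @param ann `go_annotations`.
#' @param panel a `vit_panel`.
#' @param alpha diffusion restart-complement weight.
#' @param top_k number of top-ranked proteins used as the enrichment study
#'   set.
#' @param enrich_alpha BH-adjusted significance level for enrichment.
#' @return list of class `adr_features` with `features` (data.frame from
#'   [assemble_features()] over all nodes), `scores`, `enriched`, `seeds`.
#' @export
adr_feature_table <- function(ctx, seeds, ann, panel, alpha = 0.5,
                              top_k = 100L, enrich_alpha = 0.05) {
  stopifnot(inherits(ctx, "network_context"))
  scores <- propagate(ctx$net, seeds, alpha = alpha)
  study <- top_ranked(scores, top_k)
  enriched <- suppressWarnings(
    fisher_enrichment(ann, study, background = nodes(ctx$net),
                      alpha = enrich_alpha))
  feats <- assemble_features(ctx$net, nodes(ctx$net), scores, ctx$k1, ctx$ln,
                             seeds, ann, enriched, panel,
                             topology = ctx$topology)
  structure(list(features = feats, scores = scores, enriched = enriched,
                 seeds = seeds),
            class = "adr_features")
}

.default_run_config <- function() {
  list(alpha = 0.5, top_k_enrichment = 100L, enrich_alpha = 0.05,
       spectral_k = NULL, walk_length = 5L, resolution = 1.0,
       min_proteins_per_adr = 10L, min_adrs_per_soc = 5L,
       soc_models = FALSE, diamond_max_steps = 200L,
       diamond_thresholds = 0.9, neg_ratios = 1.0,
       classifiers = c("SVM", "RF", "NN"), rng_seed = 1L)
}

.read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(.default_run_config(), config)
  for (p in c("network", "associations", "annotations", "panel")) {
    if (is.null(cfg[[p]])) stop("config is missing required path: ", p)
    if (!file.exists(cfg[[p]])) stop("input path does not exist: ", cfg[[p]])
  }
  if (is.null(cfg$output_dir)) stop("config is missing output_dir")
  cfg
}

#' Train per-ADR (and optionally per-SOC) model bundles
#'
#' Full training orchestration: loads the network, association table, GO
#' annotations and safety panel; filters ADRs; and for every retained ADR
#' (and eligible SOC when `soc_models` is on) expands the seeds with
#' DIAMOnD, builds a labeled dataset for each (threshold, ratio)
#' configuration, trains each requested classifier with grid search and
#' 5-fold CV, keeps the best configuration per classifier, and persists
#' bundles, feature tables and CV reports under `output_dir`.
#'
#' @param config path to a YAML run configuration, or an equivalent named
#'   list. Required entries: `network`, `associations`, `annotations`,
#'   `panel`, `output_dir`. See the package vignette for the optional ones.
#' @return data.frame summary (one row per ADR x classifier x
#'   configuration), invisibly; also written to
#'   `output_dir/training_summary.tsv`.
#' @export
run_train <- function(config) {
  cfg <- .read_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  net <- load_interactome(cfg$network)
  assoc <- filter_associations(read_associations(cfg$associations),
                               cfg$min_proteins_per_adr, cfg$min_adrs_per_soc)
  ann <- read_go_annotations(cfg$annotations)
  panel <- read_panel(cfg$panel, net)
  ctx <- network_context(net, cfg$spectral_k, cfg$walk_length,
                         cfg$resolution, cfg$rng_seed)
  units <- split(assoc$accession, assoc$adr_label)
  if (isTRUE(cfg$soc_models)) {
    soc <- merge_to_soc(assoc)
    units <- c(units, split(soc$accession, paste0("SOC:", soc$adr_label)))
  }
  summary_rows <- list()
  for (adr in names(units)) {
    seeds <- seed_set(units[[adr]], net, adr)
    adr_dir <- file.path(cfg$output_dir, gsub("[^A-Za-z0-9._-]+", "_", adr))
    dir.create(adr_dir, showWarnings = FALSE)
    ft <- adr_feature_table(ctx, seeds, ann, panel, cfg$alpha,
                            cfg$top_k_enrichment, cfg$enrich_alpha)
    write.table(cbind(accession = rownames(ft$features), ft$features),
                file.path(adr_dir, "features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ranking <- diamond_expand(net, seeds, cfg$diamond_max_steps)
    for (thr in cfg$diamond_thresholds) {
      for (ratio in cfg$neg_ratios) {
        tc <- training_config(thr, ratio, cfg$rng_seed)
        ds <- build_training_sets(net, seeds, ranking, ft$features, tc)
        for (kind in cfg$classifiers) {
          bundle <- train_model(ds, kind, rng_seed = cfg$rng_seed)
          tag <- sprintf("%s_thr%s_ratio%s", kind, thr, ratio)
          saveRDS(bundle, file.path(adr_dir, paste0(tag, ".rds")))
          write.table(bundle$cv_report,
                      file.path(adr_dir, paste0(tag, "_cv_report.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          mean_auc <- bundle$cv_report$roc_auc[is.na(bundle$cv_report$fold)]
          summary_rows[[length(summary_rows) + 1L]] <- data.frame(
            adr_label = adr, classifier = kind, diamond_threshold = thr,
            neg_ratio = ratio, n_pos = sum(ds$data$label == 1L),
            n_neg = sum(ds$data$label == -1L), mean_roc_auc = mean_auc,
            stringsAsFactors = FALSE)
        }
      }
    }
    # keep the best configuration per classifier as <kind>_best.rds
    adr_summary <- do.call(rbind, summary_rows)
    adr_summary <- adr_summary[adr_summary$adr_label == adr, , drop = FALSE]
    for (kind in cfg$classifiers) {
      rows <- adr_summary[adr_summary$classifier == kind, , drop = FALSE]
      best <- select_best_model(rows)
      tag <- sprintf("%s_thr%s_ratio%s", kind, best$diamond_threshold,
                     best$neg_ratio)
      file.copy(file.path(adr_dir, paste0(tag, ".rds")),
                file.path(adr_dir, paste0(kind, "_best.rds")),
                overwrite = TRUE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  write.table(summary, file.path(cfg$output_dir, "training_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Predict ADR liability for a protein list
#'
#' Looks up each requested protein in the per-ADR feature tables written by
#' [run_train()], applies the three best-configuration classifier bundles
#' and combines them with the jury, consensus and red-flag rules. Proteins
#' absent from the network are reported with status `NOT_IN_NETWORK`.
#'
#' @param model_dir the `output_dir` of a [run_train()] run.
#' @param proteins character vector of accessions, or the path of a
#'   plain-text accession list.
#' @param adr_names ADR (or `SOC:` prefixed) model names to apply.
#' @param out optional path of the TSV report to write.
#' @return data.frame with one row per (protein, ADR): per-classifier class
#'   and posterior, jury/consensus/red-flag results and a `status` column.
#' @export
run_predict <- function(model_dir, proteins, adr_names, out = NULL) {
  if (length(proteins) == 1L && file.exists(proteins)) {
    proteins <- trimws(readLines(proteins, warn = FALSE))
    proteins <- proteins[nzchar(proteins)]
  }
  rows <- list()
  for (adr in adr_names) {
    adr_dir <- file.path(model_dir, gsub("[^A-Za-z0-9._-]+", "_", adr))
    if (!dir.exists(adr_dir)) {
      avail <- basename(list.dirs(model_dir, recursive = FALSE))
      stop("no model for '", adr, "'; available: ",
           paste(avail, collapse = ", "))
    }
    feats <- read.delim(file.path(adr_dir, "features.tsv"),
                        stringsAsFactors = FALSE)
    rownames(feats) <- feats$accession
    bundles <- lapply(setNames(nm = c("SVM", "RF", "NN")), function(kind) {
      readRDS(file.path(adr_dir, paste0(kind, "_best.rds")))
    })
    for (p in proteins) {
      if (!p %in% rownames(feats)) {
        row <- data.frame(accession = p, adr_label = adr,
                          status = "NOT_IN_NETWORK")
        for (kind in c("SVM", "RF", "NN")) {
          row[[paste0(tolower(kind), "_class")]] <- NA_integer_
          row[[paste0(tolower(kind), "_posterior")]] <- NA_real_
        }
        row$jury_class <- NA_integer_
        row$consensus_score <- NA_real_
        row$consensus_class <- NA_integer_
        row$redflag_class <- NA_integer_
        rows[[length(rows) + 1L]] <- row
        next
      }
      preds <- do.call(rbind, lapply(bundles, function(b) {
        predict_model(b, feats[p, , drop = FALSE])
      }))
      votes <- combine_votes(preds)
      row <- data.frame(accession = p, adr_label = adr, status = "OK")
      for (kind in c("SVM", "RF", "NN")) {
        pr <- preds[preds$kind == kind, ]
        row[[paste0(tolower(kind), "_class")]] <- pr$class
        row[[paste0(tolower(kind), "_posterior")]] <- pr$posterior
      }
      row$jury_class <- votes$jury_class
      row$consensus_score <- votes$consensus_score
      row$consensus_class <- votes$consensus_class
      row$redflag_class <- votes$redflag_class
      rows[[length(rows) + 1L]] <- row
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out)) {
    write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

#' Generate and write a synthetic fixture from a configuration
#'
#' @param config path to a YAML file with `synth` (a [synth_config()]
#'   argument list) and `output_dir`, or an equivalent named list.
#' @return the fixture file paths, invisibly.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config is missing output_dir")
  cfg <- do.call(synth_config, as.list(config$synth))
  fix <- generate_fixture(cfg)
  write_fixture(fix, config$output_dir)
}
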