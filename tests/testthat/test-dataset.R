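make_assoc <- function() {
  adr_associations(data.frame(
    adr_label = c(rep("ADR_A", 12), rep("ADR_B", 3), rep("ADR_C", 10)),
    soc_label = c(rep("SOC1", 15), rep("SOC2", 10)),
    accession = c(sprintf("P%02d", 1:12), sprintf("Q%02d", 1:3),
                  sprintf("R%02d", 1:10))))
}

test_that("association filtering applies both thresholds", {
  tab <- make_assoc()
  expect_message(out <- filter_associations(tab, min_proteins_per_adr = 10,
                                            min_adrs_per_soc = 2),
                 "retained")
  expect_setequal(unique(out$adr_label), c("ADR_A", "ADR_C"))  # ADR_B dropped
  # SOC1 retains 1 ADR < 2 -> ineligible; its ADR is still modeled
  expect_equal(attr(out, "eligible_socs"), character(0))
  expect_true("ADR_A" %in% out$adr_label)
  expect_error(suppressMessages(filter_associations(tab, 99)), "no ADR passes")
})

test_that("duplicate (ADR, accession) pairs collapse and schema is enforced", {
  dup <- data.frame(adr_label = c("A", "A"), soc_label = "S",
                    accession = c("P1", "P1"))
  expect_equal(nrow(adr_associations(dup)), 1)
  f <- withr::local_tempfile(lines = c("adr\tsoc\tacc", "A\tS\tP1"))
  expect_error(read_associations(f), "header columns")
})

test_that("SOC merging unions member-ADR proteins", {
  tab <- adr_associations(data.frame(
    adr_label = c("A1", "A1", "A1", "A2", "A2", "A2", "B1"),
    soc_label = c(rep("SOC1", 6), "SOC2"),
    accession = c("P1", "P2", "P3", "P3", "P4", "P5", "P9")))
  soc <- merge_to_soc(tab)
  soc1 <- soc$accession[soc$adr_label == "SOC1"]
  expect_setequal(soc1, c("P1", "P2", "P3", "P4", "P5"))  # shared P3 deduped
  expect_equal(soc$accession[soc$adr_label == "SOC2"], "P9")
  # union contains every member ADR's set
  expect_true(all(tab$accession[tab$soc_label == "SOC1"] %in% soc1))
})

test_that("DIAMOnD step p-values match direct hypergeometric tail sums", {
  set.seed(31)
  for (i in 1:12) {
    net <- random_test_graph(sample(6:12, 1), connected = TRUE)
    nm <- nodes(net)
    N <- length(nm)
    seeds <- seed_set(sample(nm, sample(2:4, 1)), net)
    rk <- suppressWarnings(diamond_expand(net, seeds, max_steps = 5L))
    A <- adj_matrix(net)
    deg <- rowSums(A)
    current <- seeds$accessions
    for (j in seq_len(nrow(rk$steps))) {
      s0 <- length(current)
      cand <- setdiff(nm, current)
      ks <- sapply(cand, function(v) sum(A[v, current]))
      cand <- cand[ks >= 1]
      ks <- ks[ks >= 1]
      p <- mapply(function(v, k_in) oracle_hyper_tail(k_in, N, s0, deg[[v]]),
                  cand, ks)
      step <- rk$steps[j, ]
      expect_equal(step$p_hyper, min(p), tolerance = 1e-9)
      expect_equal(step$score, 1 - step$p_hyper)
      expect_equal(step$step_index, j)
      # the added node attains the minimal p (ties allowed)
      expect_equal(p[[step$accession]], min(p), tolerance = 1e-12)
      current <- c(current, step$accession)
    }
  }
})

test_that("DIAMOnD worked example: N=10, s0=3, candidate deg 2 fully linked", {
  # star-of-seeds construction: candidate X has 2 edges, both into the seed
  # set {S1,S2,S3}; 10 nodes in total
  edges <- rbind(
    c("S1", "S2"), c("S2", "S3"),           # seeds connected
    c("X", "S1"), c("X", "S2"),             # candidate, deg 2, ks 2
    c("S3", "F1"),                           # filler tree keeping graph connected
    c("F1", "F2"), c("F2", "F3"), c("F3", "F4"), c("F4", "F5"),
    c("F5", "F6"))
  net <- as_interactome(as.data.frame(edges))
  expect_equal(length(nodes(net)), 10)
  seeds <- seed_set(c("S1", "S2", "S3"), net)
  rk <- suppressWarnings(diamond_expand(net, seeds, max_steps = 1L))
  expect_equal(rk$steps$accession[1], "X")
  expect_equal(rk$steps$p_hyper[1], 3 / 45, tolerance = 1e-12)
  expect_equal(rk$steps$score[1], 1 - 3 / 45, tolerance = 1e-12)
})

test_that("training config menus are enforced unless overridden", {
  expect_error(training_config(0.65), "diamond_threshold")
  expect_error(training_config(0.9, 2.0), "neg_ratio")
  expect_s3_class(training_config(0.65, 2.0, override = TRUE),
                  "training_config")
})

test_that("labeled datasets have the configured composition", {
  fix <- generate_fixture(synth_config(n_nodes = 200, module_size = 12,
                                       panel_size = 8, rng_seed = 17))
  ctx <- network_context(fix$net, rng_seed = 17)
  ft <- adr_feature_table(ctx, fix$seeds, fix$annotations, fix$panel)
  rk <- diamond_expand(fix$net, fix$seeds, 40)
  for (ratio in c(1.0, 3.0)) {
    ds <- build_training_sets(fix$net, fix$seeds, rk, ft$features,
                              training_config(0.9, ratio, 17))
    n_pos <- sum(ds$data$label == 1)
    n_neg <- sum(ds$data$label == -1)
    expect_equal(n_neg, round(ratio * n_pos))
    # positives = seeds + ranked above threshold
    expected_pos <- union(fix$seeds$accessions,
                          rk$steps$accession[rk$steps$score >= 0.9])
    expect_setequal(ds$data$accession[ds$data$label == 1], expected_pos)
    # labels are disjoint by construction
    expect_equal(anyDuplicated(ds$data$accession), 0)
    # negatives avoid high-score ranked nodes
    neg <- ds$data$accession[ds$data$label == -1]
    high <- rk$steps$accession[rk$steps$score >= 0.9]
    expect_length(intersect(neg, high), 0)
  }
  # identical seed -> identical negative sample; different seed -> differs
  d1 <- build_training_sets(fix$net, fix$seeds, rk, ft$features,
                            training_config(0.9, 1.0, 42))
  d2 <- build_training_sets(fix$net, fix$seeds, rk, ft$features,
                            training_config(0.9, 1.0, 42))
  expect_identical(d1$data, d2$data)
  # impossible demand errors with the deficit stated
  expect_error(build_training_sets(fix$net, fix$seeds, rk, ft$features,
                                   training_config(0.9, 50, 1, override = TRUE)),
               "negative pool too small")
})
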