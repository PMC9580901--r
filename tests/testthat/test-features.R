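test_that("Fisher enrichment equals the exact hypergeometric tail", {
  # background of 20, study of 5, term carried by exactly the 5 study
  # proteins: p = 1 / C(20, 5)
  background <- sprintf("B%02d", 1:20)
  study <- background[1:5]
  ann <- go_annotation_map(setNames(rep(list("GO:0000001"), 5), study))
  res <- fisher_enrichment(ann, study, background)
  expect_equal(res$terms$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$terms$go_id, "GO:0000001")

  # a term carried only outside the study is never tested/retained
  ann2 <- go_annotation_map(c(setNames(rep(list("GO:0000001"), 5), study),
                              list(B10 = "GO:0000002")))
  res2 <- fisher_enrichment(ann2, study, background)
  expect_false("GO:0000002" %in% res2$tested$go_id)

  # term present in study at background frequency -> large p, dropped
  ann3 <- go_annotation_map(setNames(rep(list("GO:0000003"), 20), background))
  res3 <- fisher_enrichment(ann3, study, background)
  expect_equal(res3$tested$p_value, 1, tolerance = 1e-12)
  expect_equal(nrow(res3$terms), 0)

  expect_error(fisher_enrichment(ann, character(), background), "empty")
  expect_error(fisher_enrichment(ann, "Z9", background), "subset")
})

test_that("BH adjustment matches the step-up formula", {
  # raw p (0.01, 0.04) over 2 tests -> adjusted (0.02, 0.04)
  background <- sprintf("B%02d", 1:30)
  study <- background[1:6]
  # craft two terms with different enrichment strengths
  ann <- go_annotation_map(list(
    B01 = c("GO:0000001", "GO:0000002"), B02 = c("GO:0000001", "GO:0000002"),
    B03 = c("GO:0000001", "GO:0000002"), B04 = "GO:0000001",
    B07 = "GO:0000002", B08 = "GO:0000002"))
  res <- fisher_enrichment(ann, study, background, alpha = 1)
  expect_equal(res$tested$adjusted_p,
               p.adjust(res$tested$p_value, "BH"), tolerance = 1e-12)
  expect_equal(res$tested$p_value, sort(res$tested$p_value))
})

test_that("function index is the enriched-term overlap fraction", {
  enr <- structure(list(terms = data.frame(
    go_id = sprintf("GO:%07d", 1:4), p_value = rep(0.001, 4),
    adjusted_p = rep(0.004, 4)), alpha = 0.05), class = "enriched_terms")
  expect_equal(function_index(sprintf("GO:%07d", 1:2), enr), 0.5)
  expect_equal(function_index(sprintf("GO:%07d", 1:4), enr), 1.0)
  expect_equal(function_index("GO:0000099", enr), 0)
  expect_equal(function_index(character(), enr), 0)
  # duplicates in the protein's term list do not inflate the index
  expect_equal(function_index(rep("GO:0000001", 3), enr), 0.25)
  empty <- structure(list(terms = data.frame(go_id = character(),
                                             p_value = numeric(),
                                             adjusted_p = numeric()),
                          alpha = 0.05), class = "enriched_terms")
  expect_warning(v <- function_index("GO:0000001", empty), "empty")
  expect_equal(v, 0)
})

test_that("GO readers parse GAF and TSV and validate ids", {
  gaf <- withr::local_tempfile(lines = c(
    "!gaf-version: 2.2",
    paste(c("UniProt", "P1", "G1", "", "GO:0000001", rep("x", 12)), collapse = "\t"),
    paste(c("UniProt", "P2", "G2", "NOT", "GO:0000001", rep("x", 12)), collapse = "\t"),
    paste(c("UniProt", "P1", "G1", "", "GO:0000002", rep("x", 12)), collapse = "\t")))
  ann <- read_go_annotations(gaf)
  expect_setequal(ann$P1, c("GO:0000001", "GO:0000002"))
  expect_false("P2" %in% names(ann))

  tsv <- withr::local_tempfile(lines = c("accession\tgo_id",
                                         "P1\tGO:0000001", "P2\tGO:0000002"))
  ann2 <- read_go_annotations(tsv)
  expect_equal(ann2$P2, "GO:0000002")

  bad <- withr::local_tempfile(lines = "P1\tGO:1")
  expect_error(read_go_annotations(bad), "invalid GO id")
  expect_error(go_annotation_map(list(P1 = "NOPE")), "GO ids")
})

test_that("first-quartile panel distance uses linear interpolation", {
  # star: center H, leaves L1..L4; P attached to L1
  net <- as_interactome(data.frame(c("H", "H", "H", "H", "P"),
                                   c("L1", "L2", "L3", "L4", "L1")))
  # distances from P: L1=1, L2=L3=L4 via H = 3 -> {1,3,3,3}
  pan <- vit_panel(c("L1", "L2", "L3", "L4"), net)
  expect_equal(unname(vit_q1_distance(net, "P", pan)),
               1 + 0.75 * (3 - 1))  # type-7 interpolation at h = 1.75
  # constant sample {1,1,1,1} -> 1
  panH <- vit_panel(paste0("L", 1:4), net)
  expect_equal(unname(vit_q1_distance(net, "H", panH)), 1.0)
  # worked interpolation case {1,2,2,3} -> 1.75
  chain <- as_interactome(data.frame(c("A", "B", "B", "C"),
                                     c("B", "C", "C2", "D")))
  # from A: B=1, C=2, C2=2, D=3
  pan2 <- vit_panel(c("B", "C", "C2", "D"), chain)
  expect_equal(unname(vit_q1_distance(chain, "A", pan2)), 1.75)
  # self-membership contributes distance 0
  panself <- vit_panel("A", chain)
  expect_equal(unname(vit_q1_distance(chain, "A", panself)), 0)
  # invariant to panel duplicates and ordering
  expect_equal(
    vit_q1_distance(chain, "A", vit_panel(c("D", "C2", "C", "B", "B"), chain)),
    vit_q1_distance(chain, "A", pan2))
  expect_error(vit_q1_distance(chain, "ZZ", pan2), "unknown protein")
})

test_that("unreachable panel yields the node-count sentinel", {
  net <- as_interactome(data.frame(c("A", "X"), c("B", "Y")),
                        largest_component = FALSE)
  pan <- vit_panel(c("X", "Y"), net)
  expect_warning(d <- vit_q1_distance(net, "A", pan), "sentinel")
  expect_equal(unname(d), 4)
})

test_that("panel members absent from the network are dropped", {
  net <- as_interactome(data.frame("A", "B"))
  expect_warning(pan <- vit_panel(c("A", "ZZ"), net), "dropped")
  expect_equal(pan$accessions, "A")
  expect_error(suppressWarnings(vit_panel("ZZ", net)), "no panel member")
})

test_that("assemble_features yields finite 8-vectors deterministically", {
  fix <- generate_fixture(synth_config(n_nodes = 150, module_size = 10,
                                       panel_size = 8, rng_seed = 3))
  ctx <- network_context(fix$net, rng_seed = 3)
  ft1 <- adr_feature_table(ctx, fix$seeds, fix$annotations, fix$panel)
  ft2 <- adr_feature_table(ctx, fix$seeds, fix$annotations, fix$panel)
  expect_identical(ft1$features, ft2$features)
  expect_equal(names(ft1$features), feature_names())
  expect_true(all(vapply(ft1$features, function(x) all(is.finite(x)),
                         logical(1))))
  expect_error(
    assemble_features(fix$net, "NOT_A_NODE", ft1$scores, ctx$k1, ctx$ln,
                      fix$seeds, fix$annotations, ft1$enriched, fix$panel),
    "absent from the interactome")
})
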