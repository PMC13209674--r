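test_that("direction labels classify as up, down or non-directional", {
  tax <- direction_taxonomy()
  expect_identical(classify_direction("increases^expression", tax), 1L)
  expect_identical(classify_direction("decreases^degradation", tax), 1L)
  expect_identical(classify_direction("increases^ubiquitination", tax), -1L)
  expect_identical(classify_direction("decreases^abundance", tax), -1L)
  expect_identical(classify_direction("affects^binding", tax), 0L)
  # vectorized
  expect_identical(
    classify_direction(
      c("increases^expression", "decreases^expression", "nonsense"), tax
    ),
    c(1L, -1L, 0L)
  )
  expect_length(tax$up_labels, 5)
  expect_length(tax$down_labels, 5)
  expect_error(
    direction_taxonomy(up_labels = "a", down_labels = c("a", "b")),
    "disjoint"
  )
})

test_that("interaction parser applies defaults and skips malformed rows", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ChemicalName\tGeneSymbol\tInteractionActions\tPubMedIDs-count",
    "Aspirin\tegfr\tdecreases^expression\t",
    "aspirin\tEGFR\tincreases^expression\t2",
    "\tEGFR\tincreases^expression\t1",
    "tamoxifen\tESR1\taffects^binding\t4",
    "tamoxifen\t\tdecreases^expression\t1",
    "metformin\tPRKAA1\tincreases^expression\t3"
  ), tf)
  rec <- suppressMessages(read_interactions(tf))
  # 6 data rows, 2 malformed (missing drug / gene)
  expect_equal(nrow(rec), 4)
  expect_equal(attr(rec, "skipped"), 2)
  # normalization: drug lowercased, gene uppercased, blank evidence -> 1
  expect_equal(rec$drug_id[1], "aspirin")
  expect_equal(rec$gene_symbol[1], "EGFR")
  expect_equal(rec$evidence_count[1], 1L)
  expect_true(all(rec$evidence_count >= 1))
})

test_that("parser fails on missing files, columns and empty tables", {
  expect_error(read_interactions(tempfile()), "not found")
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), tf)
  expect_error(read_interactions(tf), "required column")
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "ChemicalName\tGeneSymbol\tInteractionActions",
    "\tEGFR\tincreases^expression"
  ), tf2)
  expect_error(suppressMessages(read_interactions(tf2)), "no parsable")
})

test_that("regulation bias matches its closed form and handles thresholds", {
  expect_equal(regulation_bias(3, 0), 1)
  expect_equal(regulation_bias(0, 3), -1)
  expect_equal(regulation_bias(2, 2), 0) # perfectly conflicting -> dropped
  expect_equal(regulation_bias(3, 1, ambiguity_threshold = 0.2), 0.5)
  # below the ambiguity threshold -> conservative zero
  expect_equal(regulation_bias(5, 4, ambiguity_threshold = 0.2), 0)
  # below minimum evidence -> zero
  expect_equal(regulation_bias(1, 0, min_evidence = 2), 0)
  expect_equal(regulation_bias(0, 0), 0)
})

test_that("regulation bias is bounded, antisymmetric and monotone", {
  set.seed(42)
  u <- sample(0:20, 200, replace = TRUE)
  v <- sample(0:20, 200, replace = TRUE)
  b <- regulation_bias(u, v)
  expect_true(all(abs(b) <= 1))
  expect_equal(regulation_bias(u, v), -regulation_bias(v, u))
  # monotone non-decreasing in up-evidence at fixed down-evidence
  for (vv in c(0, 2, 5)) {
    seqb <- regulation_bias(0:15, rep(vv, 16), ambiguity_threshold = 0)
    expect_true(all(diff(seqb) >= -1e-12))
  }
})

test_that("effect matrix assembles per-pair biases over observed pairs", {
  rec <- tibble::tibble(
    drug_id = c("d1", "d1", "d1", "d2", "d2", "d3", "d3"),
    gene_symbol = c("G1", "G1", "G2", "G1", "G1", "G2", "G2"),
    action_label = c(
      "increases^expression", "decreases^expression", "increases^expression",
      "increases^expression", "decreases^expression",
      "decreases^expression", "affects^binding"
    ),
    evidence_count = c(3L, 1L, 1L, 2L, 2L, 4L, 9L)
  )
  m <- build_effect_matrix(rec)
  # d1/G1: (3-1)/4 = 0.5; d1/G2: +1; d2/G1: 2 up vs 2 down -> 0;
  # d3/G2: -1 (non-directional rows never count)
  expect_equal(m$weights["G1", "d1"], 0.5)
  expect_equal(m$weights["G2", "d1"], 1)
  expect_equal(m$weights["G1", "d2"], 0)
  expect_equal(m$weights["G2", "d3"], -1)
  expect_equal(m$weights["G2", "d2"], 0) # unobserved pair
  expect_true(all(abs(m$weights) <= 1))
})

test_that("non-directional records never change any matrix cell", {
  rec <- tibble::tibble(
    drug_id = c("d1", "d2"),
    gene_symbol = c("G1", "G2"),
    action_label = c("increases^expression", "decreases^expression"),
    evidence_count = c(2L, 2L)
  )
  base <- build_effect_matrix(rec)
  noisy <- dplyr::bind_rows(rec, tibble::tibble(
    drug_id = c("d1", "d2", "d1"),
    gene_symbol = c("G1", "G2", "G2"),
    action_label = c("affects^binding", "affects^phosphorylation", "affects^binding"),
    evidence_count = c(50L, 50L, 50L)
  ))
  m2 <- build_effect_matrix(noisy)
  expect_equal(m2$weights[base$genes, base$drugs], base$weights)
})

test_that("single-record and pruning behavior", {
  one <- tibble::tibble(
    drug_id = "d1", gene_symbol = "G1",
    action_label = "increases^expression", evidence_count = 1L
  )
  m <- build_effect_matrix(one)
  expect_equal(unname(m$weights), matrix(1, 1, 1), ignore_attr = FALSE)
  conflicted <- tibble::tibble(
    drug_id = c("d1", "d1", "d2"),
    gene_symbol = c("G1", "G1", "G1"),
    action_label = c("increases^expression", "decreases^expression", "increases^expression"),
    evidence_count = c(2L, 2L, 1L)
  )
  pruned <- build_effect_matrix(conflicted, prune = TRUE)
  expect_identical(pruned$drugs, "d2") # d1 zeroed by conflict, pruned away
})

test_that("effect matrix round-trips through its delimited serialization", {
  m <- simulate_effect_matrix(fixture_spec(n_genes = 5, n_drugs = 4, seed = 11))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_effect_matrix(m, tf)
  expect_true(file.exists(paste0(tf, ".json")))
  m2 <- read_effect_matrix(tf)
  expect_equal(m2$weights, m$weights)
  side <- jsonlite::read_json(paste0(tf, ".json"))
  expect_equal(side$ambiguity_threshold, 0.2)
  expect_length(side$up_labels, 5)
})
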