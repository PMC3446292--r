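test_that("ancestor simulation is deterministic with complete ordinals", {
  a1 <- simulate_ancestor(3, 10, seed = 100)
  a2 <- simulate_ancestor(3, 10, seed = 100)
  expect_equal(gene_table(a1), gene_table(a2))
  expect_equal(n_genes(a1), 30)
  expect_equal(
    sort(gene_table(a1)$ordinal[gene_table(a1)$scaffold_id == "scaffold_02"]),
    0:9
  )
  expect_error(simulate_ancestor(0, 10), "n_scaffolds")
})

test_that("simulated gene lengths match the requested mean", {
  ann <- simulate_ancestor(5, 200, mean_gene_len = 1500, seed = 101)
  g <- gene_table(ann)
  lens <- g$end - g$start + 1
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 1500), 3 * se + 10) # +10 for rounding/floor bias
})

test_that("an empty plan leaves the genome identical up to relayout", {
  ann <- simulate_ancestor(3, 8, seed = 102)
  res <- apply_events(ann, event_plan(), species = "derived")
  expect_equal(
    gene_table(res$annotation)[, c("gene_id", "scaffold_id", "strand", "ordinal")],
    gene_table(ann)[, c("gene_id", "scaffold_id", "strand", "ordinal")]
  )
  expect_equal(res$truth$gene_in, res$truth$gene_out)
  expect_equal(nrow(res$truth), 24)
  expect_length(res$events, 0)
})

test_that("the inversion operator reverses a segment and flips strands", {
  ann <- toy_annotation(list(s1 = paste0("g", 0:5)))
  ann$genes$strand <- rep("+", 6)
  # invert genes at ordinals 2..4 (positions 3..5)
  orders <- replay_events(ann, list(list(type = "inversion", scaffold = "s1", from = 3, len = 3)))
  expect_equal(orders$s1, paste0("g", c(0, 1, 4, 3, 2, 5)))
})

test_that("structural operators conserve gene content", {
  log <- list(
    list(type = "inversion", scaffold = "scaffold_01", from = 2, len = 3),
    list(type = "transposition", scaffold = "scaffold_02", from = 1, len = 2, to = 4),
    list(
      type = "translocation", from_scaffold = "scaffold_01", from = 1, len = 2,
      to_scaffold = "scaffold_03", to = 0
    ),
    list(type = "fusion", first = "scaffold_02", second = "scaffold_03"),
    list(type = "fission", scaffold = "scaffold_02", at = 3, new_id = "scaffold_02b")
  )
  ann <- simulate_ancestor(3, 8, seed = 103)
  orders <- replay_events(ann, log)
  expect_setequal(unlist(orders), gene_table(ann)$gene_id)
  expect_equal(sum(lengths(orders)), 24)
})

test_that("replaying an event log reproduces the derived gene order", {
  for (seed in 1:6) {
    pair <- simulate_pair(
      plan_a = event_plan(n_inversions = 3, n_fissions = 1),
      plan_b = event_plan(
        n_inversions = 5, n_transpositions = 3, n_translocations = 3,
        n_fusions = 1, gene_loss_rate = 0.05, gene_gain_rate = 0.05
      ),
      n_scaffolds = 4, genes_per_scaffold = 12, seed = 110 + seed
    )
    for (side in c("a", "b")) {
      replayed <- replay_events(pair$ancestor, pair[[paste0("events_", side)]])
      derived <- syntenica:::gene_orders(pair[[paste0("genome_", side)]])
      prefix <- toupper(side)
      replayed <- lapply(replayed, function(x) {
        if (length(x)) paste0(prefix, "_", x) else character(0)
      })
      expect_equal(replayed[sort(names(replayed))], derived[sort(names(derived))],
        ignore_attr = TRUE
      )
    }
  }
})

test_that("the truth map covers exactly the genes never lost on either branch", {
  pair <- simulate_pair(
    plan_a = event_plan(gene_loss_rate = 0.2),
    plan_b = event_plan(gene_loss_rate = 0.2, gene_gain_rate = 0.1),
    n_scaffolds = 3, genes_per_scaffold = 20, seed = 120
  )
  anc_ids <- gene_table(pair$ancestor)$gene_id
  in_a <- sub("^A_", "", grep("^A_g", gene_table(pair$genome_a)$gene_id, value = TRUE))
  in_b <- sub("^B_", "", grep("^B_g", gene_table(pair$genome_b)$gene_id, value = TRUE))
  surv <- sort(intersect(in_a, in_b))
  expect_equal(sort(sub("^A_", "", pair$truth$gene_a)), surv)
  expect_false(any(duplicated(pair$truth$gene_a)))
  expect_false(any(duplicated(pair$truth$gene_b)))
  # gained genes never enter the truth map
  expect_false(any(grepl("novel", pair$truth$gene_b)))
})

test_that("identity pairs have perfect synteny and colinearity", {
  pair <- identity_pair(3, 10, seed = 121)
  m <- build_contingency(pair$truth, pair$genome_a, pair$genome_b)
  expect_equal(synteny_correlation(m), 1.0)
  expect_equal(count_cpao(pair$truth, pair$genome_a, pair$genome_b)$n_cpao, 3 * 9)
})

test_that("within-scaffold inversions keep rho at 1 but erode CPAOs", {
  pair <- simulate_pair(
    plan_b = event_plan(n_inversions = 10),
    n_scaffolds = 3, genes_per_scaffold = 20, seed = 122
  )
  m <- build_contingency(pair$truth, pair$genome_a, pair$genome_b)
  expect_identical(synteny_correlation(m), 1.0)
  expect_lt(count_cpao(pair$truth, pair$genome_a, pair$genome_b)$n_cpao, 3 * 19)
})

test_that("between-scaffold translocations pull rho below 1", {
  below <- vapply(1:20, function(seed) {
    pair <- simulate_pair(
      plan_b = event_plan(n_translocations = 10),
      n_scaffolds = 4, genes_per_scaffold = 15, seed = 130 + seed
    )
    synteny_correlation(build_contingency(pair$truth, pair$genome_a, pair$genome_b))
  }, numeric(1))
  expect_lt(stats::median(below), 1)
  expect_true(all(below <= 1))
})

test_that("similarity simulation is deterministic and recoverable", {
  pair <- identity_pair(3, 12, seed = 140)
  s1 <- simulate_similarity(pair, confusion_rate = 0.1, seed = 141)
  s2 <- simulate_similarity(pair, confusion_rate = 0.1, seed = 141)
  expect_equal(s1$ab, s2$ab)
  expect_equal(s1$ba, s2$ba)

  clean <- simulate_similarity(pair, confusion_rate = 0, seed = 142)
  rbh <- reciprocal_best_hits(clean$ab, clean$ba)
  expect_equal(
    dplyr::arrange(rbh[, c("gene_a", "gene_b")], gene_a),
    dplyr::arrange(pair$truth, gene_a)
  )
})

test_that("landscape sequences honour the background GC when nothing is planted", {
  ann <- simulate_ancestor(3, 4, seed = 150)
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 100000)
  ls <- simulate_landscape_sequences(ann,
    clusters_per_scaffold = 0, telomere_copies = 0, cluster_span = 5000, seed = 151
  )
  freq <- Biostrings::letterFrequency(ls$sequences, c("C", "G"))
  n <- sum(Biostrings::width(ls$sequences))
  gc <- sum(freq) / n
  se <- sqrt(0.53 * 0.47 / n)
  expect_lt(abs(gc - 0.53), 3 * se)
})

test_that("infeasible landscape requests fail loudly", {
  ann <- toy_annotation(list(s1 = paste0("g", 1:3)))
  expect_error(
    simulate_landscape_sequences(ann, cluster_span = 50000, seed = 1),
    "too short"
  )
})

test_that("event plans validate their parameters", {
  expect_error(event_plan(n_inversions = -1), ">= 0")
  expect_error(event_plan(gene_loss_rate = 1.2), "\\[0, 1\\]")
  expect_error(event_plan(mean_segment_genes = 0), "mean_segment_genes")
})
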