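test_that("dot plot geometry puts every ortholog inside its scaffold box", {
  pair <- simulate_pair(
    plan_b = event_plan(n_inversions = 3),
    n_scaffolds = 4, genes_per_scaffold = 10, seed = 200
  )
  spec <- dotplot_spec(pair$truth, pair$genome_a, pair$genome_b, top_k = 29)
  expect_equal(nrow(spec$dots), nrow(pair$truth))
  expect_true(all(diff(spec$axis_a$offset) > 0))
  expect_true(all(diff(spec$axis_b$offset) > 0))
  boxes <- spec$boxes
  for (i in seq_len(nrow(spec$dots))) {
    b <- boxes[boxes$scaffold_a == spec$dots$scaffold_a[i] &
      boxes$scaffold_b == spec$dots$scaffold_b[i], ]
    expect_true(spec$dots$x[i] >= b$xmin && spec$dots$x[i] <= b$xmax)
    expect_true(spec$dots$y[i] >= b$ymin && spec$dots$y[i] <= b$ymax)
  }
})

test_that("top-k restriction drops dots outside the largest scaffolds", {
  pair <- identity_pair(5, 8, seed = 201)
  spec <- dotplot_spec(pair$truth, pair$genome_a, pair$genome_b, top_k = 3)
  kept_a <- spec$axis_a$scaffold_id
  ga <- gene_table(pair$genome_a)
  expected <- sum(ga$scaffold_id[match(pair$truth$gene_a, ga$gene_id)] %in% kept_a &
    pair$truth$gene_b %in% gene_table(pair$genome_b)$gene_id[
      gene_table(pair$genome_b)$scaffold_id %in% spec$axis_b$scaffold_id
    ])
  expect_equal(nrow(spec$dots), expected)
  expect_equal(nrow(spec$axis_a), 3)
})

test_that("identity pairs light up the diagonal in the significant shade", {
  pair <- identity_pair(3, 20, seed = 202)
  z <- scaffold_pair_significance(pair$truth, pair$genome_a, pair$genome_b,
    replicates = 200, seed = 203
  )
  spec <- dotplot_spec(pair$truth, pair$genome_a, pair$genome_b, z)
  expect_true(all(spec$dots$scaffold_a == spec$dots$scaffold_b))
  diag_boxes <- spec$boxes[spec$boxes$scaffold_a == spec$boxes$scaffold_b, ]
  expect_true(all(diag_boxes$z_class == "z > 3"))
})

test_that("strand classes and empty maps render as specified", {
  a <- toy_annotation(list(s1 = c("a1", "a2")))
  b <- toy_annotation(list(t1 = c("b1", "b2")))
  b$genes$strand <- c("+", "-") # one flipped ortholog
  spec <- dotplot_spec(make_map(c("a1", "a2"), c("b1", "b2")), a, b)
  expect_equal(sum(spec$dots$strand_class == "opposite strand"), 1)

  empty <- dotplot_spec(make_map(character(), character()), a, b)
  expect_equal(nrow(empty$dots), 0)
  expect_equal(nrow(empty$boxes), 1)
  p <- plot_dotplot(make_map(character(), character()), a, b)
  expect_s3_class(p, "ggplot")
})

test_that("rendered dot plots are written to disk", {
  pair <- identity_pair(2, 6, seed = 204)
  f <- withr::local_tempfile(fileext = ".png")
  render_dotplot(pair$truth, pair$genome_a, pair$genome_b,
    out_path = f, format = "png"
  )
  expect_true(file.exists(f) && file.size(f) > 500)
})

test_that("the pipeline reproduces identity-pair statistics end to end", {
  dir <- withr::local_tempdir()
  pair <- identity_pair(3, 12, seed = 210)
  write_gff3(pair$genome_a, file.path(dir, "a.gff3"))
  write_gff3(pair$genome_b, file.path(dir, "b.gff3"))
  sim <- simulate_similarity(pair, seed = 211)
  write_blast_tab(sim$ab, file.path(dir, "ab.tsv"))
  write_blast_tab(sim$ba, file.path(dir, "ba.tsv"))
  cfg <- list(
    gff_a = file.path(dir, "a.gff3"), gff_b = file.path(dir, "b.gff3"),
    blast_ab = file.path(dir, "ab.tsv"), blast_ba = file.path(dir, "ba.tsv"),
    out_dir = file.path(dir, "out"), replicates = 200, seed = 212
  )
  rep <- run_pipeline(cfg)
  expect_equal(rep$synteny_correlation$rho, 1.0)
  expect_equal(rep$cpao$n_cpao, 3 * 11)
  expect_equal(rep$orthology$n_pairs, 36)
  expect_true(file.exists(file.path(dir, "out", "report.json")))
  expect_true(file.exists(file.path(dir, "out", "dotplot.png")))

  # byte-identical report for the same config + seed
  json1 <- readLines(file.path(dir, "out", "report.json"))
  run_pipeline(cfg)
  expect_identical(readLines(file.path(dir, "out", "report.json")), json1)
})

test_that("missing inputs abort before any computation", {
  dir <- withr::local_tempdir()
  expect_error(run_pipeline(list(gff_a = "x")), "missing required field")
  expect_error(
    run_pipeline(list(
      gff_a = file.path(dir, "nope.gff3"), gff_b = file.path(dir, "nope.gff3"),
      orthologs = file.path(dir, "nope.tsv"), out_dir = dir
    )),
    "not found"
  )
  expect_false(file.exists(file.path(dir, "report.json")))
})

test_that("the pipeline runs the landscape stage when sequences are given", {
  dir <- withr::local_tempdir()
  pair <- identity_pair(3, 8, seed = 220)
  ann <- pair$genome_a
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 80000)
  ann <- genome_annotation(ann$genes, ann$scaffolds, species = ann$species)
  write_gff3(ann, file.path(dir, "a.gff3"))
  write_gff3(pair$genome_b, file.path(dir, "b.gff3"))
  write_orthologs(pair$truth, file.path(dir, "orth.tsv"))
  ls <- simulate_landscape_sequences(ann, cluster_span = 5000, seed = 221)
  write_fasta(ls$sequences, file.path(dir, "a.fa"))
  write_bed(ls$repeats, file.path(dir, "rep.bed"))
  rep <- run_pipeline(list(
    gff_a = file.path(dir, "a.gff3"), gff_b = file.path(dir, "b.gff3"),
    orthologs = file.path(dir, "orth.tsv"),
    fasta_a = file.path(dir, "a.fa"), repeats_bed = file.path(dir, "rep.bed"),
    out_dir = file.path(dir, "out"), replicates = 100, seed = 222
  ))
  expect_equal(rep$landscape$n_clusters, 3)
  expect_true(rep$landscape$one_cluster_per_scaffold)
  expect_equal(rep$landscape$n_complete, 3)
  expect_true(file.exists(file.path(dir, "out", "gc_track.tsv")))
  expect_true(file.exists(file.path(dir, "out", "repeat_clusters.tsv")))
})

test_that("tidy and glance methods expose results as tibbles", {
  pair <- identity_pair(2, 8, seed = 230)
  m <- build_contingency(pair$truth, pair$genome_a, pair$genome_b)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$observed), nrow(pair$truth))
  expect_equal(sum(td$expected), nrow(pair$truth), tolerance = 1e-9)

  ct <- cpao_significance(pair$truth, pair$genome_a, pair$genome_b,
    replicates = 100, seed = 231
  )
  expect_s3_class(tidy(ct), "tbl_df")
  expect_equal(nrow(tidy(ct)), ct$n_cpao)
  expect_equal(glance(ct)$n_cpao, ct$n_cpao)
})
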