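test_that("windowed GC is exact on homogeneous sequences", {
  seqs <- Biostrings::DNAStringSet(c(
    allG = strrep("G", 30000),
    acgt = strrep("ACGT", 7500)
  ))
  tr <- gc_windows(seqs, window = 10000, step = 2000)
  expect_true(all(tr$gc_fraction[tr$scaffold_id == "allG"] == 1))
  expect_true(all(tr$gc_fraction[tr$scaffold_id == "acgt"] == 0.5))
  expect_error(gc_windows(seqs, window = 100, step = 200), "window")
  expect_error(gc_windows(seqs, window = -1), "positive")
})

test_that("all-N windows are reported as undefined, N excluded elsewhere", {
  seqs <- Biostrings::DNAStringSet(c(s = paste0(
    strrep("N", 5000), strrep("G", 5000)
  )))
  tr <- gc_windows(seqs, window = 5000, step = 5000)
  expect_true(is.na(tr$gc_fraction[1]))
  expect_equal(tr$gc_fraction[2], 1)
})

test_that("window GC averages back to bulk GC on an exact tiling", {
  set.seed(70)
  n <- 50000
  x <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(s = x))
  tr <- gc_windows(seqs, window = 5000, step = 5000)
  f <- Biostrings::letterFrequency(seqs, c("C", "G"))
  expect_equal(mean(tr$gc_fraction), sum(f) / n, tolerance = 1e-12)
})

test_that("planted high-GC clusters appear as windowed GC maxima", {
  ann <- simulate_ancestor(4, 4, seed = 71)
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 120000)
  ls <- simulate_landscape_sequences(ann, cluster_span = 10000, seed = 72)
  tr <- gc_windows(ls$sequences, window = 10000, step = 2000)
  for (i in seq_len(nrow(ls$truth$clusters))) {
    cl <- ls$truth$clusters[i, ]
    sub <- dplyr::filter(tr, scaffold_id == cl$scaffold_id)
    peak <- sub[which.max(sub$gc_fraction), ]
    # peak window localises within the planted segment +/- one window
    expect_lt(cl$start - 10000, peak$start)
    expect_gt(cl$end + 10000, peak$end)
  }
})

test_that("tandem telomere arrays are called at the right ends only", {
  set.seed(73)
  core <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")
  with_right <- Biostrings::DNAStringSet(c(s = paste0(core, strrep("TTTAGGG", 20))))
  calls <- detect_telomere_arrays(with_right)
  expect_true(calls$present[calls$end == "right"])
  expect_false(calls$present[calls$end == "left"])
  expect_gte(calls$tandem_copies[calls$end == "right"], 20)
  st <- telomere_status(calls)
  expect_equal(st$status, "one_ended")
})

test_that("random sequence yields no telomere calls across seeds", {
  for (seed in 1:5) {
    set.seed(80 + seed)
    x <- paste(sample(c("A", "C", "G", "T"), 100000, replace = TRUE), collapse = "")
    calls <- detect_telomere_arrays(Biostrings::DNAStringSet(c(s = x)))
    expect_false(any(calls$present))
  }
})

test_that("telomere detection is strand-symmetric", {
  set.seed(74)
  core <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")
  x <- Biostrings::DNAStringSet(c(s = paste0(strrep("TTTAGGG", 10), core)))
  rc <- Biostrings::reverseComplement(x)
  names(rc) <- "s"
  fwd <- detect_telomere_arrays(x)
  rev <- detect_telomere_arrays(rc)
  expect_equal(
    fwd$present[fwd$end == "left"],
    rev$present[rev$end == "right"]
  )
  expect_equal(
    fwd$tandem_copies[fwd$end == "left"],
    rev$tandem_copies[rev$end == "right"]
  )
  expect_error(detect_telomere_arrays(x, end_window = 30), "end_window")
})

test_that("repeat clustering merges by gap and filters by span", {
  iv <- tibble::tibble(
    scaffold_id = "s1", start = c(101, 501), end = c(400, 900), family = "Zepp"
  )
  one <- cluster_repeats(iv, max_gap = 2000, min_span = 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 101)
  expect_equal(one$end, 900)
  expect_equal(one$n_elements, 2L)

  two <- cluster_repeats(iv, max_gap = 50, min_span = 100)
  expect_equal(nrow(two), 2)
  none <- cluster_repeats(iv, max_gap = 50, min_span = 1000)
  expect_equal(nrow(none), 0)
})

test_that("clustering is idempotent on its own output", {
  set.seed(75)
  iv <- tibble::tibble(
    scaffold_id = sample(c("s1", "s2"), 40, replace = TRUE),
    start = sample.int(200000, 40)
  )
  iv$end <- iv$start + sample(200:2000, 40, replace = TRUE)
  iv$family <- "Zepp"
  cl1 <- cluster_repeats(iv, max_gap = 1500, min_span = 500)
  cl2 <- cluster_repeats(
    dplyr::mutate(cl1[, c("scaffold_id", "start", "end")], family = "Zepp"),
    max_gap = 1500, min_span = 500
  )
  expect_equal(cl2$start, cl1$start)
  expect_equal(cl2$end, cl1$end)
  expect_equal(nrow(cl2), nrow(cl1))
})

test_that("planted clusters are recovered exactly, one per scaffold", {
  ann <- simulate_ancestor(10, 4, seed = 76)
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 300000)
  ls <- simulate_landscape_sequences(ann,
    clusters_per_scaffold = 5,
    cluster_span = 6000, seed = 77
  )
  cl <- cluster_repeats(ls$repeats, family_filter = "Zepp")
  expect_equal(nrow(cl), 50)
  expected <- ls$repeats %>%
    dplyr::mutate(cluster = rep(seq_len(50), each = 3)) %>%
    dplyr::group_by(cluster) %>%
    dplyr::summarise(
      scaffold_id = dplyr::first(scaffold_id),
      start = min(start), end = max(end), .groups = "drop"
    ) %>%
    dplyr::arrange(scaffold_id, start)
  expect_equal(cl$start, expected$start)
  expect_equal(cl$end, expected$end)
  expect_equal(cl$scaffold_id, expected$scaffold_id)
})

test_that("cluster positions classify as internal or sub-telomeric", {
  ann <- toy_annotation(list(s1 = paste0("g", 1:3)))
  ann$scaffolds$length <- 1e6
  mid <- tibble::tibble(
    scaffold_id = "s1", start = 499000, end = 501000,
    span = 2001, n_elements = 1L, families = list("Zepp")
  )
  near_end <- dplyr::mutate(mid, start = 15000, end = 25000) # midpoint at 2%
  s1 <- summarize_clusters(mid, ann)
  expect_equal(s1$clusters$positional_class, "internal")
  s2 <- summarize_clusters(near_end, ann)
  expect_equal(s2$clusters$positional_class, "sub-telomeric")
  expect_error(
    summarize_clusters(dplyr::mutate(mid, scaffold_id = "nope"), ann),
    "unknown scaffold"
  )
})

test_that("one planted cluster per scaffold is summarised as such, with high GC", {
  ann <- simulate_ancestor(5, 4, seed = 78)
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 120000)
  ls <- simulate_landscape_sequences(ann, cluster_span = 8000, seed = 79)
  cl <- cluster_repeats(ls$repeats, family_filter = "Zepp")
  tel <- detect_telomere_arrays(ls$sequences)
  summ <- summarize_clusters(cl, ann, telomeres = tel, sequences = ls$sequences)
  expect_true(all(summ$scaffolds$n_clusters == 1))
  expect_true(all(summ$scaffolds$status == "complete"))
  # planted clusters run hotter than the genome background
  expect_true(all(summ$clusters$gc_fraction > summ$genome_gc + 0.03))
})

test_that("genome structure summary reports scaffold, gene and GC totals", {
  ann <- simulate_ancestor(3, 10, seed = 90)
  ann$scaffolds$length <- pmax(ann$scaffolds$length, 60000)
  ls <- simulate_landscape_sequences(ann,
    clusters_per_scaffold = 0,
    telomere_copies = 8, cluster_span = 5000, seed = 91
  )
  tel <- detect_telomere_arrays(ls$sequences)
  summ <- genome_structure_summary(ann, ls$sequences, tel)
  expect_equal(summ$n_scaffolds, 3)
  expect_equal(summ$n_genes, 30)
  expect_equal(summ$total_length, sum(ann$scaffolds$length))
  expect_equal(summ$n_complete, 3)
  expect_equal(summ$gc_fraction, 0.53, tolerance = 0.02)
})
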