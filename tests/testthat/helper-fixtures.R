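# Fixture builders and independent oracles used across the suite.

# annotation from a list of per-scaffold gene-id vectors; genes 100 bp,
# spaced 1000 bp, strands "+" unless given
toy_annotation <- function(orders, strands = NULL, species = "toy") {
  rows <- lapply(seq_along(orders), function(s) {
    ids <- orders[[s]]
    k <- length(ids)
    starts <- 1000 + (seq_len(k) - 1) * 1100
    tibble::tibble(
      gene_id = ids,
      scaffold_id = names(orders)[s] %||% paste0("s", s),
      start = starts, end = starts + 99,
      strand = if (is.null(strands)) rep("+", k) else strands[ids]
    )
  })
  genes <- dplyr::bind_rows(rows)
  scaf <- tibble::tibble(
    scaffold_id = unique(genes$scaffold_id),
    length = vapply(unique(genes$scaffold_id), function(s) {
      max(genes$end[genes$scaffold_id == s]) + 1000
    }, numeric(1))
  )
  genome_annotation(genes, scaf, species = species)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

make_map <- function(ids_a, ids_b) {
  tibble::tibble(gene_a = ids_a, gene_b = ids_b)
}

# all permutations of seq_len(n), one per row (n! rows); small n only
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# independent brute-force CPAO count: scan every adjacent pair of genome A
# genes and test adjacency of the images in B by start-sorted position
brute_cpao <- function(map, annot_a, annot_b) {
  ga <- gene_table(annot_a)
  gb <- gene_table(annot_b)
  b_of <- stats::setNames(map$gene_b, map$gene_a)
  count <- 0L
  for (s in unique(ga$scaffold_id)) {
    ids <- ga$gene_id[ga$scaffold_id == s][order(ga$start[ga$scaffold_id == s])]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) {
      g1 <- ids[i]; g2 <- ids[i + 1]
      if (!(g1 %in% map$gene_a && g2 %in% map$gene_a)) next
      h1 <- b_of[[g1]]; h2 <- b_of[[g2]]
      s1 <- gb$scaffold_id[gb$gene_id == h1]
      s2 <- gb$scaffold_id[gb$gene_id == h2]
      if (s1 != s2) next
      ids_b <- gb$gene_id[gb$scaffold_id == s1][order(gb$start[gb$scaffold_id == s1])]
      if (abs(which(ids_b == h1) - which(ids_b == h2)) == 1) count <- count + 1L
    }
  }
  count
}

# identity genome pair fixture: no events on either branch
identity_pair <- function(n_scaffolds = 3, genes_per_scaffold = 10, seed = 1) {
  simulate_pair(
    n_scaffolds = n_scaffolds, genes_per_scaffold = genes_per_scaffold,
    seed = seed
  )
}
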