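# per-gene (scaffold index, ordinal) positions for one genome, under the
# requested adjacency mode
gene_positions <- function(annot, mapped_ids = NULL,
                           adjacency_mode = c("all_genes", "orthologs_only")) {
  adjacency_mode <- match.arg(adjacency_mode)
  g <- gene_table(annot)
  if (adjacency_mode == "orthologs_only") {
    g <- g %>%
      filter(.data$gene_id %in% mapped_ids) %>%
      group_by(.data$scaffold_id) %>%
      mutate(ordinal = seq_len(dplyr::n()) - 1L) %>%
      ungroup()
  }
  g
}

#' Count conserved pairs of adjacent orthologs (CPAOs)
#'
#' A CPAO is an unordered pair of genes adjacent (consecutive ordinals on one
#' scaffold) in genome A, both with orthologs, whose orthologs are adjacent
#' in genome B. Orientation and strand are ignored; adjacency never spans a
#' scaffold boundary; each pair is counted once. CPAO counting is symmetric
#' in the two genomes.
#'
#' By default adjacency is computed over all annotated genes, so an
#' unmatched gene sitting between two orthologs breaks their adjacency;
#' `adjacency_mode = "orthologs_only"` instead ranks only the mapped genes on
#' each scaffold.
#'
#' @inheritParams build_contingency
#' @param adjacency_mode `"all_genes"` (default) or `"orthologs_only"`.
#' @return A `cpao_result`: list with `n_cpao`, the tibble `pairs`
#'   (`gene_a1`, `gene_a2`, `gene_b1`, `gene_b2`), and `adjacency_mode`.
#' @export
count_cpao <- function(map, annot_a, annot_b,
                       adjacency_mode = c("all_genes", "orthologs_only")) {
  adjacency_mode <- match.arg(adjacency_mode)
  map <- validate_map(map, annot_a, annot_b)
  ga <- gene_positions(annot_a, map$gene_a, adjacency_mode)
  gb <- gene_positions(annot_b, map$gene_b, adjacency_mode)
  ga <- arrange(ga, .data$scaffold_id, .data$ordinal)
  adj <- tibble(
    gene_a1 = head(ga$gene_id, -1),
    gene_a2 = tail(ga$gene_id, -1),
    same = head(ga$scaffold_id, -1) == tail(ga$scaffold_id, -1)
  ) %>% filter(.data$same)
  b_of <- setNames(map$gene_b, map$gene_a)
  adj <- adj %>%
    filter(.data$gene_a1 %in% map$gene_a, .data$gene_a2 %in% map$gene_a) %>%
    mutate(gene_b1 = unname(b_of[.data$gene_a1]), gene_b2 = unname(b_of[.data$gene_a2]))
  scaf_b <- setNames(gb$scaffold_id, gb$gene_id)
  ord_b <- setNames(gb$ordinal, gb$gene_id)
  hit <- scaf_b[adj$gene_b1] == scaf_b[adj$gene_b2] &
    abs(ord_b[adj$gene_b1] - ord_b[adj$gene_b2]) == 1L
  pairs <- adj[hit, c("gene_a1", "gene_a2", "gene_b1", "gene_b2")]
  structure(
    list(n_cpao = nrow(pairs), pairs = pairs, adjacency_mode = adjacency_mode),
    class = "cpao_result"
  )
}

#' @export
print.cpao_result <- function(x, ...) {
  cat(sprintf(
    "<cpao_result> %d conserved adjacent ortholog pairs (adjacency: %s)\n",
    x$n_cpao, x$adjacency_mode
  ))
  invisible(x)
}

#' @export
tidy.cpao_result <- function(x, ...) x$pairs

#' @export
glance.cpao_result <- function(x, ...) {
  tibble(n_cpao = x$n_cpao, adjacency_mode = x$adjacency_mode)
}

#' CPAO count with significance against the gene-order reshuffling null
#'
#' The colinearity null model: the order of all genes — orthologs and
#' non-orthologs alike — in one genome is reshuffled uniformly across all
#' gene positions genome-wide, keeping the number of genes on each scaffold
#' constant. The mean and standard deviation of the CPAO count over
#' `replicates` such datasets give z = (observed - null mean) / null sd.
#'
#' @inheritParams count_cpao
#' @param replicates Number of reshuffled datasets (>= 2). Default 1000.
#' @param seed Integer seed.
#' @param shuffled_genome Which genome's gene order is reshuffled, `"B"`
#'   (default) or `"A"`. The statistic is symmetric; the choice only affects
#'   the Monte-Carlo stream.
#' @return A `cpao_test`: `cpao_result` fields plus `null_mean`, `null_sd`,
#'   `z`, `undefined`, `replicates`, `seed`, `shuffled_genome`.
#' @export
cpao_significance <- function(map, annot_a, annot_b, replicates = 1000,
                              seed = NULL, shuffled_genome = c("B", "A"),
                              adjacency_mode = c("all_genes", "orthologs_only")) {
  shuffled_genome <- match.arg(shuffled_genome)
  adjacency_mode <- match.arg(adjacency_mode)
  if (replicates < 2) abort("replicates must be >= 2")
  if (shuffled_genome == "A") {
    swapped <- cpao_significance(
      tibble(gene_a = map$gene_b, gene_b = map$gene_a),
      annot_b, annot_a,
      replicates = replicates, seed = seed,
      shuffled_genome = "B", adjacency_mode = adjacency_mode
    )
    swapped$pairs <- swapped$pairs %>%
      rename(
        gene_a1 = "gene_b1", gene_a2 = "gene_b2",
        gene_b1 = "gene_a1", gene_b2 = "gene_a2"
      ) %>%
      select("gene_a1", "gene_a2", "gene_b1", "gene_b2")
    swapped$shuffled_genome <- "A"
    return(swapped)
  }

  observed <- count_cpao(map, annot_a, annot_b, adjacency_mode)
  map <- validate_map(map, annot_a, annot_b)

  # adjacency pairs of genome A with both members mapped, as indices into the
  # genome-B gene table (the images h, h')
  ga <- gene_positions(annot_a, map$gene_a, adjacency_mode) %>%
    arrange(.data$scaffold_id, .data$ordinal)
  same <- head(ga$scaffold_id, -1) == tail(ga$scaffold_id, -1)
  a1 <- head(ga$gene_id, -1)[same]
  a2 <- tail(ga$gene_id, -1)[same]
  in_map <- a1 %in% map$gene_a & a2 %in% map$gene_a
  a1 <- a1[in_map]
  a2 <- a2[in_map]
  b_of <- setNames(map$gene_b, map$gene_a)
  gb_all <- gene_table(annot_b)
  h1 <- match(b_of[a1], gb_all$gene_id)
  h2 <- match(b_of[a2], gb_all$gene_id)

  n_b <- nrow(gb_all)
  scaf_slot <- match(gb_all$scaffold_id, scaffold_table(annot_b)$scaffold_id)
  ord_slot <- gb_all$ordinal
  mapped_b <- match(map$gene_b, gb_all$gene_id)

  if (!is.null(seed)) set.seed(seed)
  counts <- integer(replicates)
  if (adjacency_mode == "all_genes") {
    for (r in seq_len(replicates)) {
      slot <- sample.int(n_b) # gene i occupies slot[i]
      sc <- scaf_slot[slot]
      od <- ord_slot[slot]
      counts[r] <- sum(sc[h1] == sc[h2] & abs(od[h1] - od[h2]) == 1L)
    }
  } else {
    for (r in seq_len(replicates)) {
      slot <- sample.int(n_b)
      sc <- scaf_slot[slot][mapped_b]
      od <- ord_slot[slot][mapped_b]
      o <- order(sc, od)
      succ <- integer(length(mapped_b)) # successor among mapped genes
      succ[o[-length(o)]] <- ifelse(
        sc[o[-length(o)]] == sc[o[-1]], o[-1], 0L
      )
      # h1/h2 index gb_all rows; re-index into the mapped-genes vector
      m1 <- match(h1, mapped_b)
      m2 <- match(h2, mapped_b)
      counts[r] <- sum(succ[m1] == m2 | succ[m2] == m1)
    }
  }
  mu <- mean(counts)
  sdv <- sqrt(mean((counts - mu)^2))
  undef <- sdv < 1e-12
  structure(
    list(
      n_cpao = observed$n_cpao, pairs = observed$pairs,
      adjacency_mode = adjacency_mode,
      null_mean = mu, null_sd = sdv,
      z = if (undef) NA_real_ else (observed$n_cpao - mu) / sdv,
      undefined = undef, replicates = replicates, seed = seed,
      shuffled_genome = "B"
    ),
    class = c("cpao_test", "cpao_result")
  )
}

#' @export
print.cpao_test <- function(x, ...) {
  cat(sprintf(
    "CPAO = %d (null %.2f +/- %.2f over %d reshuffles of genome %s), Z = %s\n",
    x$n_cpao, x$null_mean, x$null_sd, x$replicates, x$shuffled_genome,
    if (x$undefined) "undefined (null sd = 0)" else sprintf("%.2f", x$z)
  ))
  invisible(x)
}

#' @export
glance.cpao_test <- function(x, ...) {
  tibble(
    n_cpao = x$n_cpao, z = x$z, null_mean = x$null_mean, null_sd = x$null_sd,
    replicates = x$replicates, seed = x$seed %||% NA_integer_,
    shuffled_genome = x$shuffled_genome, adjacency_mode = x$adjacency_mode
  )
}
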