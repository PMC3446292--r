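#' Build a genome annotation from gene and scaffold tables
#'
#' A `genome_annotation` is the gene-order substrate of every statistic in the
#' package: an ordered table of gene loci per scaffold plus the scaffold
#' lengths. Coordinates are 1-based inclusive throughout the package; BED
#' input/output converts at the boundary.
#'
#' Each gene receives a 0-based `ordinal` giving its rank among the genes of
#' its scaffold ordered by start position (ties broken by end, then gene id),
#' so adjacency of two genes means their ordinals differ by exactly 1.
#' Overlapping genes are permitted; ordinals still follow sorted starts.
#'
#' @param genes Data frame with columns `gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand` (`"+"` or `"-"`).
#' @param scaffolds Data frame with columns `scaffold_id`, `length` (bp).
#'   Scaffold order is kept as given.
#' @param species Label for the genome (used in reports and plots).
#' @return A `genome_annotation`: a list with tibbles `genes` (with an
#'   `ordinal` column) and `scaffolds`, and the `species` label.
#' @examples
#' ann <- genome_annotation(
#'   genes = data.frame(
#'     gene_id = c("g1", "g2"), scaffold_id = "s1",
#'     start = c(900, 100), end = c(1200, 500), strand = c("-", "+")
#'   ),
#'   scaffolds = data.frame(scaffold_id = "s1", length = 10000)
#' )
#' gene_table(ann)
#' @export
genome_annotation <- function(genes, scaffolds, species = "genome") {
  genes <- as_tibble(genes)
  scaffolds <- as_tibble(scaffolds)
  req <- c("gene_id", "scaffold_id", "start", "end", "strand")
  if (!all(req %in% names(genes))) {
    abort(paste0("`genes` must have columns: ", paste(req, collapse = ", ")))
  }
  if (!all(c("scaffold_id", "length") %in% names(scaffolds))) {
    abort("`scaffolds` must have columns scaffold_id and length")
  }
  if (anyDuplicated(scaffolds$scaffold_id)) {
    abort("duplicate scaffold_id in `scaffolds`")
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- genes$gene_id[duplicated(genes$gene_id)][1]
    abort(paste0("duplicate gene_id: ", dup))
  }
  bad <- setdiff(genes$scaffold_id, scaffolds$scaffold_id)
  if (length(bad)) {
    abort(paste0("gene scaffold_id not in scaffold table: ", bad[1]))
  }
  if (any(genes$start > genes$end)) {
    g <- genes$gene_id[genes$start > genes$end][1]
    abort(paste0("gene with start > end: ", g))
  }
  if (any(genes$start < 1)) {
    abort(paste0("gene with start < 1: ", genes$gene_id[genes$start < 1][1]))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  len <- setNames(as.numeric(scaffolds$length), scaffolds$scaffold_id)
  over <- genes$end > len[genes$scaffold_id]
  if (any(over)) {
    abort(paste0("gene extends beyond scaffold length: ", genes$gene_id[over][1]))
  }

  genes <- genes %>%
    select("gene_id", "scaffold_id", "start", "end", "strand") %>%
    mutate(scaffold_id = as.character(.data$scaffold_id)) %>%
    arrange(
      match(.data$scaffold_id, scaffolds$scaffold_id),
      .data$start, .data$end, .data$gene_id
    ) %>%
    group_by(.data$scaffold_id) %>%
    mutate(ordinal = seq_len(dplyr::n()) - 1L) %>%
    ungroup() %>%
    arrange(match(.data$scaffold_id, scaffolds$scaffold_id), .data$ordinal)

  structure(
    list(species = species, scaffolds = scaffolds, genes = genes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %s: %d genes on %d scaffolds (%.3f Mb)\n",
    x$species, nrow(x$genes), nrow(x$scaffolds), sum(x$scaffolds$length) / 1e6
  ))
  invisible(x)
}

#' Accessors for genome annotations
#'
#' @param annot A [genome_annotation()].
#' @return `gene_table()` returns the gene tibble (with ordinals),
#'   `scaffold_table()` the scaffold tibble, `n_genes()` the gene count.
#' @export
gene_table <- function(annot) {
  stopifnot(inherits(annot, "genome_annotation"))
  annot$genes
}

#' @rdname gene_table
#' @export
scaffold_table <- function(annot) {
  stopifnot(inherits(annot, "genome_annotation"))
  annot$scaffolds
}

#' @rdname gene_table
#' @export
n_genes <- function(annot) nrow(gene_table(annot))

# per-scaffold gene-id lists in ordinal order (the simulator's working form)
gene_orders <- function(annot) {
  g <- annot$genes
  ids <- annot$scaffolds$scaffold_id
  out <- lapply(ids, function(s) g$gene_id[g$scaffold_id == s])
  names(out) <- ids
  out
}
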