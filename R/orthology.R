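#' Best hit per query from a similarity table
#'
#' For every query, keeps the subject with maximal bitscore; ties are broken
#' by lower evalue, then lexicographically smaller subject id, so results are
#' identical across runs and platforms.
#'
#' @param records Similarity tibble from [read_blast_tab()] (columns
#'   `query_id`, `subject_id`, `bitscore`, `evalue`).
#' @param exclude_self Drop records where query and subject id coincide.
#' @param min_bitscore,max_evalue Optional filters applied before ranking;
#'   the reciprocal-best-hit criterion itself imposes no threshold.
#' @return Tibble `query_id`, `subject_id`, `bitscore`, `evalue`, one row per
#'   query present after filtering.
#' @export
best_hits <- function(records, exclude_self = FALSE,
                      min_bitscore = NULL, max_evalue = NULL) {
  rec <- as_tibble(records)
  if (exclude_self) rec <- filter(rec, .data$query_id != .data$subject_id)
  if (!is.null(min_bitscore)) rec <- filter(rec, .data$bitscore >= min_bitscore)
  if (!is.null(max_evalue)) rec <- filter(rec, .data$evalue <= max_evalue)
  rec %>%
    arrange(
      .data$query_id, dplyr::desc(.data$bitscore),
      .data$evalue, .data$subject_id
    ) %>%
    distinct(.data$query_id, .keep_all = TRUE) %>%
    select("query_id", "subject_id", "bitscore", "evalue")
}

#' Reciprocal-best-hit ortholog pairing
#'
#' A pair (g, h) is a putative ortholog pair when h is g's best hit in the
#' A-to-B search and g is h's best hit in the B-to-A search. The result is
#' one-to-one by construction; genes without a reciprocal best hit simply
#' remain unpaired.
#'
#' @param records_ab Similarity records with genome-A queries and genome-B
#'   subjects.
#' @param records_ba The reverse direction.
#' @inheritParams best_hits
#' @return An ortholog map: tibble with `gene_a`, `gene_b`, `bitscore_ab`,
#'   `bitscore_ba`, sorted by `gene_a`.
#' @examples
#' ab <- data.frame(query_id = "g1", subject_id = "h1", bitscore = 200, evalue = 1e-50)
#' ba <- data.frame(query_id = "h1", subject_id = "g1", bitscore = 190, evalue = 1e-48)
#' reciprocal_best_hits(ab, ba)
#' @export
reciprocal_best_hits <- function(records_ab, records_ba,
                                 min_bitscore = NULL, max_evalue = NULL) {
  bh_ab <- best_hits(records_ab, min_bitscore = min_bitscore, max_evalue = max_evalue)
  bh_ba <- best_hits(records_ba, min_bitscore = min_bitscore, max_evalue = max_evalue)
  out <- bh_ab %>%
    rename(gene_a = "query_id", gene_b = "subject_id", bitscore_ab = "bitscore") %>%
    inner_join(
      bh_ba %>%
        rename(gene_b = "query_id", gene_a_back = "subject_id", bitscore_ba = "bitscore"),
      by = "gene_b"
    ) %>%
    filter(.data$gene_a == .data$gene_a_back) %>%
    select("gene_a", "gene_b", "bitscore_ab", "bitscore_ba") %>%
    arrange(.data$gene_a)
  stopifnot(!anyDuplicated(out$gene_a), !anyDuplicated(out$gene_b))
  out
}

# check an ortholog map against the two annotations; returns the map with
# genes guaranteed present and one-to-one
validate_map <- function(map, annot_a, annot_b) {
  map <- as_tibble(map)
  stopifnot(all(c("gene_a", "gene_b") %in% names(map)))
  if (anyDuplicated(map$gene_a) || anyDuplicated(map$gene_b)) {
    abort("ortholog map is not one-to-one")
  }
  miss_a <- setdiff(map$gene_a, gene_table(annot_a)$gene_id)
  if (length(miss_a)) {
    abort(paste0("mapped gene absent from genome A annotation: ", miss_a[1]))
  }
  miss_b <- setdiff(map$gene_b, gene_table(annot_b)$gene_id)
  if (length(miss_b)) {
    abort(paste0("mapped gene absent from genome B annotation: ", miss_b[1]))
  }
  map
}
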