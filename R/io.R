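#' Read gene loci from a GFF3 file
#'
#' Features of the requested type become gene loci; scaffold lengths are taken
#' from `##sequence-region` pragmas or, failing that, from a two-column
#' `scaffold_id`/`length` TSV supplied via `scaffold_lengths`.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type to keep (GFF3 column 3). Default `"gene"`.
#' @param id_attribute Attribute holding the gene identifier. Default `"ID"`;
#'   JGI and GenBank dialects differ, hence configurable.
#' @param scaffold_lengths Optional: a data frame with `scaffold_id`/`length`,
#'   or path to a headerless two-column TSV. Overrides pragma lengths.
#' @param species Genome label.
#' @return A [genome_annotation()].
#' @export
read_gff3 <- function(path, feature_type = "gene", id_attribute = "ID",
                      scaffold_lengths = NULL, species = NULL) {
  species <- species %||% sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    miss <- if (is.null(ids)) seq_along(gr) else which(is.na(ids) | !nzchar(ids))
    loc <- if (length(gr)) {
      paste0(GenomicRanges::seqnames(gr)[miss[1]], ":",
             GenomicRanges::start(gr)[miss[1]], "-",
             GenomicRanges::end(gr)[miss[1]])
    } else "no features"
    abort(paste0(
      "missing '", id_attribute, "' attribute on '", feature_type,
      "' feature at ", loc, " in ", path
    ))
  }
  scaf <- scaffold_lengths_from(path, scaffold_lengths)
  genes <- tibble(
    gene_id = as.character(ids),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(genes$strand == "*")) {
    abort(paste0("feature without strand: ", genes$gene_id[genes$strand == "*"][1]))
  }
  # keep scaffolds that carry genes but are absent from the length source? No:
  # lengths are required; a gene on an unknown scaffold is an input error.
  genome_annotation(genes, scaf, species = species)
}

scaffold_lengths_from <- function(gff_path, scaffold_lengths) {
  if (!is.null(scaffold_lengths)) {
    if (is.character(scaffold_lengths)) {
      tab <- readr::read_tsv(scaffold_lengths,
        col_names = c("scaffold_id", "length"),
        col_types = readr::cols(
          scaffold_id = readr::col_character(), length = readr::col_double()
        ),
        progress = FALSE
      )
      return(tab)
    }
    tab <- as_tibble(scaffold_lengths)
    stopifnot(all(c("scaffold_id", "length") %in% names(tab)))
    return(tab)
  }
  hdr <- readLines(gff_path, n = 10000L)
  hdr <- hdr[startsWith(hdr, "##sequence-region")]
  if (!length(hdr)) {
    abort(paste0(
      "no ##sequence-region pragmas in ", gff_path,
      " and no scaffold_lengths table supplied"
    ))
  }
  parts <- strsplit(trimws(hdr), "[ \t]+")
  tibble(
    scaffold_id = vapply(parts, `[`, "", 2L),
    length = as.numeric(vapply(parts, `[`, "", 4L))
  )
}

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas for every scaffold so the file
#' round-trips through [read_gff3()] without a companion lengths table.
#'
#' @param annot A [genome_annotation()].
#' @param path Output path.
#' @param feature_type Feature type for column 3.
#' @param id_attribute Attribute name carrying the gene id.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annot, path, feature_type = "gene", id_attribute = "ID") {
  stopifnot(inherits(annot, "genome_annotation"))
  s <- annot$scaffolds
  g <- annot$genes
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", s$scaffold_id, as.integer(s$length)),
    sprintf(
      "%s\tsyntenica\t%s\t%d\t%d\t.\t%s\t.\t%s=%s",
      g$scaffold_id, feature_type, as.integer(g$start), as.integer(g$end),
      g$strand, id_attribute, g$gene_id
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read scaffold sequences from FASTA
#'
#' @param path FASTA path (multi-line records allowed).
#' @return A [Biostrings::DNAStringSet]; names are the first
#'   whitespace-delimited token of each header, lengths are residue counts.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    abort(paste0("duplicate FASTA identifier: ", names(x)[duplicated(names(x))][1]))
  }
  if (any(Biostrings::width(x) == 0)) {
    abort(paste0("empty FASTA record: ", names(x)[Biostrings::width(x) == 0][1]))
  }
  x
}

#' @rdname read_fasta
#' @param sequences A named `DNAStringSet` or named character vector.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Scaffold lengths of a sequence set
#'
#' @param sequences A `DNAStringSet` as returned by [read_fasta()].
#' @return Tibble with `scaffold_id` and `length`.
#' @export
sequence_lengths <- function(sequences) {
  tibble(scaffold_id = names(sequences), length = Biostrings::width(sequences))
}

#' Read an all-vs-all similarity table in BLAST outfmt-6 layout
#'
#' Expects the 12 standard columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore); extra columns are
#' ignored. Duplicate (query, subject) rows are collapsed keeping the highest
#' bitscore (ties: lowest evalue).
#'
#' @param path File path.
#' @return Tibble of similarity records: `query_id`, `subject_id`,
#'   `pct_identity`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  raw <- readr::read_tsv(path,
    col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(raw) < 12) abort("similarity table has fewer than 12 columns")
  rec <- tibble(
    query_id = raw[[1]], subject_id = raw[[2]],
    pct_identity = suppressWarnings(as.numeric(raw[[3]])),
    evalue = suppressWarnings(as.numeric(raw[[11]])),
    bitscore = suppressWarnings(as.numeric(raw[[12]]))
  )
  bad <- which(is.na(rec$bitscore) | is.na(rec$evalue))
  if (length(bad)) {
    abort(paste0("non-numeric evalue/bitscore at data line ", bad[1], " of ", path))
  }
  dedupe_similarity(rec)
}

dedupe_similarity <- function(rec) {
  rec %>%
    arrange(.data$query_id, .data$subject_id, dplyr::desc(.data$bitscore), .data$evalue) %>%
    distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)
}

#' @rdname read_blast_tab
#' @param records Tibble of similarity records (as produced by the simulator).
#' @export
write_blast_tab <- function(records, path) {
  lines <- sprintf(
    "%s\t%s\t%.1f\t100\t0\t0\t1\t100\t1\t100\t%.3g\t%.1f",
    records$query_id, records$subject_id,
    records$pct_identity %||% 90, records$evalue, records$bitscore
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read repeat intervals from BED
#'
#' BED3+ with an optional name column used as the repeat family (default
#' family `"repeat"`). BED's 0-based half-open coordinates are converted to
#' the package's 1-based inclusive convention.
#'
#' @param path BED path.
#' @return Tibble of repeat intervals: `scaffold_id`, `start`, `end`
#'   (1-based inclusive), `family`.
#' @export
read_bed <- function(path) {
  # ragged optional columns (BED3 vs BED4+) trip readr's column-count check;
  # coordinates are validated below, so the parser warning carries no signal
  raw <- suppressWarnings(readr::read_tsv(path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  if (ncol(raw) < 3) abort("BED needs at least 3 columns")
  start0 <- suppressWarnings(as.numeric(raw[[2]]))
  end0 <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(start0) || anyNA(end0)) abort("non-numeric BED coordinates")
  if (any(start0 >= end0)) {
    abort(paste0("BED interval with start >= end at line ", which(start0 >= end0)[1]))
  }
  tibble(
    scaffold_id = raw[[1]],
    start = start0 + 1,
    end = end0,
    family = if (ncol(raw) >= 4) dplyr::coalesce(raw[[4]], "repeat") else "repeat"
  )
}

#' @rdname read_bed
#' @param intervals Tibble with `scaffold_id`, `start`, `end` (1-based
#'   inclusive) and optionally `family`.
#' @export
write_bed <- function(intervals, path) {
  fam <- intervals$family %||% rep("repeat", nrow(intervals))
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    intervals$scaffold_id, as.integer(intervals$start - 1),
    as.integer(intervals$end), fam
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read or write an ortholog pair table
#'
#' TSV with columns `gene_a`, `gene_b` and optional score columns; the
#' interchange format between the orthology step and the synteny statistics.
#'
#' @param path File path.
#' @export
read_orthologs <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      gene_a = readr::col_character(), gene_b = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}

#' @rdname read_orthologs
#' @param map Ortholog pair tibble.
#' @export
write_orthologs <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}
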