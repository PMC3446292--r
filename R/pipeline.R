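default_config <- function() {
  list(
    feature_type = "gene", id_attribute = "ID",
    replicates = 1000, seed = NULL, top_k = 29,
    adjacency_mode = "all_genes", format = "png",
    repeat_family = NULL, min_bitscore = NULL, max_evalue = NULL,
    gc_window = 10000, gc_step = 2000,
    telomere_motif = "TTTAGGG", telomere_min_copies = 5,
    telomere_end_window = 1000,
    cluster_max_gap = 2000, cluster_min_span = 1000
  )
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  utils::modifyList(default_config(), config)
}

#' Run the full synteny and colinearity pipeline
#'
#' Orthology (or a precomputed ortholog table) -> ortholog-sharing
#' contingency -> synteny correlation with Z-score -> pairwise scaffold
#' Z-scores -> CPAO count with Z-score -> dot plot, plus the landscape
#' analyses (GC track, telomere calls, repeat clusters) when sequences and
#' repeat intervals are supplied. Writes a directory of TSV/JSON/figure
#' outputs and a run log; the JSON report echoes every parameter, seed and
#' replicate count needed to re-run it, and is byte-identical across runs
#' with the same config and seed.
#'
#' @param config Named list, or path to a JSON config file. Required fields:
#'   `gff_a`, `gff_b`, `out_dir`, and either `orthologs` (TSV) or both
#'   `blast_ab` and `blast_ba`. Optional: `fasta_a`, `repeats_bed` (enable
#'   the landscape stage), `lengths_a`/`lengths_b` (scaffold-length TSVs),
#'   `replicates` (default 1000), `seed`, `top_k` (default 29),
#'   `adjacency_mode`, `format` (`"png"`/`"svg"`), `repeat_family`,
#'   `min_bitscore`, `max_evalue`, and the landscape parameters
#'   (`gc_window`, `gc_step`, `telomere_motif`, `telomere_min_copies`,
#'   `telomere_end_window`, `cluster_max_gap`, `cluster_min_span`).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  for (f in c("gff_a", "gff_b", "out_dir")) {
    if (is.null(cfg[[f]])) abort(paste0("config is missing required field: ", f))
  }
  if (is.null(cfg$orthologs) && (is.null(cfg$blast_ab) || is.null(cfg$blast_ba))) {
    abort("config needs either 'orthologs' or both 'blast_ab' and 'blast_ba'")
  }
  inputs <- c(
    "gff_a", "gff_b", "orthologs", "blast_ab", "blast_ba",
    "fasta_a", "repeats_bed", "lengths_a", "lengths_b"
  )
  paths <- unlist(cfg[intersect(inputs, names(cfg))])
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("input file not found: ", missing[1]))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- c(
    sprintf("syntenica run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("input %s md5 %s", paths, unname(tools::md5sum(paths)))
  )

  annot_a <- read_gff3(cfg$gff_a, cfg$feature_type, cfg$id_attribute,
    scaffold_lengths = cfg$lengths_a
  )
  annot_b <- read_gff3(cfg$gff_b, cfg$feature_type, cfg$id_attribute,
    scaffold_lengths = cfg$lengths_b
  )
  if (!is.null(cfg$orthologs)) {
    map <- read_orthologs(cfg$orthologs)
  } else {
    map <- reciprocal_best_hits(
      read_blast_tab(cfg$blast_ab), read_blast_tab(cfg$blast_ba),
      min_bitscore = cfg$min_bitscore, max_evalue = cfg$max_evalue
    )
  }
  write_orthologs(map, file.path(cfg$out_dir, "orthologs.tsv"))

  cont <- build_contingency(map, annot_a, annot_b)
  readr::write_tsv(tidy(cont), file.path(cfg$out_dir, "contingency.tsv"),
    progress = FALSE
  )
  rho_test <- synteny_correlation_significance(
    map, annot_a, annot_b,
    replicates = cfg$replicates, seed = cfg$seed
  )
  pairz <- scaffold_pair_significance(
    map, annot_a, annot_b,
    replicates = cfg$replicates, seed = cfg$seed
  )
  readr::write_tsv(as_tibble(pairz), file.path(cfg$out_dir, "scaffold_pair_z.tsv"),
    progress = FALSE
  )
  cpao <- cpao_significance(
    map, annot_a, annot_b,
    replicates = cfg$replicates, seed = cfg$seed,
    adjacency_mode = cfg$adjacency_mode
  )
  readr::write_tsv(cpao$pairs, file.path(cfg$out_dir, "cpao_pairs.tsv"),
    progress = FALSE
  )
  fig <- file.path(cfg$out_dir, paste0("dotplot.", cfg$format))
  render_dotplot(map, annot_a, annot_b, pairz,
    top_k = cfg$top_k,
    out_path = fig, format = cfg$format
  )

  landscape <- NULL
  if (!is.null(cfg$fasta_a)) {
    seqs <- read_fasta(cfg$fasta_a)
    track <- gc_windows(seqs, cfg$gc_window, cfg$gc_step)
    readr::write_tsv(as_tibble(track), file.path(cfg$out_dir, "gc_track.tsv"),
      progress = FALSE
    )
    tel <- detect_telomere_arrays(seqs, cfg$telomere_motif,
      cfg$telomere_min_copies, cfg$telomere_end_window
    )
    readr::write_tsv(tel, file.path(cfg$out_dir, "telomeres.tsv"), progress = FALSE)
    landscape <- list(
      genome_gc = genome_structure_summary(annot_a, seqs)$gc_fraction,
      n_complete = sum(telomere_status(tel)$status == "complete"),
      n_one_ended = sum(telomere_status(tel)$status == "one_ended")
    )
    if (!is.null(cfg$repeats_bed)) {
      clusters <- cluster_repeats(
        read_bed(cfg$repeats_bed),
        family_filter = cfg$repeat_family,
        max_gap = cfg$cluster_max_gap, min_span = cfg$cluster_min_span
      )
      summ <- summarize_clusters(clusters, annot_a,
        telomeres = tel, sequences = seqs
      )
      readr::write_tsv(
        summ$clusters %>% mutate(families = purrr::map_chr(.data$families, paste, collapse = ",")),
        file.path(cfg$out_dir, "repeat_clusters.tsv"),
        progress = FALSE
      )
      landscape$n_clusters <- nrow(summ$clusters)
      landscape$one_cluster_per_scaffold <- all(summ$scaffolds$n_clusters == 1)
    }
  }

  report <- list(
    parameters = cfg[!vapply(cfg, is.null, logical(1))],
    genomes = list(
      a = list(species = annot_a$species, n_scaffolds = nrow(annot_a$scaffolds),
               n_genes = n_genes(annot_a)),
      b = list(species = annot_b$species, n_scaffolds = nrow(annot_b$scaffolds),
               n_genes = n_genes(annot_b))
    ),
    orthology = list(n_pairs = nrow(map)),
    synteny_correlation = as.list(glance(rho_test)),
    cpao = as.list(glance(cpao)),
    scaffold_pairs = list(
      n_significant = sum(pairz$z > 3, na.rm = TRUE),
      n_undefined = sum(pairz$undefined)
    ),
    landscape = landscape
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  log_lines <- c(log_lines, sprintf(
    "rho=%.6f z=%.3f cpao=%d cpao_z=%.3f n_pairs=%d",
    rho_test$rho, rho_test$z, cpao$n_cpao, cpao$z, nrow(map)
  ))
  writeLines(log_lines, log_path)
  invisible(report)
}
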