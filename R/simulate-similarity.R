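# a crude but monotone bitscore -> evalue conversion for simulated records
score_to_evalue <- function(bitscore) 10^(-pmin(bitscore, 300) / 10)

#' Simulate all-vs-all similarity tables for a genome pair
#'
#' Emulates the statistical structure a reciprocal-best-hit search relies on:
#' every true ortholog pair receives reciprocal top-scoring records, a
#' `confusion_rate` fraction of pairs has its A-to-B best hit redirected to a
#' random decoy subject (paralog confusion), and background records with much
#' lower scores are scattered between random non-ortholog pairs.
#'
#' @param pair A `simulated_genome_pair` from [simulate_pair()].
#' @param ortholog_bitscore_mean Mean bitscore of true ortholog records
#'   (default 400).
#' @param background_bitscore_mean Mean bitscore of background records
#'   (default 80); must be below `ortholog_bitscore_mean`.
#' @param confusion_rate Probability a pair's A-to-B best hit is redirected
#'   (default 0).
#' @param background_per_gene Expected background records per true pair in
#'   each direction (default 0.5).
#' @param seed Integer seed.
#' @return List of two similarity tibbles, `ab` (A queries, B subjects) and
#'   `ba`, in the layout of [read_blast_tab()].
#' @export
simulate_similarity <- function(pair, ortholog_bitscore_mean = 400,
                                background_bitscore_mean = 80,
                                confusion_rate = 0,
                                background_per_gene = 0.5, seed = NULL) {
  stopifnot(inherits(pair, "simulated_genome_pair"))
  if (ortholog_bitscore_mean <= background_bitscore_mean) {
    abort("ortholog_bitscore_mean must exceed background_bitscore_mean")
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- pair$truth
  n <- nrow(truth)
  genes_a <- gene_table(pair$genome_a)$gene_id
  genes_b <- gene_table(pair$genome_b)$gene_id

  s <- pmax(
    rnorm(n, ortholog_bitscore_mean, 0.05 * ortholog_bitscore_mean),
    2 * background_bitscore_mean
  )
  ab <- tibble(
    query_id = truth$gene_a, subject_id = truth$gene_b,
    pct_identity = round(runif(n, 60, 95), 1),
    evalue = score_to_evalue(s), bitscore = round(s, 1)
  )
  ba <- tibble(
    query_id = truth$gene_b, subject_id = truth$gene_a,
    pct_identity = ab$pct_identity,
    evalue = ab$evalue, bitscore = ab$bitscore
  )
  confused <- which(runif(n) < confusion_rate)
  if (length(confused) && length(genes_b) > 1) {
    decoys <- vapply(confused, function(i) {
      sample(setdiff(genes_b, truth$gene_b[i]), 1)
    }, character(1))
    ab <- bind_rows(ab, tibble(
      query_id = truth$gene_a[confused], subject_id = decoys,
      pct_identity = round(runif(length(confused), 60, 95), 1),
      evalue = score_to_evalue(s[confused] + 50),
      bitscore = round(s[confused] + 50, 1)
    ))
  }
  m <- round(background_per_gene * n)
  if (m > 0) {
    bg <- function(queries, subjects) {
      sc <- pmax(rnorm(m, background_bitscore_mean, 10), 25)
      tibble(
        query_id = sample(queries, m, replace = TRUE),
        subject_id = sample(subjects, m, replace = TRUE),
        pct_identity = round(runif(m, 25, 50), 1),
        evalue = score_to_evalue(sc), bitscore = round(sc, 1)
      )
    }
    ab <- bind_rows(ab, bg(genes_a, genes_b))
    ba <- bind_rows(ba, bg(genes_b, genes_a))
  }
  list(ab = dedupe_similarity(ab), ba = dedupe_similarity(ba))
}

rand_dna <- function(n, gc) {
  paste(
    sample(c("A", "C", "G", "T"), n,
      replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ),
    collapse = ""
  )
}

#' Simulate scaffold sequences with planted repeat clusters and telomeres
#'
#' Generates i.i.d. background sequence at the requested GC, overwrites
#' planted high-GC repeat-cluster segments (recorded as BED-style intervals
#' split into a few nested-element pieces separated by small gaps), and
#' appends tandem telomere-motif arrays at both scaffold ends (reverse
#' complement on the right). The GC defaults mirror a genome whose repeat
#' clusters run about 61% GC against a 53% background, so clusters appear as
#' local windowed-GC peaks.
#'
#' @param annot [genome_annotation()] supplying scaffold ids and lengths.
#' @param background_gc,cluster_gc Background and planted-cluster GC
#'   fractions (defaults 0.53 and 0.61).
#' @param clusters_per_scaffold Planted clusters per scaffold (default 1;
#'   0 disables planting).
#' @param cluster_span Span of each planted cluster, bp (default 8000).
#' @param elements_per_cluster Number of element intervals a cluster is split
#'   into (default 3).
#' @param element_gap Gap between element intervals within a cluster, bp
#'   (default 300).
#' @param telomere_motif Telomere repeat unit (default `"TTTAGGG"`); empty
#'   string or `telomere_copies = 0` disables arrays.
#' @param telomere_copies Tandem copies planted at each end (default 12).
#' @param family Repeat family label for planted intervals (default
#'   `"Zepp"`, the nested LINE family whose clustering this emulates).
#' @param seed Integer seed.
#' @return List with `sequences` (`DNAStringSet`), `repeats` (interval
#'   tibble, 1-based inclusive), and `truth` (list of `clusters` and
#'   `telomeres` tibbles).
#' @export
simulate_landscape_sequences <- function(annot, background_gc = 0.53,
                                         cluster_gc = 0.61,
                                         clusters_per_scaffold = 1,
                                         cluster_span = 8000,
                                         elements_per_cluster = 3,
                                         element_gap = 300,
                                         telomere_motif = "TTTAGGG",
                                         telomere_copies = 12,
                                         family = "Zepp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scaf <- scaffold_table(annot)
  tel_len <- if (nzchar(telomere_motif)) nchar(telomere_motif) * telomere_copies else 0
  # planted clusters keep >= 2 * margin between one another so they never
  # merge under the default clustering gap
  margin <- 2500
  need <- (2 * tel_len + clusters_per_scaffold * (cluster_span + 2 * margin) + 2000) / 0.7
  if (any(scaf$length < need)) {
    abort(sprintf(
      "scaffold %s too short (%d bp) for the requested landscape (needs >= %d bp)",
      scaf$scaffold_id[scaf$length < need][1],
      as.integer(min(scaf$length)), as.integer(need)
    ))
  }
  seqs <- character(nrow(scaf))
  repeats <- list()
  clusters <- list()
  telomeres <- list()
  for (i in seq_len(nrow(scaf))) {
    L <- as.integer(scaf$length[i])
    sid <- scaf$scaffold_id[i]
    x <- strsplit(rand_dna(L, background_gc), "")[[1]]
    if (clusters_per_scaffold > 0) {
      # one placement slot per cluster in the central 70% of the scaffold
      zone_lo <- tel_len + round(0.15 * L)
      zone_hi <- L - tel_len - round(0.15 * L) - cluster_span
      slot_w <- (zone_hi - zone_lo) / clusters_per_scaffold
      for (k in seq_len(clusters_per_scaffold)) {
        lo <- round(zone_lo + (k - 1) * slot_w + margin)
        hi <- round(zone_lo + k * slot_w - cluster_span - margin)
        cs <- if (hi > lo) sample(lo:hi, 1) else lo
        ce <- cs + cluster_span - 1
        x[cs:ce] <- strsplit(rand_dna(cluster_span, cluster_gc), "")[[1]]
        clusters[[length(clusters) + 1]] <- tibble(
          scaffold_id = sid, start = cs, end = ce
        )
        e_span <- floor((cluster_span - (elements_per_cluster - 1) * element_gap) /
          elements_per_cluster)
        for (e in seq_len(elements_per_cluster)) {
          es <- cs + (e - 1) * (e_span + element_gap)
          repeats[[length(repeats) + 1]] <- tibble(
            scaffold_id = sid, start = es, end = es + e_span - 1, family = family
          )
        }
      }
    }
    if (tel_len > 0) {
      left <- strsplit(strrep(telomere_motif, telomere_copies), "")[[1]]
      right <- strsplit(
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(strrep(telomere_motif, telomere_copies))
        )), ""
      )[[1]]
      x[seq_len(tel_len)] <- left
      x[(L - tel_len + 1):L] <- right
      telomeres[[length(telomeres) + 1]] <- tibble(
        scaffold_id = sid, end = c("left", "right"),
        start = c(1L, L - tel_len + 1L), stop = c(tel_len, L),
        copies = telomere_copies
      )
    }
    seqs[i] <- paste(x, collapse = "")
  }
  list(
    sequences = Biostrings::DNAStringSet(setNames(seqs, scaf$scaffold_id)),
    repeats = if (length(repeats)) bind_rows(repeats) else
      tibble(scaffold_id = character(), start = numeric(), end = numeric(), family = character()),
    truth = list(
      clusters = if (length(clusters)) bind_rows(clusters) else tibble(),
      telomeres = if (length(telomeres)) bind_rows(telomeres) else tibble()
    )
  )
}
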