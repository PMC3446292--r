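#' Sliding-window GC content
#'
#' GC fraction = (G + C) / (A + C + G + T) per window; ambiguous bases and N
#' are excluded from both numerator and denominator, and windows containing
#' no unambiguous base get `NA`. Windows start every `step` bp; the final
#' window of a scaffold is truncated at the scaffold end.
#'
#' @param sequences Named `DNAStringSet` (or named character vector).
#' @param window Window width in bp (default 10000).
#' @param step Step between window starts in bp (default 2000); must not
#'   exceed `window`.
#' @return A `gc_track` tibble: `scaffold_id`, `start`, `end` (1-based
#'   inclusive), `gc_fraction`.
#' @export
gc_windows <- function(sequences, window = 10000, step = 2000) {
  if (window <= 0 || step <= 0) abort("window and step must be positive")
  if (window < step) abort("window must be >= step")
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (length(sequences) == 0) abort("no sequences supplied")
  out <- map_dfr(seq_along(sequences), function(i) {
    x <- sequences[[i]]
    len <- length(x)
    starts <- seq.int(1L, max(1L, len - window + 1L), by = step)
    ends <- pmin(starts + window - 1L, len)
    v <- Biostrings::Views(x, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    tot <- rowSums(freq)
    tibble(
      scaffold_id = names(sequences)[i],
      start = starts, end = ends,
      gc_fraction = ifelse(tot == 0, NA_real_, (freq[, "C"] + freq[, "G"]) / tot)
    )
  })
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("gc_track", class(out))
  out
}

# longest run of gap-free tandem copies of `motif` in sequence `x`
max_tandem_copies <- function(x, motif) {
  hits <- Biostrings::start(Biostrings::matchPattern(motif, x))
  if (!length(hits)) return(0L)
  w <- nchar(as.character(motif))
  # chains of matches each starting exactly one motif length after the last
  runs <- split(hits, cumsum(c(TRUE, diff(hits) != w)))
  max(lengths(runs))
}

#' Detect telomeric repeat arrays at scaffold ends
#'
#' Scans the first and last `end_window` bp of each scaffold for gap-free
#' tandem arrays of the telomere motif, on either strand (the motif and its
#' reverse complement are both tried). An end is called present when the
#' longest tandem run reaches `min_copies`.
#'
#' @param sequences Named `DNAStringSet`.
#' @param motif Telomere repeat unit. Default `"TTTAGGG"`, the plant-type
#'   heptamer typical of green algae; configurable because assemblies differ.
#' @param min_copies Minimum tandem copies to call an array (default 5).
#' @param end_window Window scanned at each scaffold end, bp (default 1000).
#' @return Tibble of telomere calls: `scaffold_id`, `end` (`"left"`/
#'   `"right"`), `motif`, `tandem_copies`, `present`.
#' @seealso [telomere_status()] to classify scaffolds as complete chromosomes.
#' @export
detect_telomere_arrays <- function(sequences, motif = "TTTAGGG",
                                   min_copies = 5, end_window = 1000) {
  if (!nzchar(motif)) abort("motif must be non-empty")
  if (end_window < nchar(motif) * min_copies) {
    abort("end_window is too small to hold min_copies tandem motifs")
  }
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  motifs <- list(
    Biostrings::DNAString(motif),
    Biostrings::reverseComplement(Biostrings::DNAString(motif))
  )
  map_dfr(seq_along(sequences), function(i) {
    x <- sequences[[i]]
    len <- length(x)
    w <- min(end_window, len)
    ends <- list(
      left = Biostrings::subseq(x, 1L, w),
      right = Biostrings::subseq(x, len - w + 1L, len)
    )
    map_dfr(names(ends), function(side) {
      copies <- max(vapply(motifs, function(m) {
        max_tandem_copies(ends[[side]], m)
      }, integer(1)))
      tibble(
        scaffold_id = names(sequences)[i], end = side, motif = motif,
        tandem_copies = copies, present = copies >= min_copies
      )
    })
  })
}

#' Classify scaffolds by telomere-array completeness
#'
#' @param calls Telomere calls from [detect_telomere_arrays()].
#' @return Tibble `scaffold_id`, `status`: `"complete"` (arrays at both
#'   ends), `"one_ended"`, or `"none"`.
#' @export
telomere_status <- function(calls) {
  calls %>%
    group_by(.data$scaffold_id) %>%
    summarise(n_ends = sum(.data$present), .groups = "drop") %>%
    mutate(status = dplyr::case_when(
      .data$n_ends == 2 ~ "complete",
      .data$n_ends == 1 ~ "one_ended",
      TRUE ~ "none"
    )) %>%
    select("scaffold_id", "status")
}

#' Cluster repeat intervals by single-linkage merging
#'
#' Same-scaffold intervals separated by at most `max_gap` bp are merged into
#' one cluster; clusters spanning less than `min_span` bp are discarded.
#' Merging is idempotent: re-clustering the cluster spans returns the same
#' clusters.
#'
#' @param intervals Repeat interval tibble from [read_bed()] (`scaffold_id`,
#'   `start`, `end` 1-based inclusive, `family`).
#' @param family_filter Optional family label to keep (e.g. `"Zepp"`).
#' @param max_gap Maximum gap between merged intervals, bp (default 2000).
#' @param min_span Minimum cluster span, bp (default 1000). Defaults are set
#'   so clusters down to 1.5 kb — the smallest reported for the Zepp family —
#'   survive.
#' @return Tibble of clusters: `scaffold_id`, `start`, `end`, `span`,
#'   `n_elements`, `families`.
#' @export
cluster_repeats <- function(intervals, family_filter = NULL,
                            max_gap = 2000, min_span = 1000) {
  iv <- as_tibble(intervals)
  if (!is.null(family_filter)) iv <- filter(iv, .data$family %in% family_filter)
  if (nrow(iv) == 0) {
    return(tibble(
      scaffold_id = character(), start = numeric(), end = numeric(),
      span = numeric(), n_elements = integer(), families = list()
    ))
  }
  iv %>%
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end)) %>%
    arrange(.data$scaffold_id, .data$start, .data$end) %>%
    group_by(.data$scaffold_id) %>%
    mutate(
      prev_end = cummax(dplyr::lag(.data$end, default = -Inf)),
      new_cluster = .data$start - .data$prev_end - 1 > max_gap,
      cluster = cumsum(.data$new_cluster)
    ) %>%
    group_by(.data$scaffold_id, .data$cluster) %>%
    summarise(
      start = min(.data$start), end = max(.data$end),
      n_elements = dplyr::n(),
      families = list(sort(unique(.data$family))),
      .groups = "drop"
    ) %>%
    mutate(span = .data$end - .data$start + 1) %>%
    filter(.data$span >= min_span) %>%
    select("scaffold_id", "start", "end", "span", "n_elements", "families")
}

#' Positional and GC summary of repeat clusters
#'
#' Classifies each cluster as sub-telomeric (midpoint within
#' `subtelomere_fraction` of scaffold length from either end) or internal,
#' and tabulates clusters per scaffold. With sequences supplied, cluster GC
#' is compared with genome-wide GC — nested high-GC repeat clusters stand out
#' as local GC peaks.
#'
#' @param clusters Cluster tibble from [cluster_repeats()].
#' @param annot [genome_annotation()] providing scaffold lengths.
#' @param telomeres Optional telomere calls from [detect_telomere_arrays()].
#' @param subtelomere_fraction Fraction of scaffold length defining the
#'   sub-telomeric zone at each end (default 0.05). A relative rule behaves
#'   sensibly across scaffolds spanning orders of magnitude in length.
#' @param sequences Optional named `DNAStringSet` for GC computation.
#' @return A `landscape_summary`: list with `clusters` (input plus
#'   `positional_class` and optional `gc_fraction`), `scaffolds` (per-scaffold
#'   cluster counts, positional tallies, telomere status, length), and
#'   `genome_gc` (scalar, `NA` without sequences).
#' @export
summarize_clusters <- function(clusters, annot, telomeres = NULL,
                               subtelomere_fraction = 0.05, sequences = NULL) {
  scaf <- scaffold_table(annot)
  bad <- setdiff(clusters$scaffold_id, scaf$scaffold_id)
  if (length(bad)) abort(paste0("cluster on unknown scaffold: ", bad[1]))
  len <- setNames(as.numeric(scaf$length), scaf$scaffold_id)
  cl <- clusters %>%
    mutate(
      scaffold_length = unname(len[.data$scaffold_id]),
      midpoint = (.data$start + .data$end) / 2,
      positional_class = ifelse(
        .data$midpoint <= subtelomere_fraction * .data$scaffold_length |
          .data$midpoint >= (1 - subtelomere_fraction) * .data$scaffold_length,
        "sub-telomeric", "internal"
      )
    )
  genome_gc <- NA_real_
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      sequences <- Biostrings::DNAStringSet(sequences)
    }
    freq <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
    genome_gc <- sum(freq[, c("C", "G")]) / sum(freq)
    cl$gc_fraction <- map_dbl(seq_len(nrow(cl)), function(i) {
      x <- sequences[[cl$scaffold_id[i]]]
      f <- Biostrings::letterFrequency(
        Biostrings::subseq(x, cl$start[i], cl$end[i]), c("A", "C", "G", "T")
      )
      tot <- sum(f)
      if (tot == 0) NA_real_ else sum(f[c("C", "G")]) / tot
    })
  }
  per_scaf <- tibble(scaffold_id = scaf$scaffold_id, length = scaf$length) %>%
    left_join(
      cl %>%
        group_by(.data$scaffold_id) %>%
        summarise(
          n_clusters = dplyr::n(),
          n_internal = sum(.data$positional_class == "internal"),
          n_subtelomeric = sum(.data$positional_class == "sub-telomeric"),
          .groups = "drop"
        ),
      by = "scaffold_id"
    ) %>%
    mutate(across(
      c("n_clusters", "n_internal", "n_subtelomeric"),
      ~ tidyr::replace_na(.x, 0L)
    ))
  if (!is.null(telomeres)) {
    per_scaf <- left_join(per_scaf, telomere_status(telomeres), by = "scaffold_id")
  }
  structure(
    list(
      clusters = cl %>% select(-"midpoint"),
      scaffolds = per_scaf,
      genome_gc = genome_gc,
      subtelomere_fraction = subtelomere_fraction
    ),
    class = "landscape_summary"
  )
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf(
    "<landscape_summary> %d clusters on %d/%d scaffolds; one-per-scaffold: %s\n",
    nrow(x$clusters), sum(x$scaffolds$n_clusters > 0), nrow(x$scaffolds),
    all(x$scaffolds$n_clusters == 1)
  ))
  invisible(x)
}

#' Genome structure summary statistics
#'
#' Headline assembly numbers: scaffold count, total length, genome GC,
#' gene count and gene density.
#'
#' @param annot [genome_annotation()].
#' @param sequences Optional `DNAStringSet` for GC.
#' @param telomeres Optional telomere calls, adding complete / one-ended
#'   scaffold counts.
#' @return One-row tibble.
#' @export
genome_structure_summary <- function(annot, sequences = NULL, telomeres = NULL) {
  gc <- NA_real_
  if (!is.null(sequences)) {
    freq <- Biostrings::letterFrequency(sequences, c("A", "C", "G", "T"))
    gc <- sum(freq[, c("C", "G")]) / sum(freq)
  }
  out <- tibble(
    species = annot$species,
    n_scaffolds = nrow(annot$scaffolds),
    total_length = sum(annot$scaffolds$length),
    gc_fraction = gc,
    n_genes = nrow(annot$genes),
    kb_per_gene = sum(annot$scaffolds$length) / 1000 / max(1, nrow(annot$genes))
  )
  if (!is.null(telomeres)) {
    st <- telomere_status(telomeres)
    out$n_complete <- sum(st$status == "complete")
    out$n_one_ended <- sum(st$status == "one_ended")
  }
  out
}
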