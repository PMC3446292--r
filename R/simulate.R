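#' Rearrangement event plan
#'
#' Counts of structural events and per-gene loss/gain rates applied to an
#' ancestor genome on one branch. Segment lengths for inversions,
#' transpositions and translocations are geometric in gene units with mean
#' `mean_segment_genes` — a minimal one-parameter size model.
#'
#' @param n_inversions,n_transpositions,n_translocations,n_fusions,n_fissions
#'   Event counts (non-negative integers).
#' @param gene_loss_rate,gene_gain_rate Per-gene probabilities in \[0, 1\].
#' @param mean_segment_genes Mean rearranged-segment length in genes
#'   (default 3).
#' @return An `event_plan` list.
#' @export
event_plan <- function(n_inversions = 0, n_transpositions = 0,
                       n_translocations = 0, n_fusions = 0, n_fissions = 0,
                       gene_loss_rate = 0, gene_gain_rate = 0,
                       mean_segment_genes = 3) {
  counts <- c(n_inversions, n_transpositions, n_translocations, n_fusions, n_fissions)
  if (any(counts < 0)) abort("event counts must be >= 0")
  rates <- c(gene_loss_rate, gene_gain_rate)
  if (any(rates < 0 | rates > 1)) abort("loss/gain rates must be in [0, 1]")
  if (mean_segment_genes < 1) abort("mean_segment_genes must be >= 1")
  structure(
    list(
      n_inversions = n_inversions, n_transpositions = n_transpositions,
      n_translocations = n_translocations, n_fusions = n_fusions,
      n_fissions = n_fissions, gene_loss_rate = gene_loss_rate,
      gene_gain_rate = gene_gain_rate, mean_segment_genes = mean_segment_genes
    ),
    class = "event_plan"
  )
}

#' Simulate an ancestor genome annotation
#'
#' Non-overlapping genes with exponential lengths (floored at 100 bp) and
#' exponential intergenic gaps, strands uniform. The defaults give a gene
#' density of about 5 kb per gene, typical of compact green-algal genomes.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param genes_per_scaffold Genes per scaffold; scalar or vector of length
#'   `n_scaffolds`.
#' @param mean_gene_len Mean gene length, bp (default 1500).
#' @param mean_intergenic Mean intergenic gap, bp (default 3500).
#' @param seed Integer seed.
#' @param species Genome label.
#' @return A [genome_annotation()].
#' @export
simulate_ancestor <- function(n_scaffolds, genes_per_scaffold,
                              mean_gene_len = 1500, mean_intergenic = 3500,
                              seed = NULL, species = "ancestor") {
  stopifnot(n_scaffolds >= 1, all(genes_per_scaffold >= 1))
  if (!is.null(seed)) set.seed(seed)
  k <- rep_len(genes_per_scaffold, n_scaffolds)
  scaffold_ids <- sprintf("scaffold_%02d", seq_len(n_scaffolds))
  gene_counter <- 0L
  rows <- vector("list", n_scaffolds)
  lens <- numeric(n_scaffolds)
  for (s in seq_len(n_scaffolds)) {
    glen <- pmax(100, round(rexp(k[s], 1 / mean_gene_len)))
    gaps <- pmax(50, round(rexp(k[s] + 1, 1 / mean_intergenic)))
    starts <- gaps[1] + cumsum(c(0, glen[-k[s]] + gaps[-c(1, k[s] + 1)]))
    if (k[s] == 1) starts <- gaps[1]
    ends <- starts + glen - 1
    lens[s] <- ends[k[s]] + gaps[k[s] + 1]
    rows[[s]] <- tibble(
      gene_id = sprintf("g%05d", gene_counter + seq_len(k[s])),
      scaffold_id = scaffold_ids[s],
      start = starts, end = ends,
      strand = sample(c("+", "-"), k[s], replace = TRUE)
    )
    gene_counter <- gene_counter + k[s]
  }
  genome_annotation(
    bind_rows(rows),
    tibble(scaffold_id = scaffold_ids, length = lens),
    species = species
  )
}

# ---- event machinery -------------------------------------------------------

# state: list(orders = named list of gene-id vectors, strands = named chr)
annotation_state <- function(annot) {
  g <- gene_table(annot)
  list(
    orders = gene_orders(annot),
    strands = setNames(g$strand, g$gene_id),
    gene_len = setNames(g$end - g$start + 1, g$gene_id)
  )
}

flip <- function(s) ifelse(s == "+", "-", "+")

# deterministic application of one recorded event; shared by the simulator
# and by replay_events(), which is the correctness oracle for event logs
apply_event <- function(state, ev) {
  o <- state$orders
  switch(ev$type,
    inversion = {
      v <- o[[ev$scaffold]]
      seg <- ev$from:(ev$from + ev$len - 1)
      v[seg] <- rev(v[seg])
      state$strands[v[seg]] <- flip(state$strands[v[seg]])
      o[[ev$scaffold]] <- v
    },
    transposition = {
      v <- o[[ev$scaffold]]
      seg <- v[ev$from:(ev$from + ev$len - 1)]
      rest <- v[-(ev$from:(ev$from + ev$len - 1))]
      o[[ev$scaffold]] <- append(rest, seg, after = ev$to)
    },
    translocation = {
      v <- o[[ev$from_scaffold]]
      seg <- v[ev$from:(ev$from + ev$len - 1)]
      o[[ev$from_scaffold]] <- v[-(ev$from:(ev$from + ev$len - 1))]
      o[[ev$to_scaffold]] <- append(o[[ev$to_scaffold]], seg, after = ev$to)
    },
    fusion = {
      o[[ev$first]] <- c(o[[ev$first]], o[[ev$second]])
      o[[ev$second]] <- NULL
    },
    fission = {
      v <- o[[ev$scaffold]]
      o[[ev$scaffold]] <- v[seq_len(ev$at)]
      new <- list(v[-seq_len(ev$at)])
      names(new) <- ev$new_id
      o <- append(o, new, after = which(names(o) == ev$scaffold))
    },
    loss = {
      for (s in names(o)) o[[s]] <- setdiff(o[[s]], ev$genes)
      state$strands <- state$strands[!names(state$strands) %in% ev$genes]
    },
    gain = {
      o[[ev$scaffold]] <- append(o[[ev$scaffold]], ev$gene, after = ev$at)
      state$strands[ev$gene] <- ev$strand
      state$gene_len[ev$gene] <- ev$gene_len
    },
    abort(paste0("unknown event type: ", ev$type))
  )
  state$orders <- o
  state
}

draw_segment <- function(k, mean_len) {
  len <- min(1L + stats::rgeom(1, 1 / mean_len), k)
  from <- sample.int(k - len + 1L, 1)
  c(from = from, len = len)
}

draw_event <- function(state, type, mean_segment) {
  o <- state$orders
  ks <- lengths(o)
  for (try in 1:100) {
    ev <- switch(type,
      inversion = {
        ok <- which(ks >= 2)
        if (!length(ok)) next
        s <- names(o)[sample(ok, 1)]
        seg <- draw_segment(ks[[s]], mean_segment)
        list(type = type, scaffold = s, from = unname(seg["from"]), len = unname(seg["len"]))
      },
      transposition = {
        ok <- which(ks >= 2)
        if (!length(ok)) next
        s <- names(o)[sample(ok, 1)]
        seg <- draw_segment(ks[[s]], mean_segment)
        to <- sample.int(ks[[s]] - seg["len"] + 1L, 1) - 1L
        list(
          type = type, scaffold = s, from = unname(seg["from"]),
          len = unname(seg["len"]), to = unname(to)
        )
      },
      translocation = {
        if (length(o) < 2) next
        ok <- which(ks >= 1)
        if (!length(ok)) next
        s1 <- names(o)[sample(ok, 1)]
        s2 <- sample(setdiff(names(o), s1), 1)
        seg <- draw_segment(ks[[s1]], mean_segment)
        to <- sample.int(ks[[s2]] + 1L, 1) - 1L
        list(
          type = type, from_scaffold = s1, from = unname(seg["from"]),
          len = unname(seg["len"]), to_scaffold = s2, to = unname(to)
        )
      },
      fusion = {
        if (length(o) < 2) next
        pick <- sample(names(o), 2)
        list(type = type, first = pick[1], second = pick[2])
      },
      fission = {
        ok <- which(ks >= 2)
        if (!length(ok)) next
        s <- names(o)[sample(ok, 1)]
        list(
          type = type, scaffold = s, at = sample.int(ks[[s]] - 1L, 1),
          new_id = paste0(s, "_fis", sample.int(1e6, 1))
        )
      }
    )
    if (!is.null(ev)) return(ev)
  }
  abort(paste0("could not draw a feasible event of type: ", type))
}

# lay gene orders back onto coordinates with a fixed intergenic spacing;
# every statistic in scope depends on order and membership, not exact bp
layout_annotation <- function(state, spacing, species) {
  o <- state$orders
  o <- o[order(names(o))]
  rows <- vector("list", length(o))
  lens <- numeric(length(o))
  for (s in seq_along(o)) {
    ids <- o[[s]]
    k <- length(ids)
    if (k == 0) {
      lens[s] <- spacing
      rows[[s]] <- NULL
      next
    }
    glen <- unname(state$gene_len[ids])
    starts <- spacing + cumsum(c(0, glen[-k] + spacing))
    rows[[s]] <- tibble(
      gene_id = ids, scaffold_id = names(o)[s],
      start = starts, end = starts + glen - 1,
      strand = unname(state$strands[ids])
    )
    lens[s] <- starts[k] + glen[k] - 1 + spacing
  }
  genome_annotation(
    bind_rows(rows),
    tibble(scaffold_id = names(o), length = lens),
    species = species
  )
}

#' Apply a rearrangement plan to a genome
#'
#' Draws and applies the plan's events in random order: an inversion reverses
#' a contiguous gene segment and flips its strands; a transposition moves a
#' segment elsewhere on the same scaffold; a translocation moves a segment to
#' another scaffold; a fusion concatenates two scaffolds; a fission splits
#' one. Gene losses (dropped from the truth map) and gains (inserted without
#' orthologs) are applied last. Coordinates of the derived genome are re-laid
#' out with a fixed intergenic spacing.
#'
#' @param annot Ancestor [genome_annotation()].
#' @param plan An [event_plan()].
#' @param seed Integer seed.
#' @param spacing Intergenic spacing of the re-laid-out derived genome, bp.
#' @param species Label for the derived genome.
#' @return List with `annotation` (derived genome), `events` (ordered event
#'   log; replaying it with [replay_events()] reproduces the derived gene
#'   order exactly), and `truth` (tibble `gene_in`/`gene_out` of surviving
#'   ancestor genes).
#' @export
apply_events <- function(annot, plan, seed = NULL, spacing = 3500,
                         species = paste0(annot$species, "_derived")) {
  stopifnot(inherits(plan, "event_plan"))
  if (!is.null(seed)) set.seed(seed)
  state <- annotation_state(annot)
  types <- rep(
    c("inversion", "transposition", "translocation", "fusion", "fission"),
    times = c(
      plan$n_inversions, plan$n_transpositions, plan$n_translocations,
      plan$n_fusions, plan$n_fissions
    )
  )
  if (length(types) > 1) types <- sample(types)
  events <- list()
  for (ty in types) {
    ev <- draw_event(state, ty, plan$mean_segment_genes)
    state <- apply_event(state, ev)
    events[[length(events) + 1]] <- ev
  }
  ancestor_ids <- gene_table(annot)$gene_id
  if (plan$gene_loss_rate > 0) {
    lost <- ancestor_ids[runif(length(ancestor_ids)) < plan$gene_loss_rate]
    if (length(lost)) {
      ev <- list(type = "loss", genes = lost)
      state <- apply_event(state, ev)
      events[[length(events) + 1]] <- ev
    }
  }
  if (plan$gene_gain_rate > 0) {
    n_gain <- rbinom(1, length(ancestor_ids), plan$gene_gain_rate)
    mean_len <- round(mean(state$gene_len))
    for (i in seq_len(n_gain)) {
      ks <- lengths(state$orders)
      s <- sample(names(state$orders), 1, prob = ks + 1)
      ev <- list(
        type = "gain", gene = sprintf("novel%04d", i), scaffold = s,
        at = sample.int(ks[[s]] + 1L, 1) - 1L,
        strand = sample(c("+", "-"), 1), gene_len = mean_len
      )
      state <- apply_event(state, ev)
      events[[length(events) + 1]] <- ev
    }
  }
  derived <- layout_annotation(state, spacing, species)
  surv <- intersect(ancestor_ids, gene_table(derived)$gene_id)
  list(
    annotation = derived,
    events = events,
    truth = tibble(gene_in = surv, gene_out = surv)
  )
}

#' Replay an event log on an ancestor genome
#'
#' Deterministically re-applies a recorded event log; the result must equal
#' the gene order of the derived genome the log came from.
#'
#' @param annot Ancestor [genome_annotation()].
#' @param events Event log from [apply_events()].
#' @return Named list of per-scaffold gene-id vectors in final order.
#' @export
replay_events <- function(annot, events) {
  state <- annotation_state(annot)
  for (ev in events) state <- apply_event(state, ev)
  state$orders
}

# prefix ancestor gene ids with a species tag so the two derived genomes
# share no identifier
rename_genes <- function(annot, prefix) {
  g <- gene_table(annot) %>% mutate(gene_id = paste0(prefix, .data$gene_id))
  genome_annotation(g, scaffold_table(annot), species = annot$species)
}

#' Simulate a pair of genomes descended from one ancestor
#'
#' Two independent branches apply their own [event_plan()] to a simulated
#' ancestor. The true ortholog map contains exactly the ancestor genes never
#' lost on either branch; gained genes have no orthologs. Gene ids carry the
#' prefixes `A_`/`B_` so the two genomes share no identifier.
#'
#' @param plan_a,plan_b [event_plan()]s for the two branches.
#' @param n_scaffolds,genes_per_scaffold,mean_gene_len,mean_intergenic
#'   Ancestor parameters, passed to [simulate_ancestor()].
#' @param seed Integer seed governing the whole simulation.
#' @return A `simulated_genome_pair`: list with `ancestor`, `genome_a`,
#'   `genome_b`, `truth` (tibble `gene_a`/`gene_b`), `events_a`, `events_b`
#'   (logs in ancestor id space), and `seed`.
#' @export
simulate_pair <- function(plan_a = event_plan(), plan_b = event_plan(),
                          n_scaffolds = 10, genes_per_scaffold = 40,
                          mean_gene_len = 1500, mean_intergenic = 3500,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ancestor <- simulate_ancestor(
    n_scaffolds, genes_per_scaffold, mean_gene_len, mean_intergenic,
    species = "ancestor"
  )
  res_a <- apply_events(ancestor, plan_a, spacing = mean_intergenic, species = "genome_A")
  res_b <- apply_events(ancestor, plan_b, spacing = mean_intergenic, species = "genome_B")
  surv <- sort(intersect(res_a$truth$gene_in, res_b$truth$gene_in))
  structure(
    list(
      ancestor = ancestor,
      genome_a = rename_genes(res_a$annotation, "A_"),
      genome_b = rename_genes(res_b$annotation, "B_"),
      truth = tibble(gene_a = paste0("A_", surv), gene_b = paste0("B_", surv)),
      events_a = res_a$events, events_b = res_b$events,
      seed = seed
    ),
    class = "simulated_genome_pair"
  )
}

#' @export
print.simulated_genome_pair <- function(x, ...) {
  cat(sprintf(
    "<simulated_genome_pair> %d/%d genes, %d true ortholog pairs, %d + %d events\n",
    n_genes(x$genome_a), n_genes(x$genome_b), nrow(x$truth),
    length(x$events_a), length(x$events_b)
  ))
  invisible(x)
}
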