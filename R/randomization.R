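# scaffold index vectors for the two sides of an ortholog map; the working
# form of every re-association null replicate
map_scaffold_indices <- function(map, annot_a, annot_b) {
  map <- validate_map(map, annot_a, annot_b)
  sa <- scaffold_table(annot_a)$scaffold_id
  sb <- scaffold_table(annot_b)$scaffold_id
  ga <- gene_table(annot_a)
  gb <- gene_table(annot_b)
  list(
    a_idx = match(ga$scaffold_id[match(map$gene_a, ga$gene_id)], sa),
    b_idx = match(gb$scaffold_id[match(map$gene_b, gb$gene_id)], sb),
    row_ids = sa, col_ids = sb, n = nrow(map)
  )
}

#' Re-associate ortholog pairs at random (the non-syntenic null)
#'
#' The null model behind the pairwise scaffold Z-scores and the synteny
#' correlation significance: the genome-B members of the ortholog pairs are
#' permuted uniformly at random among the pairs. Every gene keeps its
#' scaffold, so the number of mapped orthologs per scaffold — all contingency
#' marginals — is conserved by construction, and the result is one-to-one.
#'
#' @param map Ortholog map tibble.
#' @param seed Integer seed (optional; set for reproducibility).
#' @return A tibble with the same `gene_a` column and permuted `gene_b`.
#' @export
randomize_ortholog_assignment <- function(map, seed = NULL) {
  map <- as_tibble(map)
  if (nrow(map) == 0) abort("cannot randomize an empty ortholog map")
  if (!is.null(seed)) set.seed(seed)
  tibble(gene_a = map$gene_a, gene_b = map$gene_b[sample.int(nrow(map))])
}

#' Pairwise scaffold synteny Z-scores
#'
#' For every scaffold pair (i, j), compares the observed number of shared
#' ortholog pairs with its distribution under the re-association null
#' ([randomize_ortholog_assignment()]):
#' z = (observed - null mean) / null sd, with the null moments estimated from
#' `replicates` randomized datasets (population standard deviation).
#' Pairs whose count is constant under the null (sd = 0) are flagged
#' `undefined` and get `z = NA`, never 0 or infinity. By the convention used
#' throughout, z > 3 marks significantly elevated sharing (one-sided
#' P < 0.01).
#'
#' @inheritParams build_contingency
#' @param replicates Number of null datasets (>= 2). Default 1000.
#' @param seed Integer seed for the null randomization.
#' @return A `scaffold_pair_z` tibble: `scaffold_a`, `scaffold_b`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `undefined`, with attributes
#'   `replicates` and `seed`.
#' @export
scaffold_pair_significance <- function(map, annot_a, annot_b,
                                       replicates = 1000, seed = NULL) {
  if (replicates < 2) abort("replicates must be >= 2")
  idx <- map_scaffold_indices(map, annot_a, annot_b)
  R <- length(idx$row_ids)
  C <- length(idx$col_ids)
  obs <- tabulate((idx$a_idx - 1L) * C + idx$b_idx, nbins = R * C)
  if (!is.null(seed)) set.seed(seed)
  s1 <- numeric(R * C)
  s2 <- numeric(R * C)
  for (r in seq_len(replicates)) {
    cnt <- tabulate(
      (idx$a_idx - 1L) * C + idx$b_idx[sample.int(idx$n)],
      nbins = R * C
    )
    s1 <- s1 + cnt
    s2 <- s2 + cnt * cnt
  }
  mu <- s1 / replicates
  sdv <- sqrt(pmax(s2 / replicates - mu^2, 0))
  undef <- sdv < 1e-12
  z <- ifelse(undef, NA_real_, (obs - mu) / sdv)
  out <- tibble(
    scaffold_a = rep(idx$row_ids, each = C),
    scaffold_b = rep(idx$col_ids, times = R),
    observed = obs, null_mean = mu, null_sd = sdv,
    z = z, undefined = undef
  )
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  class(out) <- c("scaffold_pair_z", class(out))
  out
}

#' Synteny correlation with significance against the re-association null
#'
#' Computes [synteny_correlation()] on the real ortholog map, then estimates
#' the null mean and standard deviation of the statistic from `replicates`
#' randomized datasets in which the ortholog pairs are re-associated at
#' random (per-scaffold ortholog counts fixed), and reports the Z-score.
#'
#' @inheritParams scaffold_pair_significance
#' @return A `synteny_test` object with fields `rho`, `null_mean`,
#'   `null_sd`, `z`, `undefined`, `replicates`, `seed`. `tidy()` and
#'   `glance()` methods return one-row tibbles.
#' @export
synteny_correlation_significance <- function(map, annot_a, annot_b,
                                             replicates = 1000, seed = NULL) {
  if (replicates < 2) abort("replicates must be >= 2")
  idx <- map_scaffold_indices(map, annot_a, annot_b)
  R <- length(idx$row_ids)
  C <- length(idx$col_ids)
  obs_m <- matrix(
    tabulate((idx$a_idx - 1L) * C + idx$b_idx, nbins = R * C),
    nrow = R, ncol = C, byrow = TRUE
  )
  rho_obs <- synteny_correlation(obs_m)
  # marginals are invariant under the null, so the expected matrix and the
  # set of informative rows/columns are fixed across replicates
  keep_r <- rowSums(obs_m) > 0
  keep_c <- colSums(obs_m) > 0
  n <- idx$n
  ri <- rowSums(obs_m)[keep_r]
  cj <- colSums(obs_m)[keep_c]
  marg <- outer(ri, cj)
  denom <- n * min(length(ri) - 1, length(cj) - 1)
  if (!is.null(seed)) set.seed(seed)
  rho_null <- numeric(replicates)
  for (r in seq_len(replicates)) {
    cnt <- matrix(
      tabulate((idx$a_idx - 1L) * C + idx$b_idx[sample.int(n)], nbins = R * C),
      nrow = R, ncol = C, byrow = TRUE
    )[keep_r, keep_c, drop = FALSE]
    rho_null[r] <- (n * sum(cnt^2 / marg) - n) / denom
  }
  mu <- mean(rho_null)
  sdv <- sqrt(mean((rho_null - mu)^2))
  undef <- sdv < 1e-12
  structure(
    list(
      statistic = "synteny_correlation",
      rho = rho_obs, null_mean = mu, null_sd = sdv,
      z = if (undef) NA_real_ else (rho_obs - mu) / sdv,
      undefined = undef, replicates = replicates, seed = seed
    ),
    class = "synteny_test"
  )
}

#' @export
print.synteny_test <- function(x, ...) {
  cat(sprintf(
    "Synteny correlation rho = %.4f (null %.4f +/- %.4f over %d replicates), Z = %s\n",
    x$rho, x$null_mean, x$null_sd, x$replicates,
    if (x$undefined) "undefined (null sd = 0)" else sprintf("%.2f", x$z)
  ))
  invisible(x)
}

#' @export
tidy.synteny_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, estimate = x$rho,
    null_mean = x$null_mean, null_sd = x$null_sd, z = x$z,
    undefined = x$undefined
  )
}

#' @export
glance.synteny_test <- function(x, ...) {
  tibble(
    rho = x$rho, z = x$z, null_mean = x$null_mean, null_sd = x$null_sd,
    replicates = x$replicates, seed = x$seed %||% NA_integer_
  )
}
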