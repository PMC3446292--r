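#' Scaffold-by-scaffold ortholog-sharing contingency table
#'
#' Cell (i, j) counts the genes on scaffold i of genome A whose ortholog lies
#' on scaffold j of genome B. Scaffolds with no mapped ortholog appear as
#' all-zero rows/columns; they are excluded only inside the synteny
#' correlation, where the expected count would be zero.
#'
#' @param map Ortholog map tibble (`gene_a`, `gene_b`), one-to-one.
#' @param annot_a,annot_b [genome_annotation()]s for the two genomes.
#' @return A `synteny_contingency`: integer matrix of counts with scaffold
#'   ids as dimnames, plus `n` (total pairs) as an attribute.
#' @export
build_contingency <- function(map, annot_a, annot_b) {
  map <- validate_map(map, annot_a, annot_b)
  sa <- scaffold_table(annot_a)$scaffold_id
  sb <- scaffold_table(annot_b)$scaffold_id
  ga <- gene_table(annot_a)
  gb <- gene_table(annot_b)
  fa <- factor(ga$scaffold_id[match(map$gene_a, ga$gene_id)], levels = sa)
  fb <- factor(gb$scaffold_id[match(map$gene_b, gb$gene_id)], levels = sb)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(scaffold_a = sa, scaffold_b = sb)
  structure(counts,
    n = sum(counts),
    class = c("synteny_contingency", "matrix", "array")
  )
}

#' @export
print.synteny_contingency <- function(x, ...) {
  cat(sprintf(
    "<synteny_contingency> %d x %d scaffolds, n = %d ortholog pairs\n",
    nrow(x), ncol(x), sum(x)
  ))
  print(unclass(x)[seq_len(min(8, nrow(x))), seq_len(min(8, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @export
tidy.synteny_contingency <- function(x, ...) {
  m <- unclass(x)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  tibble(
    scaffold_a = rep(rownames(m), times = ncol(m)),
    scaffold_b = rep(colnames(m), each = nrow(m)),
    observed = as.vector(m),
    expected = as.vector(e)
  )
}

#' Synteny correlation coefficient
#'
#' The chi-square-derived association measure of Housworth and Postlethwait
#' over the ortholog-sharing contingency table:
#' \deqn{\rho = \sum_{i=1}^{r}\sum_{j=1}^{c}
#'   \frac{(n_{ij} - e_{ij})^2}{n\,\min\{r-1, c-1\}\, e_{ij}},\qquad
#'   e_{ij} = n_{i\cdot} n_{\cdot j} / n.}
#' \eqn{\rho} is 1 at perfect scaffold-to-scaffold association (every row and
#' column has a single nonzero cell, any sizes) and 0 exactly at independence
#' (\eqn{n_{ij} = e_{ij}} everywhere). Rows or columns whose marginal total is
#' zero carry no orthology information and would make \eqn{e_{ij} = 0}; they
#' are dropped, and r and c shrink accordingly.
#'
#' @param x A `synteny_contingency` from [build_contingency()], or any
#'   non-negative count matrix.
#' @return The scalar \eqn{\rho}.
#' @examples
#' synteny_correlation(matrix(c(4, 0, 0, 4), 2)) # 1
#' synteny_correlation(matrix(c(2, 2, 2, 2), 2)) # 0
#' synteny_correlation(matrix(c(3, 1, 1, 3), 2)) # 0.25
#' @export
synteny_correlation <- function(x) {
  m <- unclass(as.matrix(x))
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("negative counts in contingency matrix")
  n <- sum(m)
  if (n == 0) abort("synteny correlation undefined: no ortholog pairs (n = 0)")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  r <- nrow(m)
  c <- ncol(m)
  if (r < 2 || c < 2) {
    abort("synteny correlation undefined: fewer than 2 scaffolds with orthologs in a genome")
  }
  # chi-square via n * sum(n_ij^2 / (n_i. n_.j)) - n: algebraically equal to
  # sum((n_ij - e_ij)^2 / e_ij) but exact in floating point for the perfect
  # one-to-one association (integer counts), so rho = 1 is reported exactly
  chi2 <- n * sum(m^2 / outer(rowSums(m), colSums(m))) - n
  chi2 / (n * min(r - 1, c - 1))
}
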