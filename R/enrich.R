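#' One-sided hypergeometric overrepresentation test
#'
#' Exact upper-tail probability of observing `k` or more annotated genes in
#' a draw of `n` from a universe of `N` containing `m` annotated genes:
#' `p = sum_{i=k}^{min(m,n)} C(m,i) C(N-m, n-i) / C(N,n)`.
#'
#' @param k Overlap (DEGs in the set).
#' @param m Set size within the universe.
#' @param n DEG-list size.
#' @param N Universe size.
#' @return p-value in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeometric_test <- function(k, m, n, N) {
  bad <- k < 0 | m < 0 | n < 0 | N < 0 | k > pmin(m, n) | m > N | n > N
  if (any(bad)) stop("invalid input: inconsistent hypergeometric counts")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Direction-specific gene-set overrepresentation
#'
#' Tests each gene set for overrepresentation of the contrast's DEGs of one
#' direction against the measured-gene universe (all genes measured in the
#' stratum after probe collapse). Sets are intersected with the universe
#' before sizing. P-values are BH-adjusted across all sets within the
#' (contrast, direction); a set is "active" when its adjusted p is below
#' `set_fdr` (strict `<`, default FDR < 5%).
#'
#' @param gene_deg Gene-level DegTable for one contrast
#'   (see [collapse_probes_to_genes()]).
#' @param gene_sets Named list of gene-id vectors.
#' @param direction `"up"` or `"down"`.
#' @param universe Character vector of measured gene ids; defaults to
#'   `gene_deg$gene_id`.
#' @param set_fdr Activity threshold on adjusted p.
#' @return data.frame per set: contrast key, `set_name`, `direction`, `k`,
#'   `m`, `n`, `N`, `pvalue`, `padj`, `active`.
#' @export
enrich <- function(gene_deg, gene_sets, direction = c("up", "down"),
                   universe = NULL, set_fdr = 0.05) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- unique(gene_deg$gene_id)
  if (length(universe) == 0L) stop("invalid input: empty universe")
  degs <- unique(gene_deg$gene_id[gene_deg$is_dep &
                                    !is.na(gene_deg$direction) &
                                    gene_deg$direction == direction])
  degs <- intersect(degs, universe)
  N <- length(universe)
  n <- length(degs)
  m <- vapply(gene_sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(gene_sets, function(s) length(intersect(s, degs)), 0L)
  p <- if (n == 0L) rep(1, length(gene_sets)) else
    hypergeometric_test(k, m, n, N)
  padj <- p.adjust(p, method = "BH")
  key <- gene_deg[1, c("species_strain", "chemical", "concentration_label",
                       "timepoint_h"), drop = FALSE]
  out <- data.frame(key, set_name = names(gene_sets), direction = direction,
                    k = unname(k), m = unname(m), n = n, N = N,
                    pvalue = unname(p), padj = unname(padj),
                    active = unname(padj < set_fdr),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}
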