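#' Map interacting genes to the gene sets containing them
#'
#' For each interacting gene in the catalog (union over chemicals), finds
#' every gene set that contains it. A set containing several interacting
#' genes serves all of them.
#'
#' @param catalog data.frame `chemical`, `rank`, `gene_id` (per-chemical
#'   top interacting genes, as curated chemical-gene interaction databases
#'   provide; at most 10 per chemical).
#' @param gene_sets Named list of gene-id vectors.
#' @return Named list gene_id -> character vector of containing set names
#'   (possibly empty, with a warning).
#' @export
select_targeted_sets <- function(catalog, gene_sets) {
  stopifnot(nrow(catalog) > 0, all(c("chemical", "gene_id") %in%
                                     names(catalog)))
  genes <- unique(catalog$gene_id)
  out <- lapply(genes, function(g)
    names(gene_sets)[vapply(gene_sets, function(s) g %in% s, logical(1))])
  names(out) <- genes
  empty <- genes[lengths(out) == 0L]
  if (length(empty))
    warning("interacting genes absent from every set: ",
            paste(empty, collapse = ", "))
  out
}

#' Reverse-log scaling of adjusted p-values
#'
#' Maps the adjusted p-values of significant gene sets onto (0, 1] so that
#' the most significant set in the pool scores exactly 1 and significance
#' order is preserved: `s_i = log10(p_i) / log10(p_min)` where `p_min` is
#' the smallest adjusted p in the pool. Non-significant sets (adjusted
#' p >= `alpha`) score 0. P-values are floored at `p_floor` before the log.
#'
#' The pool must span all treatment groups and timepoints of a
#' species/strain so scores are comparable across groups.
#'
#' @param adj_p Numeric vector of adjusted p-values.
#' @param alpha Significance threshold (strict `<`; default 0.05).
#' @param p_floor Lower floor protecting the logarithm.
#' @param p_min Optional externally supplied pool minimum (overrides the
#'   minimum of `adj_p`), for scaling one group against a species-wide pool.
#' @return Numeric vector of scaled values in `[0, 1]`.
#' @export
reverse_log_scale <- function(adj_p, alpha = 0.05, p_floor = 1e-300,
                              p_min = NULL) {
  sig <- !is.na(adj_p) & adj_p < alpha
  s <- numeric(length(adj_p))
  if (!any(sig) && is.null(p_min)) return(s)
  p <- pmax(adj_p, p_floor)
  pm <- if (is.null(p_min)) min(p[sig]) else max(p_min, p_floor)
  s[sig] <- log10(p[sig]) / log10(pm)
  s
}

#' Sum reverse-log-scaled values per interacting gene
#'
#' For one treatment group's enrichment results, sums the scaled values of
#' every gene set containing each interacting gene.
#'
#' @param scaled Named numeric vector (set name -> scaled value) for one
#'   treatment group.
#' @param gene_to_sets Map from [select_targeted_sets()].
#' @return Named numeric vector gene -> raw sum (>= 0).
#' @export
aggregate_by_gene <- function(scaled, gene_to_sets) {
  vapply(gene_to_sets, function(sets)
    sum(scaled[intersect(sets, names(scaled))]), numeric(1))
}

#' Internal scaling of aggregation scores
#'
#' Scales one treatment group's per-gene sums relative to each other:
#' each value divided by the group's maximum (all zeros stay zero), so the
#' strongest gene within the group scores exactly 1.
#'
#' @param raw_sums Named numeric vector for one group.
#' @return Scaled vector in `[0, 1]`.
#' @export
scale_internal <- function(raw_sums) {
  m <- max(raw_sums)
  if (m <= 0) return(raw_sums * 0)
  raw_sums / m
}

#' External scaling of aggregation scores
#'
#' Scales each gene's sums across all treatment groups and timepoints of a
#' species/strain: each column (gene) divided by its maximum over groups,
#' so each gene with any signal attains 1 in its strongest group.
#'
#' @param score_matrix Groups x genes matrix of raw sums.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
scale_external <- function(score_matrix) {
  stopifnot(is.matrix(score_matrix))
  mx <- apply(score_matrix, 2, max)
  mx[mx <= 0] <- 1          # all-zero genes stay zero
  sweep(score_matrix, 2, mx, "/")
}

#' Aggregate enrichment results over interacting genes for a species/strain
#'
#' End-to-end targeted aggregation: pools the adjusted p-values of
#' significant targeted sets over all supplied treatment groups, reverse-log
#' scales them against the pool minimum, sums per interacting gene within
#' each group, and applies both internal and external scaling.
#'
#' @param enrich_list Named list (group id -> EnrichmentTable of that
#'   group) covering all treatment groups/timepoints of one species/strain.
#' @param gene_to_sets Map from [select_targeted_sets()].
#' @param alpha Significance threshold for pool membership.
#' @return List with `raw` (groups x genes matrix of sums), `internal`,
#'   `external` (same shape, scaled).
#' @export
aggregate_interacting_genes <- function(enrich_list, gene_to_sets,
                                        alpha = 0.05) {
  stopifnot(is.list(enrich_list), !is.null(names(enrich_list)))
  targeted <- unique(unlist(gene_to_sets, use.names = FALSE))
  pool <- unlist(lapply(enrich_list, function(e)
    e$padj[e$set_name %in% targeted & e$padj < alpha]))
  p_min <- if (length(pool)) min(pool) else NULL
  genes <- names(gene_to_sets)
  raw <- matrix(0, nrow = length(enrich_list), ncol = length(genes),
                dimnames = list(names(enrich_list), genes))
  for (g in names(enrich_list)) {
    e <- enrich_list[[g]]
    scaled <- setNames(
      reverse_log_scale(e$padj, alpha = alpha, p_min = p_min), e$set_name)
    raw[g, ] <- aggregate_by_gene(scaled, gene_to_sets)
  }
  rowmax <- apply(raw, 1, max)
  rowmax[rowmax <= 0] <- 1
  internal <- sweep(raw, 1, rowmax, "/")
  list(raw = raw, internal = internal, external = scale_external(raw))
}

#' Export aggregation scores as a ToxPi-compatible wide CSV
#'
#' Rows are treatment groups, columns are interacting genes; values are the
#' chosen scaling. Loadable by radial "pie-wedge" scoring tools.
#'
#' @param score_matrix Groups x genes matrix (one element of
#'   [aggregate_interacting_genes()]'s result).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_toxpi <- function(score_matrix, path) {
  stopifnot(is.matrix(score_matrix))
  if (nrow(score_matrix) == 0L)
    warning("empty score matrix; writing header only")
  df <- data.frame(group_id = rownames(score_matrix), score_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
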