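#' Median-of-ratios normalization
#'
#' Computes per-sample size factors by the median-of-ratios method: the
#' reference profile is the per-probe geometric mean over samples, taken on
#' probes with all-positive counts; each sample's factor is the median over
#' those probes of count/reference. Factors are then rescaled to geometric
#' mean exactly 1 so that normalized library sizes are anchored to the
#' study's overall scale.
#'
#' @param counts Probe x sample count matrix, non-negative.
#' @return List with `normalized` (counts / size factor, same dim) and
#'   `size_factors` (named numeric, geometric mean 1).
#' @export
median_of_ratios_normalize <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (any(colSums(counts) == 0))
    stop("every sample must have at least one probe with a nonzero count")
  if (ncol(counts) == 1L) {
    sf <- setNames(1, colnames(counts))
    return(list(normalized = counts, size_factors = sf))
  }
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no probe with all-positive counts; rerun with total-count ",
         "scaling (normalize_total_count) instead")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logref)))
  sf <- sf / exp(mean(log(sf)))     # anchor geometric mean to 1
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

#' Total-count normalization fallback
#'
#' Used when no probe has all-positive counts (very sparse matrices):
#' size factor proportional to total depth, rescaled to geometric mean 1.
#'
#' @param counts Probe x sample count matrix.
#' @return Same shape of result as [median_of_ratios_normalize()].
#' @export
normalize_total_count <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  depth <- colSums(counts)
  if (any(depth == 0)) stop("sample with zero total count")
  sf <- depth / exp(mean(log(depth)))
  list(normalized = sweep(counts, 2, sf, "/"), size_factors = sf)
}

# Vectorized Welch two-sample t-test on rows of two matrices.
# Zero-variance degenerate rows: p = 1 when the means agree, ~0 otherwise.
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, var); v2 <- apply(b, 1, var)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  p <- numeric(length(diff))
  zero <- se2 == 0
  p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  ok <- !zero
  tstat <- diff[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  list(diff = diff, p = p)
}

#' Test one treatment-vs-control contrast
#'
#' For one chemical x concentration label x timepoint x species/strain,
#' compares treated wells with the matched solvent-control wells of the same
#' stratum and timepoint on `log2(normalized + 1)`: per probe, log2FC is the
#' difference of arm means and the p-value comes from an unequal-variance
#' (Welch) t-test. P-values are Benjamini-Hochberg adjusted across all
#' probes within the contrast; a probe is a differentially expressed probe
#' (DEP) when its adjusted p is below `deg_fdr` (default FDR < 10%).
#' Direction (`up`/`down`) is reported for DEPs only.
#'
#' @param normalized Normalized probe x sample matrix.
#' @param metadata Sample metadata (see [design_metadata()]); only samples
#'   present as columns of `normalized` are considered, so pass a QC-filtered
#'   matrix to honor exclusions.
#' @param species_strain,chemical,concentration_label,timepoint_h Contrast key.
#' @param probe_map data.frame `probe_id`, `gene_id`.
#' @param deg_fdr DEP threshold on BH-adjusted p (strict `<`).
#' @return data.frame, one row per probe: contrast key columns, `probe_id`,
#'   `gene_id`, `log2fc`, `pvalue`, `padj`, `is_dep`, `direction`.
#' @export
test_contrast <- function(normalized, metadata, species_strain, chemical,
                          concentration_label, timepoint_h, probe_map,
                          deg_fdr = 0.10) {
  md <- metadata[metadata$sample_id %in% colnames(normalized), , drop = FALSE]
  trt <- md$sample_id[md$species_strain == species_strain &
                        md$chemical == chemical &
                        md$concentration_label == concentration_label &
                        md$timepoint_h == timepoint_h]
  if (length(trt) == 0L)
    stop("no treated samples for the requested contrast")
  solvent <- unique(md$solvent[md$sample_id %in% trt])
  ctl <- md$sample_id[md$species_strain == species_strain &
                        md$chemical == solvent &
                        md$concentration_label == "control" &
                        md$timepoint_h == timepoint_h]
  if (length(ctl) == 0L)
    stop("missing control: no matched '", solvent, "' solvent control for ",
         species_strain, " at ", timepoint_h, "h")
  if (length(trt) < 2L || length(ctl) < 2L)
    stop("fewer than 2 replicates remain in an arm after QC")
  a <- log2(normalized[, trt, drop = FALSE] + 1)
  b <- log2(normalized[, ctl, drop = FALSE] + 1)
  w <- welch_rows(a, b)
  padj <- p.adjust(w$p, method = "BH")
  is_dep <- padj < deg_fdr
  gene <- probe_map$gene_id[match(rownames(normalized), probe_map$probe_id)]
  data.frame(species_strain = species_strain, chemical = chemical,
             concentration_label = concentration_label,
             timepoint_h = timepoint_h,
             probe_id = rownames(normalized), gene_id = gene,
             log2fc = unname(w$diff), pvalue = unname(w$p),
             padj = unname(padj), is_dep = unname(is_dep),
             direction = ifelse(is_dep, ifelse(w$diff > 0, "up", "down"),
                                NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse probes to genes
#'
#' For genes measured by multiple probes, keeps exactly one probe per gene:
#' the probe with the highest total raw count summed over all supplied
#' samples. Ties are broken toward the lexicographically smaller probe id.
#' Probes mapping to no gene are dropped (their number is attached as
#' attribute `n_unmapped`).
#'
#' @param counts Raw probe x sample count matrix of the stratum (used only
#'   for the probe totals; pass the stratum's full sample set).
#' @param deg DegTable from [test_contrast()].
#' @return Gene-level data.frame inheriting the retained probe's statistics,
#'   one row per gene.
#' @export
collapse_probes_to_genes <- function(counts, deg) {
  total <- rowSums(counts)[deg$probe_id]
  unmapped <- is.na(deg$gene_id)
  if (any(unmapped))
    warning(sum(unmapped), " probes mapped to no gene; dropped")
  tab <- deg[!unmapped, , drop = FALSE]
  total <- total[!unmapped]
  # order: gene, then total desc, then probe_id asc; keep first per gene
  o <- order(tab$gene_id, -total, tab$probe_id)
  tab <- tab[o, , drop = FALSE]
  out <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Map gene identifiers to a reference (human) namespace
#'
#' Applies a static one-to-at-most-one ortholog mapping to a gene-level
#' table. Unmapped genes are dropped and counted (attribute `n_unmapped`).
#' When two source genes collapse onto the same target id, the record with
#' the smaller p-value is kept and the collision counted (attribute
#' `n_collisions`).
#'
#' @param gene_table Gene-level DegTable.
#' @param mapping data.frame `source_gene`, `human_gene`.
#' @return Mapped table keyed by `gene_id` in the target namespace.
#' @export
map_orthologs <- function(gene_table, mapping) {
  stopifnot(all(c("source_gene", "human_gene") %in% names(mapping)))
  if (anyDuplicated(mapping$source_gene))
    stop("mapping must be one-to-at-most-one in source_gene")
  target <- mapping$human_gene[match(gene_table$gene_id, mapping$source_gene)]
  keep <- !is.na(target)
  out <- gene_table[keep, , drop = FALSE]
  out$gene_id <- target[keep]
  o <- order(out$gene_id, out$pvalue)
  out <- out[o, , drop = FALSE]
  dup <- duplicated(out$gene_id)
  n_coll <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- sum(!keep)
  attr(out, "n_collisions") <- n_coll
  out
}
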