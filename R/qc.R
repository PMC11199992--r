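#' Flag low-quality samples by sequencing depth and probe breadth
#'
#' Applies the two exclusion rules used for targeted-sequencing hepatocyte
#' studies, independently within each species/strain stratum: a sample is
#' excluded when its total depth (sum of reads over all probes) falls more
#' than `k_sd` sample standard deviations below the stratum mean depth, or
#' when its number of detected probes (probes with >= 1 read) falls more
#' than `k_sd` SDs below the stratum mean probe count. Each criterion uses
#' its own statistic; thresholds are computed over ALL samples of the
#' stratum, pooled across chemicals and timepoints, in a single pass.
#' Comparisons are strict (`<`), so ties with the threshold are retained.
#'
#' @param counts Probe x sample count matrix (column names = sample ids).
#' @param metadata Sample metadata with `sample_id` and `species_strain`.
#' @param k_sd Number of standard deviations (default 2).
#' @return Object of class `qc_report`: list with `samples` (per-sample
#'   depth, detected probes, exclusion flag and reasons) and `groups`
#'   (per-group remaining replicate counts, `group_dropped` initialized
#'   FALSE; see [drop_depleted_groups()]).
#' @export
flag_low_quality_samples <- function(counts, metadata, k_sd = 2) {
  stopifnot(is.matrix(counts), all(counts >= 0),
            all(colnames(counts) %in% metadata$sample_id))
  md <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  depth <- colSums(counts)
  nprobe <- colSums(counts >= 1)
  excl <- logical(ncol(counts))
  r_depth <- logical(ncol(counts))
  r_probe <- logical(ncol(counts))
  for (ss in unique(md$species_strain)) {
    i <- which(md$species_strain == ss)
    if (length(i) < 3L)
      stop("insufficient samples: stratum '", ss, "' has fewer than 3")
    thr_d <- mean(depth[i]) - k_sd * sd(depth[i])
    thr_p <- mean(nprobe[i]) - k_sd * sd(nprobe[i])
    r_depth[i] <- depth[i] < thr_d
    r_probe[i] <- nprobe[i] < thr_p
    excl[i] <- r_depth[i] | r_probe[i]
  }
  reasons <- mapply(function(d, p) {
    paste(c(if (d) "low_depth", if (p) "low_probes"), collapse = ",")
  }, r_depth, r_probe)
  samples <- data.frame(sample_id = md$sample_id,
                        species_strain = md$species_strain,
                        group_id = md$group_id,
                        total_depth = unname(depth),
                        probes_detected = unname(nprobe),
                        excluded = excl,
                        exclusion_reasons = unname(unlist(reasons)),
                        stringsAsFactors = FALSE)
  agg_total <- tapply(samples$sample_id, samples$group_id, length)
  agg_kept <- tapply(!samples$excluded, samples$group_id, sum)
  groups <- data.frame(group_id = names(agg_total),
                       n_total = as.integer(agg_total),
                       n_remaining = as.integer(agg_kept[names(agg_total)]),
                       group_dropped = FALSE,
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(samples = samples, groups = groups, k_sd = k_sd),
            class = "qc_report")
}

#' Drop treatment groups depleted below a minimum replicate count
#'
#' After sample-level exclusion, any treatment group left with fewer than
#' `min_replicates` usable wells is dropped entirely: its `group_dropped`
#' flag is set and its remaining samples are excluded from downstream
#' contrasts (reason `group_dropped`).
#'
#' @param report A `qc_report` from [flag_low_quality_samples()].
#' @param min_replicates Minimum usable replicates to keep a group.
#' @return Updated `qc_report`.
#' @export
drop_depleted_groups <- function(report, min_replicates = 2L) {
  stopifnot(inherits(report, "qc_report"))
  drop <- report$groups$n_remaining < min_replicates
  report$groups$group_dropped <- drop
  bad_groups <- report$groups$group_id[drop]
  hit <- report$samples$group_id %in% bad_groups & !report$samples$excluded
  report$samples$excluded[hit] <- TRUE
  report$samples$exclusion_reasons[hit] <- ifelse(
    nzchar(report$samples$exclusion_reasons[hit]),
    paste0(report$samples$exclusion_reasons[hit], ",group_dropped"),
    "group_dropped")
  report
}

#' Samples usable after QC
#' @param report A `qc_report`.
#' @return Character vector of retained sample ids.
#' @export
qc_kept_samples <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  report$samples$sample_id[!report$samples$excluded]
}

#' Call cytotoxicity from LDH release and morphology
#'
#' A treatment group is called cytotoxic when percent LDH release is >= 25
#' AND hepatocyte morphology changes indicative of cytotoxicity were
#' observed; either signal alone is insufficient.
#'
#' @param ldh_table data.frame `group_id`, `ldh_percent`, `morphology_flag`.
#' @param ldh_threshold Percent-LDH threshold (default 25).
#' @return The input with a logical `cytotoxic` column appended.
#' @export
call_cytotoxicity <- function(ldh_table, ldh_threshold = 25) {
  stopifnot(all(c("group_id", "ldh_percent", "morphology_flag") %in%
                  names(ldh_table)))
  if (any(is.na(ldh_table$ldh_percent)))
    stop("invalid input: missing ldh_percent")
  if (any(ldh_table$ldh_percent < 0))
    stop("invalid input: negative ldh_percent")
  ldh_table$cytotoxic <- ldh_table$ldh_percent >= ldh_threshold &
    as.logical(ldh_table$morphology_flag)
  ldh_table
}
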