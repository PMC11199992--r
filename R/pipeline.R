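#' Run configuration for the end-to-end pipeline
#'
#' Bundles the study design, simulator configuration, thresholds and
#' policies of a full run. Thresholds default to the values used throughout
#' the analysis: DEP FDR < 10%, active-set FDR < 5%, LDH >= 25%,
#' QC at 2 SD, Williams trend alpha 0.05, pathway Fisher two-tail < 0.1,
#' model fit p >= 0.1.
#'
#' @param design A [study_design()].
#' @param truth A [truth_config()].
#' @param seed Integer seed governing all randomness in the run.
#' @param outdir Output directory.
#' @param deg_fdr,set_fdr,ldh,k_sd,min_replicates,trend_alpha,fisher_two_tail,fit_p
#'   Stage thresholds.
#' @param direction Enrichment direction used for concordance.
#' @param policy Concentration-selection policy for concordance
#'   (see [concentration_policy()]).
#' @param n_decoy_sets Decoy gene sets emitted by the simulator.
#' @param bmc_n_perm Permutations for the Williams prefilter in the BMC
#'   stage.
#' @param bmc_chemical,bmc_species Chemical series and stratum modeled in
#'   the BMC stage (default: first chemical, first species/strain).
#' @return List of class `run_config`.
#' @export
run_config <- function(design = study_design(), truth = truth_config(),
                       seed = 1L, outdir = tempfile("toxconcord_run_"),
                       deg_fdr = 0.10, set_fdr = 0.05, ldh = 25, k_sd = 2,
                       min_replicates = 2L, trend_alpha = 0.05,
                       fisher_two_tail = 0.1, fit_p = 0.1,
                       direction = "up", policy = "medium_high",
                       n_decoy_sets = 20L, bmc_n_perm = 500L,
                       bmc_chemical = NULL, bmc_species = NULL) {
  probs <- c(deg_fdr = deg_fdr, set_fdr = set_fdr,
             trend_alpha = trend_alpha, fisher_two_tail = fisher_two_tail,
             fit_p = fit_p)
  if (any(probs <= 0 | probs >= 1))
    stop("probability thresholds must lie in (0, 1): ",
         paste(names(probs)[probs <= 0 | probs >= 1], collapse = ", "))
  structure(list(design = design, truth = truth, seed = as.integer(seed),
                 outdir = outdir, deg_fdr = deg_fdr, set_fdr = set_fdr,
                 ldh = ldh, k_sd = k_sd,
                 min_replicates = as.integer(min_replicates),
                 trend_alpha = trend_alpha,
                 fisher_two_tail = fisher_two_tail, fit_p = fit_p,
                 direction = direction, policy = policy,
                 n_decoy_sets = as.integer(n_decoy_sets),
                 bmc_n_perm = as.integer(bmc_n_perm),
                 bmc_chemical = bmc_chemical, bmc_species = bmc_species),
            class = "run_config")
}

#' Run the full pipeline on a simulated study
#'
#' Executes simulate -> QC -> differential expression -> enrichment ->
#' concordance -> interacting-gene aggregation -> BMC, writing each stage's
#' tables under `config$outdir` together with a manifest recording every
#' output file, the thresholds applied, and methodological notes (the
#' differential-expression stand-in, tie-breaks, interval method). The run
#' is deterministic given `config$seed`.
#'
#' Contrasts are computed per species/strain at the concordance policy's
#' concentration label for every chemical and timepoint; enrichment is
#' direction-specific; concordance grids are produced per species/strain
#' and timepoint. The BMC stage models one chemical series in one stratum
#' (configurable) at the earliest timepoint.
#'
#' @param config A [run_config()].
#' @return List with the in-memory stage results (`study`, `qc`,
#'   `cytotox`, `deg`, `enrichment`, `concordance`, `aggregation`, `bmc`)
#'   plus `manifest` (data.frame) and `outdir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, file, what) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, description = what,
      stringsAsFactors = FALSE)
  }
  emit <- function(stage, name, obj) {
    path <- file.path(config$outdir, name)
    write_tsv_table(obj, path)
    note(stage, name, paste0(stage, " output"))
    path
  }
  stage <- "simulate"
  res <- tryCatch({
    ## 1. simulate
    study <- simulate_counts(config$design, config$truth, config$seed)
    gene_sets <- emit_gene_sets(study, config$n_decoy_sets,
                                seed = config$seed,
                                path = file.path(config$outdir,
                                                 "gene_sets.gmt"))
    note("simulate", "gene_sets.gmt", "planted + decoy gene sets (GMT)")
    ldh <- emit_ldh_table(study)
    emit("simulate", "metadata.tsv", study$metadata)
    emit("simulate", "probe_map.tsv", study$probe_map)

    ## 2. qc
    stage <- "qc"
    qc <- flag_low_quality_samples(study$counts, study$metadata,
                                   k_sd = config$k_sd)
    qc <- drop_depleted_groups(qc, config$min_replicates)
    cytotox <- call_cytotoxicity(ldh, config$ldh)
    emit("qc", "qc_samples.tsv", qc$samples)
    emit("qc", "qc_groups.tsv", qc$groups)
    emit("qc", "cytotoxicity.tsv", cytotox)
    kept <- qc_kept_samples(qc)

    ## 3. differential expression
    stage <- "dge"
    labs <- concentration_policy(names(config$design$chemicals),
                                 config$policy)
    deg_tables <- list()        # gene-level, keyed by group_id
    enrich_tables <- list()
    for (ss in config$design$species_strains) {
      md_ss <- study$metadata[study$metadata$species_strain == ss, ]
      counts_ss <- study$counts[, intersect(md_ss$sample_id, kept),
                                drop = FALSE]
      norm <- median_of_ratios_normalize(counts_ss)$normalized
      for (tp in config$design$timepoints_h) {
        for (cn in names(config$design$chemicals)) {
          lab <- labs[[cn]]
          dep <- tryCatch(
            test_contrast(norm, study$metadata, ss, cn, lab, tp,
                          study$probe_map, deg_fdr = config$deg_fdr),
            error = function(e) NULL)
          if (is.null(dep)) next
          gd <- collapse_probes_to_genes(counts_ss, dep)
          key <- sprintf("%s:%s:%s:%dh", ss, cn, lab, tp)
          deg_tables[[key]] <- gd
          enrich_tables[[key]] <- enrich(gd, gene_sets, config$direction,
                                         set_fdr = config$set_fdr)
        }
      }
    }
    emit("dge", "deg_gene_level.tsv", do.call(rbind, deg_tables))
    stage <- "enrich"
    emit("enrich", "enrichment.tsv", do.call(rbind, enrich_tables))

    ## 4. concordance per stratum x timepoint
    stage <- "concord"
    concord <- list()
    for (ss in config$design$species_strains) {
      for (tp in config$design$timepoints_h) {
        act <- list()
        for (cn in names(config$design$chemicals)) {
          key <- sprintf("%s:%s:%s:%dh", ss, cn, labs[[cn]], tp)
          if (is.null(enrich_tables[[key]])) next
          act[[cn]] <- binarize_activity(
            filter_sets_with_deg(enrich_tables[[key]]))
        }
        if (length(act) < 2L) next
        ckey <- sprintf("%s:%dh", ss, tp)
        concord[[ckey]] <- list(grid = concordance_grid(act),
                                long = concurrence_long(act))
      }
    }
    long_all <- do.call(rbind, lapply(names(concord), function(k)
      cbind(stratum_timepoint = k, concord[[k]]$long)))
    emit("concord", "concordance_long.tsv", long_all)

    ## 5. interacting-gene aggregation (per species/strain)
    stage <- "aggregate"
    catalog <- default_interaction_catalog(study)
    g2s <- select_targeted_sets(catalog, gene_sets)
    aggregation <- list()
    for (ss in config$design$species_strains) {
      keys <- grep(paste0("^", ss, ":"), names(enrich_tables), value = TRUE)
      if (!length(keys)) next
      aggregation[[ss]] <- aggregate_interacting_genes(
        enrich_tables[keys], g2s, alpha = config$set_fdr)
      export_toxpi(aggregation[[ss]]$internal,
                   file.path(config$outdir,
                             sprintf("toxpi_internal_%s.csv", ss)))
      note("aggregate", sprintf("toxpi_internal_%s.csv", ss),
           "internally scaled interacting-gene scores")
      export_toxpi(aggregation[[ss]]$external,
                   file.path(config$outdir,
                             sprintf("toxpi_external_%s.csv", ss)))
      note("aggregate", sprintf("toxpi_external_%s.csv", ss),
           "externally scaled interacting-gene scores")
    }

    ## 6. BMC on one chemical series
    stage <- "bmc"
    bmc_chem <- config$bmc_chemical %||% names(config$design$chemicals)[1]
    bmc_ss <- config$bmc_species %||% config$design$species_strains[1]
    tp <- config$design$timepoints_h[1]
    md <- study$metadata
    solvent <- config$design$chemicals[[bmc_chem]]$solvent
    sel <- md$sample_id[md$species_strain == bmc_ss &
                          md$timepoint_h == tp &
                          (md$chemical == bmc_chem |
                             (md$chemical == solvent &
                                md$concentration_label == "control"))]
    sel <- intersect(sel, kept)
    counts_sel <- study$counts[, sel, drop = FALSE]
    norm_sel <- median_of_ratios_normalize(counts_sel)$normalized
    # collapse to genes: keep the max-total probe per gene
    totals <- rowSums(counts_sel)
    pm <- study$probe_map
    o <- order(pm$gene_id, -totals[pm$probe_id], pm$probe_id)
    keep_probe <- pm$probe_id[o][!duplicated(pm$gene_id[o])]
    gexpr <- log2(norm_sel[keep_probe, , drop = FALSE] + 1)
    rownames(gexpr) <- pm$gene_id[match(keep_probe, pm$probe_id)]
    conc <- md$concentration[match(colnames(gexpr), md$sample_id)]
    bmc_fits <- bmc_genewise(gexpr, conc, trend_alpha = config$trend_alpha,
                             n_perm = config$bmc_n_perm, seed = config$seed)
    bmc_fits <- filter_bmc(bmc_fits, conc, fit_p_min = config$fit_p)
    emit("bmc", "bmc_gene_fits.tsv", bmc_fits)
    pathways <- pathway_classification(bmc_fits, gene_sets,
                                       universe = rownames(gexpr),
                                       p_cut = config$fisher_two_tail)
    emit("bmc", "bmc_pathways.tsv", pathways)
    if (nrow(pathways))
      emit("bmc", "bmc_accumulation.tsv", bmc_accumulation(pathways))

    list(study = study, gene_sets = gene_sets, qc = qc, cytotox = cytotox,
         deg = deg_tables, enrichment = enrich_tables, concordance = concord,
         aggregation = aggregation, bmc = list(fits = bmc_fits,
                                               pathways = pathways))
  }, error = function(e) {
    mf <- do.call(rbind, manifest)
    if (!is.null(mf))
      write_tsv_table(mf, file.path(config$outdir, "manifest.tsv"))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  settings <- data.frame(
    stage = "settings", file = "",
    description = c(
      sprintf("seed=%d", config$seed),
      sprintf("deg_fdr=%g set_fdr=%g ldh=%g k_sd=%g trend_alpha=%g fisher_two_tail=%g fit_p=%g",
              config$deg_fdr, config$set_fdr, config$ldh, config$k_sd,
              config$trend_alpha, config$fisher_two_tail, config$fit_p),
      sprintf("direction=%s policy=%s", config$direction, config$policy),
      "DE model: median-of-ratios normalization + Welch t on log2(norm+1), BH per contrast (stand-in for an NB GLM)",
      "probe collapse tie-break: lexicographically smaller probe id",
      "BMC intervals: Wald on log(BMC) via delta method"),
    stringsAsFactors = FALSE)
  mf <- rbind(do.call(rbind, manifest), settings)
  write_tsv_table(mf, file.path(config$outdir, "manifest.tsv"))
  res$manifest <- mf
  res$outdir <- config$outdir
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal-component coordinates of samples
#'
#' PCA of samples on `log2(x + 1)` of a normalized matrix; returns the top
#' two component coordinates with variance fractions. The sign convention
#' is fixed by making the loading with the largest absolute value positive
#' in each component.
#'
#' @param normalized Probe/gene x sample matrix.
#' @param metadata Sample metadata joined onto the coordinates by
#'   `sample_id`.
#' @return data.frame `sample_id`, `PC1`, `PC2`, metadata columns; the
#'   variance fractions are attached as attribute `var_frac`.
#' @export
report_pca <- function(normalized, metadata = NULL) {
  stopifnot(is.matrix(normalized), ncol(normalized) >= 3)
  x <- t(log2(normalized + 1))
  keep <- apply(x, 2, var) > 0
  if (!any(keep)) stop("constant matrix: PCA undefined")
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  for (j in 1:2) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  vf <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out <- data.frame(sample_id = rownames(x), PC1 = pc$x[, 1],
                    PC2 = pc$x[, 2], stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
  attr(out, "var_frac") <- vf
  out
}
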