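#' Ground-truth configuration for the study simulator
#'
#' Defines what is planted in a simulated study: per-chemical affected gene
#' modules (emitted downstream as gene sets), the effect ramp across
#' concentration ranks, dispersion of the negative-binomial count model,
#' and any deliberately degraded samples or cytotoxic treatment groups.
#'
#' The default module wiring mirrors the mechanistic layout the pipeline is
#' meant to resolve: the test chemical and the PPARα agonist share one
#' upregulated module (so their pathway-level concordance should be the
#' strongest pairwise signal), while the PPARγ agonist and the two cytotoxic
#' controls each perturb their own distinct module.
#'
#' @param n_genes Total genes in the simulated namespace (>= 200).
#' @param multi_probe_frac Fraction of genes measured by 2 probes (>= 0.10).
#' @param module_size Genes per planted module.
#' @param max_log2fc Planted log2 fold change at the high concentration.
#' @param ramp Multiplier on `max_log2fc` for concentration ranks
#'   low..high; must be non-decreasing.
#' @param dispersion Either `NULL` (gene-wise dispersions drawn uniformly
#'   from `dispersion_range`) or a single positive value used for all genes.
#' @param dispersion_range Range of gene-wise NB dispersions.
#' @param chemical_modules Named character vector chemical -> module name.
#' @param n_bad_samples Number of samples with degraded sequencing depth.
#' @param cytotoxic_groups Character vector of `group_id`s to mark cytotoxic
#'   in the LDH table, or `NULL`.
#' @return Object of class `truth_config`.
#' @export
truth_config <- function(n_genes = 300L,
                         multi_probe_frac = 0.2,
                         module_size = 30L,
                         max_log2fc = 4,
                         ramp = c(0.25, 0.5, 0.75, 1),
                         dispersion = NULL,
                         dispersion_range = c(0.05, 0.5),
                         chemical_modules = c(HFPO_DA = "ppara",
                                              GW7647 = "ppara",
                                              rosiglitazone = "pparg",
                                              acetaminophen = "stress_a",
                                              d_galactosamine = "stress_b"),
                         n_bad_samples = 0L,
                         cytotoxic_groups = NULL) {
  if (n_genes < 200L) stop("invalid configuration: n_genes must be >= 200")
  if (multi_probe_frac < 0.10)
    stop("invalid configuration: at least 10% of genes need 2 probes")
  if (length(ramp) != 4L || is.unsorted(ramp))
    stop("invalid configuration: ramp must be non-decreasing, length 4")
  if (!is.null(dispersion) && dispersion <= 0)
    stop("invalid configuration: dispersion must be positive")
  if (any(dispersion_range <= 0))
    stop("invalid configuration: dispersion_range must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 multi_probe_frac = multi_probe_frac,
                 module_size = as.integer(module_size),
                 max_log2fc = max_log2fc, ramp = ramp,
                 dispersion = dispersion,
                 dispersion_range = dispersion_range,
                 chemical_modules = chemical_modules,
                 n_bad_samples = as.integer(n_bad_samples),
                 cytotoxic_groups = cytotoxic_groups),
            class = "truth_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a seeded hepatocyte concentration-response study
#'
#' Draws a probe x sample count matrix from a negative-binomial model:
#' per-gene baseline means are log-normal, each probe of a gene carries its
#' own efficiency factor, each sample a library-size factor, and each gene a
#' dispersion. Genes in a chemical's planted module have their means
#' multiplied by `2^(max_log2fc * ramp[rank])` in that chemical's treated
#' samples, so planted effects grow monotonically with concentration.
#' Planted "bad" samples have their library factor collapsed far enough that
#' the 2-SD depth rule flags them. Identical `(design, truth, seed)` give
#' byte-identical output.
#'
#' @param design A [study_design()].
#' @param truth A [truth_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return Object of class `tox_study`: list with `counts` (integer matrix,
#'   probes x samples), `metadata` (see [design_metadata()]), `probe_map`
#'   (data.frame `probe_id`, `gene_id`), and `truth` (modules, per-chemical
#'   affected sets, expected per-concentration log2FCs, planted bad samples
#'   and cytotoxic groups).
#' @export
simulate_counts <- function(design, truth = truth_config(), seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "truth_config"))
  chems <- intersect(names(design$chemicals), names(truth$chemical_modules))
  with_seed(seed, {
    md <- design_metadata(design)
    n_s <- nrow(md)

    genes <- sprintf("g%04d", seq_len(truth$n_genes))
    n_multi <- ceiling(truth$multi_probe_frac * truth$n_genes)
    multi <- genes[seq_len(n_multi)]
    probe_map <- data.frame(
      probe_id = c(sprintf("%s_p1", genes), sprintf("%s_p2", multi)),
      gene_id = c(genes, multi), stringsAsFactors = FALSE)
    probe_map <- probe_map[order(probe_map$probe_id), , drop = FALSE]
    rownames(probe_map) <- NULL
    n_p <- nrow(probe_map)

    # planted modules: disjoint gene blocks taken after the multi-probe head
    mod_names <- unique(unname(truth$chemical_modules[chems]))
    pool <- genes
    modules <- list()
    offset <- 0L
    for (m in mod_names) {
      idx <- seq_len(truth$module_size) + offset
      if (max(idx) > length(pool))
        stop("invalid configuration: modules exceed gene namespace")
      modules[[m]] <- pool[idx]
      offset <- offset + truth$module_size
    }

    base_mean <- rlnorm(truth$n_genes, meanlog = 4.5, sdlog = 1)
    names(base_mean) <- genes
    probe_eff <- rlnorm(n_p, meanlog = 0, sdlog = 0.3)
    disp <- if (is.null(truth$dispersion))
      runif(truth$n_genes, truth$dispersion_range[1], truth$dispersion_range[2])
    else rep(truth$dispersion, truth$n_genes)
    names(disp) <- genes
    lib <- rlnorm(n_s, meanlog = 0, sdlog = 0.15)

    bad <- character(0)
    if (truth$n_bad_samples > 0L) {
      bad <- sample(md$sample_id, truth$n_bad_samples)
      lib[md$sample_id %in% bad] <- lib[md$sample_id %in% bad] * 0.02
    }

    # per-sample log2FC vector over genes
    labs <- concentration_labels()
    lfc_for_sample <- function(row) {
      v <- numeric(truth$n_genes)
      names(v) <- genes
      cn <- row[["chemical"]]
      if (cn %in% chems && row[["concentration_label"]] %in% labs) {
        rank <- match(row[["concentration_label"]], labs)
        mod <- modules[[truth$chemical_modules[[cn]]]]
        v[mod] <- truth$max_log2fc * truth$ramp[rank]
      }
      v
    }

    counts <- matrix(0L, nrow = n_p, ncol = n_s,
                     dimnames = list(probe_map$probe_id, md$sample_id))
    gene_of_probe <- probe_map$gene_id
    for (j in seq_len(n_s)) {
      lfc <- lfc_for_sample(md[j, ])
      mu <- base_mean[gene_of_probe] * probe_eff * lib[j] *
        2^(lfc[gene_of_probe])
      counts[, j] <- rnbinom(n_p, mu = mu, size = 1 / disp[gene_of_probe])
    }

    # expected log2FC bookkeeping per (chemical, concentration label, gene)
    exp_rows <- list()
    for (cn in chems) {
      mod <- modules[[truth$chemical_modules[[cn]]]]
      for (i in seq_along(labs)) {
        exp_rows[[length(exp_rows) + 1L]] <- data.frame(
          chemical = cn, concentration_label = labs[i], gene_id = mod,
          expected_log2fc = truth$max_log2fc * truth$ramp[i],
          stringsAsFactors = FALSE)
      }
    }
    affected <- data.frame(
      chemical = chems,
      set_name = sprintf("SET_%s", toupper(truth$chemical_modules[chems])),
      direction = "up",
      max_log2fc = truth$max_log2fc,
      stringsAsFactors = FALSE)
    rownames(affected) <- NULL

    structure(list(
      counts = counts, metadata = md, probe_map = probe_map,
      design = design,
      truth = list(modules = modules,
                   chemical_modules = truth$chemical_modules[chems],
                   affected_gene_sets = affected,
                   deg_genes = do.call(rbind, exp_rows),
                   bad_samples = bad,
                   cytotoxic_groups = truth$cytotoxic_groups,
                   config = truth)),
      class = "tox_study")
  })
}

#' @export
print.tox_study <- function(x, ...) {
  cat("Simulated hepatocyte study:", nrow(x$counts), "probes x",
      ncol(x$counts), "samples\n")
  cat("  modules:", paste(names(x$truth$modules), collapse = ", "), "\n")
  cat("  bad samples:", length(x$truth$bad_samples),
      " cytotoxic groups:", length(x$truth$cytotoxic_groups), "\n")
  invisible(x)
}

#' Emit the gene-set collection for a simulated study
#'
#' Produces the planted modules as named gene sets plus decoy sets whose
#' sizes are drawn from the affected sets' size distribution, standing in
#' for a canonical-pathway collection.
#'
#' @param study A `tox_study` from [simulate_counts()].
#' @param n_decoy_sets Number of decoy sets (>= 0).
#' @param seed Integer seed for decoy sampling.
#' @param path Optional file path; when given, the collection is written in
#'   GMT format.
#' @return Named list of character vectors (gene ids), invisibly when
#'   written to `path`.
#' @export
emit_gene_sets <- function(study, n_decoy_sets = 20L, seed = 1L, path = NULL) {
  stopifnot(inherits(study, "tox_study"), n_decoy_sets >= 0)
  mods <- study$truth$modules
  if (any(lengths(mods) < 2L))
    stop("invalid configuration: affected set with < 2 genes")
  sets <- setNames(mods, sprintf("SET_%s", toupper(names(mods))))
  genes <- unique(study$probe_map$gene_id)
  with_seed(seed, {
    if (n_decoy_sets > 0L) {
      sizes <- sample(lengths(mods), n_decoy_sets, replace = TRUE)
      for (i in seq_len(n_decoy_sets)) {
        sets[[sprintf("DECOY_%03d", i)]] <- sample(genes, sizes[i])
      }
    }
  })
  if (!is.null(path)) {
    write_gmt(sets, path)
    return(invisible(sets))
  }
  sets
}

#' Emit the LDH / morphology table for a simulated study
#'
#' One row per treatment group. Groups planted as cytotoxic in the ground
#' truth receive percent LDH release of 40 with the morphology flag set;
#' all other groups receive 8 with the flag clear (both sides of the 25%
#' call with margin).
#'
#' @param study A `tox_study`.
#' @param path Optional TSV output path.
#' @return data.frame `group_id`, `ldh_percent`, `morphology_flag`.
#' @export
emit_ldh_table <- function(study, path = NULL) {
  stopifnot(inherits(study, "tox_study"))
  groups <- unique(study$metadata$group_id)
  cyto <- groups %in% study$truth$cytotoxic_groups
  tab <- data.frame(group_id = groups,
                    ldh_percent = ifelse(cyto, 40, 8),
                    morphology_flag = cyto,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
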