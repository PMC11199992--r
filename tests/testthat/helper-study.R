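# Small single-stratum designs used across tests.

tiny_design <- function(replicates = 4L,
                        chemicals = default_chemicals(),
                        species = "CD1_mouse") {
  study_design(species_strains = species, chemicals = chemicals,
               timepoints_h = 24L, replicates = replicates)
}

one_chem_design <- function(replicates = 4L) {
  tiny_design(replicates = replicates,
              chemicals = default_chemicals()["HFPO_DA"])
}

# Exhaustive upper-tail hypergeometric probability by direct enumeration.
hyper_enum <- function(k, m, n, N) {
  i <- k:min(m, n)
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up computed by hand (independent of p.adjust).
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Binarized activity vectors for all chemicals of a simulated study at one
# concentration label (single stratum / timepoint designs).
study_activity <- function(study, gene_sets, label = "medium_high",
                           timepoint = 24L) {
  ss <- study$design$species_strains[1]
  norm <- median_of_ratios_normalize(study$counts)$normalized
  chems <- names(study$design$chemicals)
  act <- lapply(chems, function(cn) {
    d <- test_contrast(norm, study$metadata, ss, cn, label, timepoint,
                       study$probe_map)
    g <- collapse_probes_to_genes(study$counts, d)
    binarize_activity(filter_sets_with_deg(enrich(g, gene_sets, "up")))
  })
  names(act) <- chems
  act
}
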