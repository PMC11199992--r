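test_that("design validation rejects malformed configurations", {
  bad <- default_chemicals()
  bad$HFPO_DA$concentrations <- c(1, 2, 3)
  expect_error(study_design(chemicals = bad), "exactly 4")
  expect_error(truth_config(n_genes = 100), "n_genes")
  expect_error(truth_config(dispersion = -1), "dispersion")
  expect_error(truth_config(ramp = c(1, 0.5, 0.75, 1)), "ramp")
  expect_error(study_design(replicates = c("24" = 0L),
                            timepoints_h = 24L), "replicate")
})

test_that("metadata pairs every treated group with a matched solvent control", {
  md <- design_metadata(tiny_design())
  treated <- md[md$concentration_label != "control", ]
  for (i in seq_len(nrow(treated))) {
    ctl <- md[md$chemical == treated$solvent[i] &
                md$concentration_label == "control" &
                md$timepoint_h == treated$timepoint_h[i] &
                md$species_strain == treated$species_strain[i], ]
    expect_gt(nrow(ctl), 0)
  }
  # 4 concentrations per chemical, bijective labels
  for (cn in unique(treated$chemical)) {
    sub <- unique(treated[treated$chemical == cn,
                          c("concentration", "concentration_label")])
    expect_equal(nrow(sub), 4L)
    expect_setequal(sub$concentration_label, concentration_labels())
  }
})

test_that("identical (design, truth, seed) give identical artifacts", {
  des <- one_chem_design()
  tr <- truth_config(n_genes = 210, module_size = 10)
  s1 <- simulate_counts(des, tr, seed = 42)
  s2 <- simulate_counts(des, tr, seed = 42)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$metadata, s2$metadata)
  g1 <- emit_gene_sets(s1, n_decoy_sets = 5, seed = 9)
  g2 <- emit_gene_sets(s2, n_decoy_sets = 5, seed = 9)
  expect_identical(g1, g2)
  s3 <- simulate_counts(des, tr, seed = 43)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("null configuration plants no effect", {
  des <- one_chem_design()
  tr <- truth_config(n_genes = 210, module_size = 10, max_log2fc = 0)
  st <- simulate_counts(des, tr, seed = 5)
  expect_true(all(st$truth$deg_genes$expected_log2fc == 0))
})

test_that("planted log2FC is non-decreasing in concentration rank", {
  st <- simulate_counts(one_chem_design(), truth_config(n_genes = 200),
                        seed = 2)
  dg <- st$truth$deg_genes
  for (g in unique(dg$gene_id)) {
    sub <- dg[dg$gene_id == g, ]
    lfc <- sub$expected_log2fc[match(concentration_labels(),
                                     sub$concentration_label)]
    expect_false(is.unsorted(lfc))
  }
})

test_that("generator mean model converges to the planted fold change", {
  # 50 replicates, near-zero dispersion, log2FC 2 at high concentration:
  # the empirical high/control count ratio of a planted gene should sit
  # within 5% of 4.0
  des <- one_chem_design(replicates = 50L)
  tr <- truth_config(n_genes = 200, module_size = 10, max_log2fc = 2,
                     dispersion = 1e-6)
  st <- simulate_counts(des, tr, seed = 31)
  md <- st$metadata
  gene <- st$truth$modules$ppara[1]
  probe <- st$probe_map$probe_id[st$probe_map$gene_id == gene][1]
  hi <- md$sample_id[md$concentration_label == "high"]
  ctl <- md$sample_id[md$concentration_label == "control"]
  ratio <- mean(st$counts[probe, hi]) / mean(st$counts[probe, ctl])
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("gene-set emission books affected sets plus decoys", {
  st <- simulate_counts(tiny_design(), truth_config(n_genes = 220,
                                                    module_size = 12),
                        seed = 8)
  n_mod <- length(st$truth$modules)
  gs <- emit_gene_sets(st, n_decoy_sets = 7, seed = 1)
  expect_length(gs, n_mod + 7L)
  gs0 <- emit_gene_sets(st, n_decoy_sets = 0, seed = 1)
  expect_setequal(names(gs0), sprintf("SET_%s",
                                      toupper(names(st$truth$modules))))
  # GMT round trip
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  expect_identical(read_gmt(path), gs)
})

test_that("LDH table reflects planted cytotoxic groups and round-trips", {
  des <- tiny_design()
  md <- design_metadata(des)
  cyto <- unique(md$group_id[md$chemical == "acetaminophen" &
                               md$concentration_label == "high"])
  st <- simulate_counts(des, truth_config(n_genes = 200,
                                          cytotoxic_groups = cyto),
                        seed = 3)
  ldh <- emit_ldh_table(st)
  expect_equal(sum(ldh$ldh_percent >= 25 & ldh$morphology_flag),
               length(cyto))
  expect_true(all(ldh$ldh_percent[!ldh$group_id %in% cyto] < 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  emit_ldh_table(st, path)
  back <- read_tsv_table(path)
  expect_equal(back$ldh_percent, ldh$ldh_percent)
  expect_equal(back$morphology_flag, ldh$morphology_flag)
})
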