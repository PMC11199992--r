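test_that("median-of-ratios size factors satisfy the contract cases", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("p", 1:3), c("a", "b")))
  sf <- median_of_ratios_normalize(m)$size_factors
  expect_equal(unname(sf), c(1, 1))                 # identical samples

  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(m2) <- paste0("p", 1:3)
  sf2 <- median_of_ratios_normalize(m2)$size_factors
  expect_equal(unname(sf2[2] / sf2[1]), 2)          # exact 2x library
  expect_equal(exp(mean(log(sf2))), 1, tolerance = 1e-12)
  expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2)))

  m1 <- matrix(c(5, 8, 2), ncol = 1, dimnames = list(paste0("p", 1:3), "a"))
  expect_equal(unname(median_of_ratios_normalize(m1)$size_factors), 1)
})

test_that("size factors have geometric mean 1 on simulated data", {
  st <- simulate_counts(one_chem_design(), truth_config(n_genes = 200),
                        seed = 4)
  sf <- median_of_ratios_normalize(st$counts)$size_factors
  expect_true(all(sf > 0))
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)
})

test_that("all-zero-probe matrices fall back with an explicit error", {
  m <- rbind(c(1, 0), c(0, 2))
  colnames(m) <- c("a", "b")
  expect_error(median_of_ratios_normalize(m), "total-count")
  out <- normalize_total_count(m)
  expect_equal(exp(mean(log(out$size_factors))), 1, tolerance = 1e-12)
})

test_that("identical arms give zero fold changes and no DEPs", {
  des <- one_chem_design()
  st <- simulate_counts(des, truth_config(n_genes = 200, max_log2fc = 0),
                        seed = 6)
  md <- st$metadata
  # make treated medium_high literally identical to control
  trt <- md$sample_id[md$concentration_label == "medium_high"]
  ctl <- md$sample_id[md$concentration_label == "control"]
  st$counts[, trt] <- st$counts[, ctl]
  norm <- median_of_ratios_normalize(st$counts)$normalized
  dep <- test_contrast(norm, md, "CD1_mouse", "HFPO_DA", "medium_high",
                       24L, st$probe_map)
  expect_true(all(dep$log2fc == 0))
  expect_true(all(dep$pvalue == 1))
  expect_false(any(dep$is_dep))
})

test_that("BH adjustment within a contrast matches the hand step-up", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, method = "BH"), rep(0.03, 3))
  expect_equal(bh_hand(p), rep(0.03, 3))
})

test_that("swapping arm labels negates every log2FC exactly", {
  st <- simulate_counts(one_chem_design(), truth_config(n_genes = 200),
                        seed = 9)
  md <- st$metadata
  norm <- median_of_ratios_normalize(st$counts)$normalized
  fwd <- test_contrast(norm, md, "CD1_mouse", "HFPO_DA", "high", 24L,
                       st$probe_map)
  # swap roles by relabeling metadata
  md2 <- md
  trt <- md$concentration_label == "high" & md$chemical == "HFPO_DA"
  ctl <- md$concentration_label == "control" & md$chemical == "water"
  md2$chemical[trt] <- "water"
  md2$concentration_label[trt] <- "control"
  md2$chemical[ctl] <- "HFPO_DA"
  md2$concentration_label[ctl] <- "high"
  rev_ <- test_contrast(norm, md2, "CD1_mouse", "HFPO_DA", "high", 24L,
                        st$probe_map)
  expect_equal(rev_$log2fc, -fwd$log2fc)
  expect_equal(rev_$pvalue, fwd$pvalue)
})

test_that("missing matched control raises a missing-control error", {
  st <- simulate_counts(one_chem_design(), truth_config(n_genes = 200),
                        seed = 2)
  md <- st$metadata
  norm <- median_of_ratios_normalize(st$counts)$normalized
  keep <- md$concentration_label != "control"
  expect_error(
    test_contrast(norm[, md$sample_id[keep]], md[keep, ], "CD1_mouse",
                  "HFPO_DA", "high", 24L, st$probe_map),
    "missing control")
})

test_that("probe collapse keeps the arg-max probe with lexicographic ties", {
  counts <- rbind(P1 = c(40, 60), P2 = c(100, 150), P3 = c(10, 10),
                  A2 = c(125, 125), A1 = c(100, 150))
  colnames(counts) <- c("s1", "s2")
  deg <- data.frame(species_strain = "m", chemical = "x",
                    concentration_label = "high", timepoint_h = 24L,
                    probe_id = c("P1", "P2", "P3", "A2", "A1"),
                    gene_id = c("G", "G", "H", "K", "K"),
                    log2fc = 1:5, pvalue = 0.5, padj = 0.5,
                    is_dep = FALSE, direction = NA_character_,
                    stringsAsFactors = FALSE)
  out <- collapse_probes_to_genes(counts, deg)
  expect_equal(nrow(out), 3L)
  expect_equal(out$probe_id[out$gene_id == "G"], "P2")   # 250 > 100
  expect_equal(out$probe_id[out$gene_id == "H"], "P3")   # single probe
  expect_equal(out$probe_id[out$gene_id == "K"], "A1")   # 250 tie, lexical
  # retained probe total equals the per-gene max
  totals <- rowSums(counts)
  for (g in unique(out$gene_id)) {
    probes <- deg$probe_id[deg$gene_id == g]
    expect_equal(unname(totals[out$probe_id[out$gene_id == g]]),
                 max(totals[probes]))
  }
})

test_that("unmapped probes are dropped with a warning count", {
  counts <- rbind(P1 = c(5, 5), P2 = c(9, 9))
  colnames(counts) <- c("s1", "s2")
  deg <- data.frame(species_strain = "m", chemical = "x",
                    concentration_label = "high", timepoint_h = 24L,
                    probe_id = c("P1", "P2"),
                    gene_id = c("G", NA), log2fc = 0, pvalue = 1, padj = 1,
                    is_dep = FALSE, direction = NA_character_,
                    stringsAsFactors = FALSE)
  expect_warning(out <- collapse_probes_to_genes(counts, deg), "no gene")
  expect_equal(out$gene_id, "G")
  expect_equal(attr(out, "n_unmapped"), 1L)
})

test_that("ortholog mapping drops, passes through, and resolves collisions", {
  tab <- data.frame(gene_id = c("a", "b", "c"), pvalue = c(0.01, 0.2, 0.5),
                    stringsAsFactors = FALSE)
  empty <- map_orthologs(tab, data.frame(source_gene = character(),
                                         human_gene = character()))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_unmapped"), 3L)

  ident <- map_orthologs(tab, data.frame(source_gene = c("a", "b", "c"),
                                         human_gene = c("a", "b", "c")))
  expect_equal(ident$gene_id, tab$gene_id)
  expect_equal(ident$pvalue, tab$pvalue)

  coll <- map_orthologs(tab, data.frame(source_gene = c("a", "b", "c"),
                                        human_gene = c("H1", "H1", "H2")))
  expect_equal(coll$pvalue[coll$gene_id == "H1"], 0.01)
  expect_equal(attr(coll, "n_collisions"), 1L)
})

test_that("a planted gene is recovered as a DEP with accurate log2FC", {
  # log2FC 2 at high concentration, dispersion 0.05, 4 replicates/arm:
  # recovered among DEPs with estimate within +/-0.5 in >=95/100 seeded runs
  des <- one_chem_design(replicates = 4L)
  tr <- truth_config(n_genes = 200, module_size = 10, max_log2fc = 2,
                     dispersion = 0.05)
  hits <- 0L
  for (s in 1:100) {
    st <- simulate_counts(des, tr, seed = 1000 + s)
    norm <- median_of_ratios_normalize(st$counts)$normalized
    dep <- test_contrast(norm, st$metadata, "CD1_mouse", "HFPO_DA", "high",
                         24L, st$probe_map)
    # calibration target: a well-measured planted gene (the module gene
    # with the deepest control-arm coverage; near-zero baselines attenuate
    # log2(x+1) fold changes by construction)
    ctl <- st$metadata$sample_id[st$metadata$concentration_label ==
                                   "control"]
    mod_probes <- st$probe_map$probe_id[
      st$probe_map$gene_id %in% st$truth$modules$ppara]
    best <- names(which.max(rowMeans(st$counts[mod_probes, ctl])))
    row <- dep[dep$probe_id == best, ]
    if (isTRUE(row$is_dep) && abs(row$log2fc - 2) <= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
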