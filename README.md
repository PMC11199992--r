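# toxconcord

Transcriptomic concordance analysis for chemical mode-of-action assessment
in primary hepatocyte concentration–response studies.

## The problem

When a data-poor test chemical (here, an HFPO-DA-like short-chain PFAS) is
screened alongside mechanistic positive controls — a PPARα agonist, a PPARγ
agonist, and overtly cytotoxic reference hepatotoxicants — the question is
not just *which* genes move, but *how similar* the pathway-level response of
the test chemical is to each reference mechanism, across species, strains,
concentrations and exposure durations. `toxconcord` implements that analysis
as a tested, seeded, end-to-end pipeline for targeted (TempO-Seq-style)
probe-level count data:

1. **Sample QC** — exclude samples whose sequencing depth or detected-probe
   count falls more than 2 SD below the stratum mean; drop treatment groups
   depleted below 2 usable replicates; call cytotoxicity from
   percent LDH release ≥ 25% *combined with* morphology changes.
2. **Differential expression** — median-of-ratios normalization, per-contrast
   Welch t-tests on `log2(normalized + 1)` against matched solvent controls,
   BH adjustment, DEPs at FDR < 10%, probe→gene collapse by maximal total
   count, optional ortholog mapping.
3. **Gene-set enrichment** — exact one-sided hypergeometric
   overrepresentation of direction-specific DEG lists, BH across sets,
   "active" at FDR < 5%.
4. **Concordance** — the core statistic. Per chemical, enriched sets are
   filtered to those containing ≥ 1 DEG and binarized (active = 1,
   inactive = 0). For a chemical pair, activity is cross-tabulated into a
   2×2 concurrence matrix over the union of the two filtered lists, and
   concordance is the Jaccard index

   J(A, B) = n_active(A & B) / [ n_active(A & B) + n_active(A)·inactive(B) + inactive(A)·n_active(B) ]

   Sets inactive for *both* chemicals do not enter J: agreement on silence
   is not similarity.
5. **Interacting-gene aggregation** — gene sets containing a chemical's top
   curated interacting genes are pooled per species/strain; significant
   adjusted p-values are reverse-log-scaled onto (0, 1] (most significant
   set = 1), summed per gene per treatment group, and scaled internally
   (within group) and externally (per gene across groups) for ToxPi-style
   radial profiles.
6. **Benchmark concentrations** — a Williams trend permutation prefilter
   (isotonic amalgamated means, two-directional, p by seeded label
   permutation), a nine-model least-squares suite (linear, power, hill,
   poly 2–3, exponential 2–5) at a benchmark response of 1 residual SD,
   AIC winner selection, BMC range/CI/fit filters, and two-tailed
   Fisher's-exact pathway classification with median pathway BMCs.

A seeded negative-binomial study simulator with planted pathway modules
(`simulate_counts()`) emulates the full design — 4 species/strains ×
5 chemicals × 4 concentrations (+ solvent controls) × 3 timepoints ×
3–4 replicates — with known ground truth, so every stage is testable
without any external data.

## Worked example

```r
library(toxconcord)

design <- study_design(species_strains = "CD1_mouse",
                       timepoints_h = 24L, replicates = 4L)
study  <- simulate_counts(design, truth_config(), seed = 101)
study
#> Simulated hepatocyte study: 360 probes x 88 samples
#>   modules: ppara, pparg, stress_a, stress_b

gene_sets <- emit_gene_sets(study, n_decoy_sets = 20, seed = 101)
norm <- median_of_ratios_normalize(study$counts)$normalized
deps <- test_contrast(norm, study$metadata, "CD1_mouse", "HFPO_DA",
                      "medium_high", 24L, study$probe_map)
sum(deps$is_dep)
#> [1] 41

genes <- collapse_probes_to_genes(study$counts, deps)
en <- enrich(genes, gene_sets, "up")
head(en[order(en$pvalue), c("set_name", "k", "m", "pvalue", "padj", "active")], 3)
#>   set_name  k  m       pvalue         padj active
#>  SET_PPARA 18 30 2.404737e-21 5.771368e-20   TRUE
#>  DECOY_012  4 30 9.186856e-02 7.349485e-01  FALSE
#>  DECOY_017  4 30 9.186856e-02 7.349485e-01  FALSE
```

41 of 360 probes are DEPs for the test chemical at the second-highest
concentration; the planted PPARα-like module is the only active set
(18 of its 30 genes are upregulated DEGs, adjusted p ≈ 6e-20). Binarizing
activity for all five chemicals and forming all pairwise Jaccard indices:

```r
chems <- names(design$chemicals)
act <- lapply(chems, function(cn) {
  d <- test_contrast(norm, study$metadata, "CD1_mouse", cn,
                     "medium_high", 24L, study$probe_map)
  binarize_activity(filter_sets_with_deg(
    enrich(collapse_probes_to_genes(study$counts, d), gene_sets, "up")))
})
names(act) <- chems
round(concordance_grid(act), 2)
#>                 HFPO_DA GW7647 rosiglitazone acetaminophen d_galactosamine
#> HFPO_DA               1      1             0             0               0
#> GW7647                1      1             0             0               0
#> rosiglitazone         0      0             1             0               0
#> acetaminophen         0      0             0             1               0
#> d_galactosamine       0      0             0             0               1
```

The test chemical's pathway activity is fully concordant with the PPARα
agonist (J = 1, their planted module is shared) and disjoint from the PPARγ
agonist and both cytotoxic controls (J = 0) — the qualitative pattern the
simulator plants and the pipeline is designed to resolve.

`run_all(run_config(...))` executes every stage and writes each table plus
a manifest (thresholds, tie-breaks, method disclosures) to an output
directory.

## Notes on method stand-ins

The differential-expression stage is a documented stand-in (median-of-ratios
normalization + Welch t on `log2(norm + 1)` + BH), not a negative-binomial
GLM; BMC confidence bounds are Wald intervals on log(BMC) via the delta
method; Williams trend significance is by seeded permutation rather than
tabulated critical values. See `vignettes/concordance-methods.Rmd` for the
full model descriptions, parameter choices, and limitations.
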