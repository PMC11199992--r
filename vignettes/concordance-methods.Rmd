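---
title: "Methods: transcriptomic concordance, aggregation and benchmark concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic concordance, aggregation and benchmark concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxconcord)
```

`toxconcord` quantifies how similar the pathway-level transcriptomic
response of a test chemical is to mechanistic positive controls in primary
hepatocyte concentration–response studies. This vignette is the package's
account of the underlying models and of every numerically consequential
choice: what each stage assumes, which parameters matter, what the
simulator does and does not emulate, and where the implementation makes a
documented choice among defensible options.

## The study simulator

`simulate_counts()` draws a probe × sample count matrix from a
negative-binomial model. For gene $g$, probe $p$, sample $j$:

$$K_{pj} \sim \mathrm{NB}\!\left(\mu_{pj},\ \phi_g\right),\qquad
\mu_{pj} = \beta_g \, \epsilon_p \, \ell_j \, 2^{\lambda_{gj}}$$

* $\beta_g$ — per-gene baseline mean, log-normal (meanlog 4.5, sdlog 1),
  i.e. a median of roughly 90 counts with a realistic right tail;
* $\epsilon_p$ — per-probe efficiency, log-normal (sdlog 0.3), so the two
  probes of a multi-probe gene differ in depth as targeted assays do;
* $\ell_j$ — library-size factor, log-normal (sdlog 0.15);
* $\phi_g$ — gene-wise dispersion drawn uniformly from 0.05–0.5 (the bulk
  RNA-seq range; a single fixed value can be supplied instead, e.g. near 0
  for mean-model checks);
* $\lambda_{gj}$ — planted log2 fold change: nonzero only when sample $j$
  is treated with a chemical whose module contains $g$.

The planted effect follows a monotone ramp over the four concentration
ranks, $\lambda = \lambda_{\max} \times \{0.25, 0.5, 0.75, 1\}$, matching
the qualitative observation that differential expression grows with
concentration. The default module wiring is the mechanistic layout the
pipeline must resolve: the test chemical and the PPARα agonist share one
upregulated module; the PPARγ agonist and the two cytotoxic controls each
get a distinct module.

**Default effect size.** $\lambda_{\max} = 4$ (16-fold at the high
concentration, 8-fold at medium-high). Reference PPARα agonists induce
hepatocyte fatty-acid-oxidation genes by one to two orders of magnitude, so
this is at the conservative end of a "strong agonist" response. It also
keeps the planted medium-high effect comfortably detectable by the Welch-t
differential-expression stand-in at the study's 3–4 replicates under the
0.05–0.5 dispersion range; a planted effect near the stand-in's detection
boundary would make the simulator's ground truth unrecoverable by design,
which would defeat its purpose as a test harness.

**What the simulator does not emulate.** No read-level error or alignment
artifacts; no inter-species ortholog divergence (all simulated strata share
one gene namespace — `map_orthologs()` is exercised with explicit mapping
tables instead); no correlation between genes beyond module co-regulation;
no batch or plate effects. Passing tests therefore demonstrate that the
statistics are implemented correctly and recover effects under a clean NB
generative model — not that the pipeline is robust to every artifact of
real hepatocyte data.

Determinism: a single integer seed governs all randomness; the RNG state is
saved and restored around every stochastic operation, so identical
(design, truth, seed) triples give byte-identical artifacts.

## Sample QC and cytotoxicity

Within each species/strain (pooled across chemicals and timepoints), a
sample is excluded when its total depth, or its number of probes with ≥ 1
read, falls strictly below mean − 2 SD of the stratum. Choices: the SD uses
the $n-1$ denominator; comparisons are strict so ties with the threshold
are retained; the rule is applied in a single pass (thresholds are not
recomputed after exclusion). Groups left with fewer than 2 usable
replicates are dropped entirely. Cytotoxicity calls require *both* percent
LDH release ≥ 25 and observed morphology changes; either alone is
insufficient.

## Differential expression stand-in

The reference analysis for such data is a negative-binomial GLM; this
package deliberately substitutes a transparent stand-in whose behavior is
fully calibrated by its own tests: median-of-ratios size factors (reference
profile = per-probe geometric mean over samples with all-positive counts),
then per-contrast Welch t-tests on $\log_2(\text{normalized} + 1)$, BH
adjustment within the contrast, DEPs at adjusted p < 0.10 (strict). Probes
collapse to genes by maximal total raw count over the stratum's samples,
ties to the lexicographically smaller probe id.

Numerical choices:

* the +1 pseudocount avoids $-\infty$ but attenuates fold changes of
  near-zero-baseline genes — an inherent property of the transform, visible
  in the Monte-Carlo calibration tests;
* size factors are rescaled to geometric mean exactly 1 (tolerance 1e-6),
  anchoring normalized library sizes to the study scale; plain
  median-of-ratios leaves the geometric mean only approximately 1;
* zero-variance degenerate probes get p = 1 when the arm means agree and
  p = 0 otherwise;
* matrices with no all-positive probe raise an explicit error directing to
  `normalize_total_count()` rather than silently switching methods.

## Enrichment, concurrence and the Jaccard index

Enrichment is the exact upper-tail hypergeometric probability for drawing
$k$ or more set members in $n$ DEGs from a universe of $N$ measured genes
containing $m$ set members. The universe is the measured genes after probe
collapse, not the genome — decoy sets and $m$, $N$ are sized against what
the assay can see. Up- and down-regulated DEG lists are tested separately;
BH runs across sets within (contrast, direction); "active" means adjusted
p strictly < 0.05.

For concordance, each chemical's enrichment table is first filtered to sets
containing ≥ 1 of its DEGs, then binarized. The pair universe is the
**union** of the two filtered lists (a set missing from one list counts as
inactive for that chemical); the alternative intersection universe would
change only the doubly-inactive count $n_{ii}$, which the Jaccard index
ignores by construction. Quadrant percentages are reported out of the total
active count $n_{aa} + n_{ai} + n_{ia}$. When no set is active for either
chemical, J is reported as missing, not 0 — silence is not evidence of
similarity. The default comparison uses upregulated sets at the
medium-high concentration; a "mixed" preset substitutes the medium
concentration for the overtly cytotoxic controls so their concordance is
not driven by cytotoxicity.

## Interacting-gene (ToxPi-style) aggregation

Gene sets containing any of a chemical's top-10 curated interacting genes
are selected; across **all** treatment groups and timepoints of a
species/strain, the adjusted p-values of significant (p < 0.05) targeted
sets form one pool. The reverse-log transform is fixed as

$$s_i = \frac{\log_{10} p_i}{\log_{10} p_{\min}}$$

with $p_{\min}$ the pool minimum and p floored at 1e-300: linear in
log-p, it satisfies the stated constraints (values in (0, 1], most
significant set = 1, non-significant sets = 0) with no free parameter; ties
at $p_{\min}$ all map to 1. Per treatment group, the scaled values of all
sets containing a gene are summed; internal scaling divides each group's
sums by the group maximum, external scaling divides each gene's sums by its
maximum across groups. Both scalings are invariant to positive rescaling of
the sums, so the choice of pool affects ranking across groups only through
$p_{\min}$.

## Benchmark concentration analysis

The Williams-type trend prefilter amalgamates dose-group means by weighted
pool-adjacent-violators isotonic regression (control excluded) in each
direction and contrasts the top amalgamated mean against the control mean
with the pooled within-group SD. Significance is by label permutation —
drawn per gene from the seeded RNG, add-one estimator
$(1 + \#\{T^\ast \ge T\})/(1 + B)$ — rather than tabulated critical values:
exact under exchangeability at any group count, at the cost of Monte-Carlo
granularity $1/(B+1)$. All-constant genes get p = 1 by convention, and the
prefilter p-values are intentionally left unadjusted for multiplicity.

Nine constant-variance models (linear, power, hill, poly2/3, exponential
2–5) are fit by least squares (bounded Levenberg–Marquardt for the
nonlinear members; power and hill exponents constrained to [0.1, 8]). The
BMC is the smallest positive concentration at which the fitted mean departs
from the fitted control mean by 1 residual SD, found by a log-spaced
bracket scan plus root refinement over (lowest conc/10⁴, 10 × highest];
no crossing means no finite BMC. The lack-of-fit p-value is the F-test
against the saturated group-means model (p = 1 when the model saturates the
groups); the winner is the converged fit with the lowest AIC — simpler than
the reference tool's nested-model ladder, and recorded as such.

**Interval choice.** BMCL/BMCU are 95% Wald bounds on log(BMC) by the
delta method (numeric gradient of the BMC in the fitted coefficients times
their covariance). Profile-likelihood bounds were considered and rejected:
profiling an implicitly defined BMC across nine model families under
bounded LM fitting is fragile (frequent non-convergence on the constraint),
while the Wald-log interval brackets the estimate by construction, is
scale-equivariant, and widens with noise — the properties the downstream
BMC/BMCL, BMCU/BMC, BMCU/BMCL ≤ 20/20/40 filters consume. Genes whose
bounds are unavailable are conservatively treated as wide-CI when that
filter is on.

Filters, in precedence order: `poor_fit` (winning fit p < 0.1 or no finite
BMC), `below_range` (BMC more than 10-fold below the lowest tested
concentration), `above_range` (BMC above the highest), `wide_ci` (the
ratio rules). Pathway classification is a two-tailed Fisher's exact test of
passing genes × set membership over the measured universe, reporting sets
at p < 0.1 with the median BMC of their passing genes.

## Problem sizes used in the tests

The test suite runs desk-scale analogues chosen to exercise every code
path while keeping the suite fast: single-stratum studies of 200–300 genes
(3–4 modules of 20–30 genes, 10–20% multi-probe genes, 20 decoy sets),
3–4 replicates, and permutation counts of 150–2000. The type-I calibration
of the Williams filter pools 3 × 1000 independent null genes at 2000
permutations; the concordance-recovery study uses 50 seeded studies at the
generator defaults. These sizes are the package's own choice of
demonstration scale; all statistics are independent of matrix size.

## Known limitations

* The DE stand-in is less powerful than a dispersion-shrinking NB GLM at
  2–4 replicates and attenuates fold changes of low-count genes; absolute
  DEP counts are not comparable to a reference NB analysis, though
  downstream set-level calls are calibrated against the stand-in itself.
* The exact enrichment engine of the reference analysis (gene-level
  weighting, statistic variants) is not recoverable from its description;
  this package's hypergeometric test is the documented, tested definition.
* BMC winner selection by AIC and Wald-log intervals are simplifications
  of the reference benchmark-dose tool; results are not bit-comparable
  with it.
* The simulator shares one gene namespace across species/strains, so
  cross-species concordance here never exercises real ortholog mapping
  ambiguity.
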