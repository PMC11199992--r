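#' Williams trend prefilter by permutation
#'
#' Screens genes for a monotone concentration-response before benchmark
#' concentration modeling. For each gene, dose-group means (control
#' excluded) are amalgamated by weighted pool-adjacent-violators isotonic
#' regression in each direction; the statistic is the larger of the two
#' t-like contrasts of the top amalgamated mean against the control mean,
#' using the pooled within-group SD. Significance comes from permuting
#' sample values across groups (`n_perm` label permutations, seeded, drawn
#' independently per gene), with the add-one estimator
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)`. All-constant genes get p = 1
#' by convention. No multiplicity correction is applied to the prefilter
#' p-values.
#'
#' @param expr Genes x samples numeric matrix (e.g. normalized expression).
#' @param conc Numeric concentration per sample; 0 marks controls.
#' @param alpha Retention threshold (strict `<`; default 0.05).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return data.frame `gene_id`, `stat`, `pvalue`, `pass`.
#' @export
williams_trend_filter <- function(expr, conc, alpha = 0.05,
                                  n_perm = 10000L, seed = 1L) {
  stopifnot(is.matrix(expr), length(conc) == ncol(expr), all(conc >= 0))
  doses <- sort(unique(conc[conc > 0]))
  if (length(doses) < 3L)
    stop("need >= 3 concentration groups plus control")
  grp <- match(conc, c(0, doses)) - 1L
  cnt <- table(grp)
  if (any(cnt < 2L)) stop("need >= 2 replicates per group")
  res <- with_seed(seed,
                   williams_perm_core(expr, as.integer(grp),
                                      as.integer(n_perm)))
  data.frame(gene_id = rownames(expr), stat = res$stat,
             pvalue = res$pvalue, pass = res$pvalue < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Williams trend test for a single response vector
#'
#' @param y Numeric response per sample.
#' @param conc Concentration per sample (0 = control).
#' @inheritParams williams_trend_filter
#' @return List `stat`, `pvalue`.
#' @export
williams_trend_test <- function(y, conc, n_perm = 10000L, seed = 1L) {
  m <- matrix(y, nrow = 1, dimnames = list("y", NULL))
  r <- williams_trend_filter(m, conc, alpha = 0.05, n_perm = n_perm,
                             seed = seed)
  list(stat = r$stat[1], pvalue = r$pvalue[1])
}
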