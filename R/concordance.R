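#' Filter enriched sets to those containing at least one DEG
#'
#' Before concurrence/concordance, each chemical's direction-specific
#' enrichment table is restricted to gene sets that contain at least 1
#' significant DEG of that chemical (i.e. overlap `k >= 1`). Active sets
#' without any DEG overlap cannot arise from the hypergeometric test, but
#' the filter also removes inactive sets with no DEG content so that the
#' "inactive" side of the concurrence matrix is restricted to sets the
#' chemical actually touched.
#'
#' @param enrichment EnrichmentTable from [enrich()] (one contrast, one
#'   direction).
#' @return Filtered EnrichmentTable.
#' @export
filter_sets_with_deg <- function(enrichment) {
  out <- enrichment[enrichment$k >= 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize gene-set activity
#'
#' Gene sets significantly enriched (adjusted p strictly below the FDR
#' threshold applied in [enrich()]) get value 1 ("active"); all others 0
#' ("inactive"). An adjusted p exactly at the threshold is inactive.
#'
#' @param enrichment (Filtered) EnrichmentTable.
#' @return Named integer vector (set name -> 0/1).
#' @export
binarize_activity <- function(enrichment) {
  setNames(as.integer(enrichment$active), enrichment$set_name)
}

#' Activity concurrence matrix for a chemical pair
#'
#' Cross-tabulates binarized gene-set activity of two chemicals over the
#' union of their filtered set lists; a set absent from one chemical's list
#' counts as inactive for that chemical. Quadrant percentages are taken out
#' of the total number of active sets in the comparison
#' (`n_aa + n_ai + n_ia`); doubly-inactive sets are excluded from the
#' percentage calculation.
#'
#' @param vec_a,vec_b Named 0/1 vectors from [binarize_activity()].
#' @return Object of class `concurrence_matrix`: `n_aa`, `n_ai` (active A
#'   only), `n_ia` (active B only), `n_ii`, `pct_aa`, `pct_ai`, `pct_ia`,
#'   `universe_size`.
#' @export
concurrence <- function(vec_a, vec_b) {
  universe <- union(names(vec_a), names(vec_b))
  a <- setNames(rep(0L, length(universe)), universe)
  b <- a
  a[names(vec_a)] <- vec_a
  b[names(vec_b)] <- vec_b
  n_aa <- sum(a == 1 & b == 1)
  n_ai <- sum(a == 1 & b == 0)
  n_ia <- sum(a == 0 & b == 1)
  n_ii <- sum(a == 0 & b == 0)
  tot <- n_aa + n_ai + n_ia
  pct <- function(x) if (tot > 0) 100 * x / tot else NA_real_
  structure(list(n_aa = n_aa, n_ai = n_ai, n_ia = n_ia, n_ii = n_ii,
                 pct_aa = pct(n_aa), pct_ai = pct(n_ai), pct_ia = pct(n_ia),
                 universe_size = length(universe)),
            class = "concurrence_matrix")
}

#' @export
print.concurrence_matrix <- function(x, ...) {
  cat("Activity concurrence (universe", x$universe_size, "sets)\n")
  m <- matrix(c(x$n_aa, x$n_ia, x$n_ai, x$n_ii), 2, 2,
              dimnames = list(c("A active", "A inactive"),
                              c("B active", "B inactive")))
  print(m)
  invisible(x)
}

#' Jaccard concordance index from a concurrence matrix
#'
#' `J = n_aa / (n_aa + n_ai + n_ia)`: the proportion of the union of the
#' two chemicals' active gene sets that is active for both. Sets inactive
#' for both chemicals do not enter the index. When no set is active for
#' either chemical the index is undefined and reported as missing rather
#' than 0.
#'
#' @param cm A `concurrence_matrix`.
#' @return List `jaccard` (number in `[0,1]`, `NA` when undefined) and
#'   `defined` (logical).
#' @export
jaccard_index <- function(cm) {
  stopifnot(inherits(cm, "concurrence_matrix"))
  denom <- cm$n_aa + cm$n_ai + cm$n_ia
  if (denom == 0) return(list(jaccard = NA_real_, defined = FALSE))
  list(jaccard = cm$n_aa / denom, defined = TRUE)
}

#' Pairwise Jaccard concordance grid
#'
#' All pairwise Jaccard indices (including positive-control vs
#' positive-control comparisons and the diagonal) over a set of chemicals'
#' binarized activity vectors.
#'
#' @param activity Named list of binarized activity vectors, one per
#'   chemical.
#' @return Square numeric matrix of Jaccard indices (`NA` where undefined).
#' @export
concordance_grid <- function(activity) {
  stopifnot(is.list(activity), !is.null(names(activity)))
  nm <- names(activity)
  J <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_len(i)) {
    cm <- concurrence(activity[[i]], activity[[j]])
    J[i, j] <- J[j, i] <- jaccard_index(cm)$jaccard
  }
  J
}

#' Concurrence results in long format
#'
#' @param activity Named list of binarized activity vectors.
#' @return data.frame, one row per unordered chemical pair, with quadrant
#'   counts, percentages, and the Jaccard index.
#' @export
concurrence_long <- function(activity) {
  nm <- names(activity)
  rows <- list()
  for (i in seq_along(nm)) for (j in seq_along(nm)) {
    if (j <= i) next
    cm <- concurrence(activity[[i]], activity[[j]])
    jc <- jaccard_index(cm)
    rows[[length(rows) + 1L]] <- data.frame(
      chemical_a = nm[i], chemical_b = nm[j],
      n_aa = cm$n_aa, n_ai = cm$n_ai, n_ia = cm$n_ia, n_ii = cm$n_ii,
      pct_aa = cm$pct_aa, pct_ai = cm$pct_ai, pct_ia = cm$pct_ia,
      universe_size = cm$universe_size,
      jaccard = jc$jaccard, defined = jc$defined,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Concentration-selection policy for concordance
#'
#' The main concordance comparisons use the second-highest
#' (`"medium_high"`) concentration of every chemical -- high enough for a
#' strong transcriptomic response while avoiding the concentrations where
#' cytotoxicity is most frequent. The `"mixed"` preset instead uses the
#' `"medium"` concentration for chemicals named in `cytotoxic_chemicals`
#' (the overtly cytotoxic reference hepatotoxicants) and `"medium_high"`
#' for the rest.
#'
#' @param chemicals Character vector of chemical names.
#' @param policy `"medium_high"` or `"mixed"`.
#' @param cytotoxic_chemicals Chemicals assigned `"medium"` under `"mixed"`.
#' @return Named character vector chemical -> concentration label.
#' @export
concentration_policy <- function(chemicals,
                                 policy = c("medium_high", "mixed"),
                                 cytotoxic_chemicals = c("acetaminophen",
                                                         "d_galactosamine")) {
  policy <- match.arg(policy)
  lab <- setNames(rep("medium_high", length(chemicals)), chemicals)
  if (policy == "mixed")
    lab[chemicals %in% cytotoxic_chemicals] <- "medium"
  lab
}
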