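#' Write a gene-set collection in GMT format
#'
#' One record per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional character vector of descriptions (recycled
#'   empty string by default).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT format
#'
#' Tolerant of empty description fields and duplicate genes within a set
#' (duplicates are dropped).
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed GMT line: ", substr(ln, 1, 50))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Read / write tab-separated tables
#'
#' Thin wrappers fixing the conventions used by every table this package
#' emits (no quoting, no row names, header line).
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Default interacting-gene catalog for a simulated study
#'
#' Emulates a per-chemical "top interacting genes" list (as curated
#' chemical-gene interaction databases provide): for each chemical, the
#' first up-to-10 genes of its planted module, ranked.
#'
#' @param study A `tox_study`.
#' @param top_n Genes per chemical (<= 10).
#' @return data.frame `chemical`, `rank`, `gene_id`.
#' @export
default_interaction_catalog <- function(study, top_n = 10L) {
  stopifnot(inherits(study, "tox_study"), top_n <= 10L)
  rows <- lapply(names(study$truth$chemical_modules), function(cn) {
    mod <- study$truth$modules[[study$truth$chemical_modules[[cn]]]]
    g <- head(mod, top_n)
    data.frame(chemical = cn, rank = seq_along(g), gene_id = g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
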