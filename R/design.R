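#' Default chemical panel
#'
#' The five-chemical hepatocyte panel: the test chemical (an HFPO-DA-like
#' PFAS) plus four mechanistic positive controls -- a PPARα agonist
#' (GW7647-like), a PPARγ agonist (rosiglitazone-like), and two overtly
#' cytotoxic reference hepatotoxicants (acetaminophen- and
#' d-galactosamine-like). Each chemical carries a 4-point concentration grid
#' (µM) and the solvent used for its matched vehicle control.
#'
#' @return Named list; one entry per chemical with elements `concentrations`
#'   (ascending, length 4, µM) and `solvent` (`"water"` or `"DMSO"`).
#' @export
default_chemicals <- function() {
  list(
    HFPO_DA         = list(concentrations = c(0.1, 5, 50, 500),      solvent = "water"),
    GW7647          = list(concentrations = c(0.01, 0.1, 1, 10),     solvent = "DMSO"),
    rosiglitazone   = list(concentrations = c(0.01, 0.1, 1, 10),     solvent = "DMSO"),
    acetaminophen   = list(concentrations = c(300, 1000, 3000, 10000), solvent = "DMSO"),
    d_galactosamine = list(concentrations = c(300, 1000, 3000, 10000), solvent = "DMSO")
  )
}

#' Concentration rank labels
#' @return Character vector `c("low","medium","medium_high","high")`.
#' @export
concentration_labels <- function() c("low", "medium", "medium_high", "high")

#' Construct a hepatocyte study design
#'
#' Describes the experimental layout: which species/strains are cultured,
#' which chemicals at which 4-point concentration grids, which exposure
#' durations, and how many replicate wells per treatment group. Every
#' treated group has a matched solvent-control group in the same
#' species/strain and timepoint.
#'
#' @param species_strains Character vector of species/strain labels.
#' @param chemicals Named list as returned by [default_chemicals()].
#' @param timepoints_h Integer vector of exposure durations in hours.
#' @param replicates Either a single integer or a named vector keyed by
#'   timepoint (as character) giving replicate wells per group.
#' @return Object of class `study_design`.
#' @export
study_design <- function(species_strains = c("CD1_mouse", "B6129SF2J_mouse",
                                             "SD_rat", "human_pool"),
                         chemicals = default_chemicals(),
                         timepoints_h = c(12L, 24L, 72L),
                         replicates = c("12" = 3L, "24" = 4L, "72" = 3L)) {
  stopifnot(length(species_strains) >= 1, length(chemicals) >= 1,
            length(timepoints_h) >= 1)
  for (nm in names(chemicals)) {
    ch <- chemicals[[nm]]
    if (length(ch$concentrations) != 4L)
      stop("chemical '", nm, "' must have exactly 4 concentrations")
    if (is.unsorted(ch$concentrations, strictly = TRUE))
      stop("chemical '", nm, "' concentrations must be strictly increasing")
    if (!ch$solvent %in% c("water", "DMSO"))
      stop("chemical '", nm, "' solvent must be 'water' or 'DMSO'")
  }
  rep_for <- function(tp) {
    r <- if (length(replicates) == 1L && is.null(names(replicates)))
      replicates else replicates[[as.character(tp)]]
    if (is.null(r) || is.na(r) || r < 1)
      stop("invalid replicate count for timepoint ", tp)
    as.integer(r)
  }
  reps <- vapply(timepoints_h, rep_for, integer(1))
  names(reps) <- as.character(timepoints_h)
  structure(list(species_strains = species_strains, chemicals = chemicals,
                 timepoints_h = as.integer(timepoints_h), replicates = reps),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Hepatocyte study design\n")
  cat("  species/strains:", paste(x$species_strains, collapse = ", "), "\n")
  cat("  chemicals:      ", paste(names(x$chemicals), collapse = ", "), "\n")
  cat("  timepoints (h): ", paste(x$timepoints_h, collapse = ", "), "\n")
  cat("  replicates:     ", paste(sprintf("%sh=%d", names(x$replicates),
                                          x$replicates), collapse = ", "), "\n")
  invisible(x)
}

#' Sample metadata table for a design
#'
#' Expands a [study_design()] into one row per well: treated groups for every
#' chemical x concentration, plus one solvent-control group per distinct
#' solvent, per species/strain and timepoint.
#'
#' @param design A `study_design`.
#' @return data.frame with columns `sample_id`, `species_strain`, `chemical`,
#'   `concentration`, `concentration_label`, `timepoint_h`, `replicate`,
#'   `solvent`, `group_id`. Control rows carry `chemical = <solvent>`,
#'   `concentration = 0`, `concentration_label = "control"`.
#' @export
design_metadata <- function(design) {
  stopifnot(inherits(design, "study_design"))
  labs <- concentration_labels()
  rows <- list()
  for (ss in design$species_strains) {
    for (tp in design$timepoints_h) {
      nrep <- design$replicates[[as.character(tp)]]
      solvents <- unique(vapply(design$chemicals, `[[`, "", "solvent"))
      for (sv in solvents) {
        rows[[length(rows) + 1L]] <- data.frame(
          species_strain = ss, chemical = sv, concentration = 0,
          concentration_label = "control", timepoint_h = tp,
          replicate = seq_len(nrep), solvent = sv,
          stringsAsFactors = FALSE)
      }
      for (cn in names(design$chemicals)) {
        ch <- design$chemicals[[cn]]
        for (i in seq_along(ch$concentrations)) {
          rows[[length(rows) + 1L]] <- data.frame(
            species_strain = ss, chemical = cn,
            concentration = ch$concentrations[i],
            concentration_label = labs[i], timepoint_h = tp,
            replicate = seq_len(nrep), solvent = ch$solvent,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  md <- do.call(rbind, rows)
  md$group_id <- group_id(md)
  md$sample_id <- sprintf("%s_r%d", md$group_id, md$replicate)
  rownames(md) <- NULL
  md[, c("sample_id", "species_strain", "chemical", "concentration",
         "concentration_label", "timepoint_h", "replicate", "solvent",
         "group_id")]
}

#' Treatment-group identifier
#'
#' @param md data.frame with `species_strain`, `chemical`,
#'   `concentration_label`, `timepoint_h`.
#' @return Character vector, `"<strain>:<chemical>:<label>:<tp>h"`.
#' @export
group_id <- function(md) {
  sprintf("%s:%s:%s:%dh", md$species_strain, md$chemical,
          md$concentration_label, md$timepoint_h)
}
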