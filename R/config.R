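#' Pipeline configuration
#'
#' Thresholds and curation inputs governing how raw profile-HMM hits are
#' turned into domain architectures.
#'
#' @details
#' The defaults reproduce the standard curation protocol for trypsin-domain
#' proteomes: a protein enters the tryptome when it carries a hit to a
#' trypsin-family profile with full-sequence E-value at most
#' `protein_evalue_max` (1e-5); every reported domain (trypsin or associated)
#' must have an independent (domain-specific) E-value at most
#' `domain_ievalue_max` (0.05); and pairs of placed domains overlapping by
#' more than `overlap_frac_max` (20%, measured against the shorter domain)
#' are resolved in favour of the lower E-value. Manual curation of gene
#' models (pseudogenes, duplicated predictions) is represented only as an
#' `exclusion_list` of protein identifiers; it is never re-derived.
#'
#' @param protein_evalue_max Maximum full-sequence E-value for the trypsin
#'   hit that selects a protein into the tryptome.
#' @param domain_ievalue_max Maximum independent (domain-specific) E-value
#'   for any domain retained in an architecture.
#' @param overlap_frac_max Maximum tolerated pairwise overlap fraction
#'   between two retained domains; the fraction is shared residues divided
#'   by the length of the shorter domain. Must lie in (0, 1).
#' @param trypsin_families Character vector of Pfam family names treated as
#'   "trypsin" for selection and classification.
#' @param exclusion_list Protein identifiers removed by external curation.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$overlap_frac_max
#' @export
pipeline_config <- function(protein_evalue_max = 1e-5,
                            domain_ievalue_max = 0.05,
                            overlap_frac_max = 0.20,
                            trypsin_families = c("Trypsin", "Trypsin_2"),
                            exclusion_list = character()) {
  stopifnot(is.numeric(protein_evalue_max), protein_evalue_max > 0,
            is.numeric(domain_ievalue_max), domain_ievalue_max > 0,
            is.numeric(overlap_frac_max),
            overlap_frac_max > 0, overlap_frac_max < 1,
            is.character(trypsin_families), length(trypsin_families) >= 1)
  structure(list(protein_evalue_max = protein_evalue_max,
                 domain_ievalue_max = domain_ievalue_max,
                 overlap_frac_max = overlap_frac_max,
                 trypsin_families = trypsin_families,
                 exclusion_list = as.character(exclusion_list)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Tryptome pipeline configuration\n")
  cat("  protein E-value max (full sequence): ", x$protein_evalue_max, "\n")
  cat("  domain i-E-value max:                ", x$domain_ievalue_max, "\n")
  cat("  overlap fraction max:                ", x$overlap_frac_max, "\n")
  cat("  trypsin families: ", paste(x$trypsin_families, collapse = ", "), "\n")
  cat("  excluded proteins:", length(x$exclusion_list), "\n")
  invisible(x)
}

as_pipeline_config <- function(x) {
  if (inherits(x, "pipeline_config")) return(x)
  if (is.null(x)) return(pipeline_config())
  stopifnot(is.list(x))
  do.call(pipeline_config, x[intersect(names(x), names(formals(pipeline_config)))])
}
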