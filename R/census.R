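# Tryptome census: trypsin-only vs multi-domain classification, associated
# domain abundance against the background proteome, and cross-taxon
# architecture sharing.

.is_trypsin <- function(family, cfg) family %in% cfg$trypsin_families

#' Classify a tryptome into trypsin-only and multi-domain proteins
#'
#' Partitions architectures by the presence of at least one non-trypsin
#' placed domain. The classification is invariant to the order of domains
#' within a protein.
#'
#' @param archs A list of [architecture()] objects from one taxon.
#' @param cfg A [pipeline_config()] (supplies `trypsin_families`).
#' @return A list with counts `n_trypsin_only` and `n_multidomain`;
#'   the two always sum to `length(archs)`.
#' @export
classify_tryptome <- function(archs, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  multi <- vapply(archs, function(a) {
    any(!.is_trypsin(a$domains$family, cfg))
  }, logical(1))
  list(n_trypsin_only = sum(!multi), n_multidomain = sum(multi))
}

#' Abundance of trypsin-associated domains relative to the proteome
#'
#' For every non-trypsin family occurring in the tryptome, counts domain
#' instances inside the tryptome (`n_tryptome`) and in the remaining
#' proteins of the predicted proteome (`n_background`), and computes the
#' tryptome fraction `n_tryptome / (n_tryptome + n_background)`. Two
#' descriptive flags are set from that fraction: `high_abundance_flag`
#' (fraction at least `high_abundance_min`, default 10%) and
#' `strong_association_flag` (fraction at least `strong_association_min`,
#' default 15%). The thresholds are descriptive, not inferential; an
#' optional hypergeometric enrichment p-value can be added with
#' `hypergeom = TRUE` (off by default), treating instances as draws of
#' tryptome vs background.
#'
#' @param archs Tryptome architectures (list of [architecture()]).
#' @param proteome_domains Data frame with columns `family` and
#'   `n_instances` giving domain-instance counts per family over the whole
#'   predicted proteome (tryptome included), and optionally
#'   `n_proteins_total` (proteins containing the family anywhere).
#' @param cfg A [pipeline_config()].
#' @param high_abundance_min,strong_association_min Flag thresholds.
#' @param hypergeom Attach a hypergeometric enrichment p-value per family.
#' @return Data frame with one row per associated family, ordered by
#'   decreasing tryptome fraction. The number of rows is the count of
#'   distinct trypsin-associated families, also stored in attribute
#'   `n_associated_families`.
#' @export
domain_abundance <- function(archs, proteome_domains,
                             cfg = pipeline_config(),
                             high_abundance_min = 0.10,
                             strong_association_min = 0.15,
                             hypergeom = FALSE) {
  cfg <- as_pipeline_config(cfg)
  dom <- placed_domains(archs)
  dom <- dom[!.is_trypsin(dom$family, cfg), , drop = FALSE]
  empty <- data.frame(family = character(), n_tryptome = integer(),
                      n_background = integer(),
                      n_proteins_total = integer(),
                      frac_tryptome = numeric(),
                      high_abundance_flag = logical(),
                      strong_association_flag = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(dom) == 0L) {
    attr(empty, "n_associated_families") <- 0L
    return(empty)
  }
  tab <- table(dom$family)
  fams <- names(tab)
  miss <- setdiff(fams, proteome_domains$family)
  if (length(miss)) {
    stop("family present in tryptome but absent from proteome table: ",
         paste(miss, collapse = ", "))
  }
  i <- match(fams, proteome_domains$family)
  total <- proteome_domains$n_instances[i]
  n_tryp <- as.integer(tab)
  if (any(total < n_tryp)) {
    stop("proteome instance count lower than tryptome count for family: ",
         paste(fams[total < n_tryp], collapse = ", "))
  }
  n_bg <- as.integer(total - n_tryp)
  frac <- n_tryp / (n_tryp + n_bg)
  out <- data.frame(
    family = fams,
    n_tryptome = n_tryp,
    n_background = n_bg,
    n_proteins_total = if ("n_proteins_total" %in% names(proteome_domains)) {
      as.integer(proteome_domains$n_proteins_total[i])
    } else NA_integer_,
    frac_tryptome = frac,
    high_abundance_flag = frac >= high_abundance_min,
    strong_association_flag = frac >= strong_association_min,
    stringsAsFactors = FALSE
  )
  if (hypergeom) {
    total_tryp <- sum(n_tryp)
    total_all <- sum(proteome_domains$n_instances)
    out$p_hyper <- stats::phyper(n_tryp - 1L, total_tryp,
                                 total_all - total_tryp,
                                 n_tryp + n_bg, lower.tail = FALSE)
  }
  out <- out[order(-out$frac_tryptome, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_associated_families") <- length(fams)
  out
}

#' Count domain instances per family in a hit table
#'
#' Convenience builder for the proteome background table consumed by
#' [domain_abundance()]: counts placed-domain instances per family over all
#' proteins in a hit table, after independent E-value gating, partial-hit
#' merging and overlap resolution (the same post-processing applied inside
#' the tryptome, so instance counting is consistent between the two sets).
#'
#' @param hits Data frame of domain hits for a whole proteome.
#' @param cfg A [pipeline_config()].
#' @return Data frame with columns `family`, `n_instances` and
#'   `n_proteins_total`.
#' @export
proteome_domain_table <- function(hits, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  h <- hits[hits$i_evalue <= cfg$domain_ievalue_max, , drop = FALSE]
  placed <- merge_partial_domains(h, cfg)
  placed <- resolve_overlaps(placed, cfg)
  tab <- table(placed$family)
  prot <- tapply(placed$protein_id, placed$family,
                 function(p) length(unique(p)))
  data.frame(family = names(tab),
             n_instances = as.integer(tab),
             n_proteins_total = as.integer(prot[names(tab)]),
             stringsAsFactors = FALSE)
}

#' Cross-taxon architecture sharing matrix
#'
#' Counts proteins per (architecture key, taxon). Keys are matched as exact
#' ordered family strings with multiplicity, so a rearranged architecture
#' counts as distinct; set `as_set = TRUE` to match unordered family sets
#' instead (a sensitivity mode).
#'
#' @param per_taxon_archs Named list (one element per taxon) of either
#'   architecture lists or plain character vectors of keys.
#' @param focal Optional focal taxon; keys observed only in that taxon are
#'   reported in attribute `unique_to_focal`.
#' @param as_set Match unordered family sets instead of ordered keys.
#' @return Integer matrix, rows = architecture keys, columns = taxa, with
#'   column sums equal to per-taxon tryptome sizes.
#' @export
architecture_sharing <- function(per_taxon_archs, focal = NULL,
                                 as_set = FALSE) {
  stopifnot(length(per_taxon_archs) >= 1, !is.null(names(per_taxon_archs)))
  keys <- lapply(per_taxon_archs, function(x) {
    k <- if (is.character(x)) x else architecture_keys(x)
    if (as_set) {
      k <- vapply(strsplit(k, "|", fixed = TRUE), function(f) {
        paste(sort(f), collapse = "|")
      }, character(1))
    }
    k
  })
  all_keys <- sort(unique(unlist(keys)))
  m <- vapply(keys, function(k) {
    as.integer(table(factor(k, levels = all_keys)))
  }, integer(length(all_keys)))
  m <- matrix(m, nrow = length(all_keys),
              dimnames = list(all_keys, names(per_taxon_archs)))
  if (!is.null(focal)) {
    stopifnot(focal %in% colnames(m))
    others <- m[, setdiff(colnames(m), focal), drop = FALSE]
    uniq <- rownames(m)[m[, focal] > 0 & rowSums(others) == 0]
    attr(m, "unique_to_focal") <- uniq
  }
  m
}
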