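# Curation of raw per-domain profile-HMM hits into canonical domain
# architectures: protein selection, merging of split partial hits, E-value
# gating and greedy pairwise overlap resolution.

#' Select tryptome proteins from a hit table
#'
#' A protein is selected when it has at least one hit to a trypsin-family
#' profile with full-sequence E-value at most `cfg$protein_evalue_max`, and
#' it is not on the curation exclusion list.
#'
#' @param hits Data frame of domain hits (see [parse_domtblout()]).
#' @param cfg A [pipeline_config()].
#' @return Sorted character vector of selected protein identifiers.
#' @export
select_trypsin_proteins <- function(hits, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  if (nrow(hits) == 0L) return(character())
  sel <- hits$family %in% cfg$trypsin_families &
    hits$full_evalue <= cfg$protein_evalue_max
  sort(setdiff(unique(hits$protein_id[sel]), cfg$exclusion_list))
}

#' Merge split partial domain hits into single placed domains
#'
#' Profile-HMM scans of fragmented or divergent sequences frequently report
#' one domain as several partial hits. Per protein and family, hits that are
#' non-overlapping in amino-acid space and complementary in profile
#' coordinates (their joint profile coverage exceeds that of each part
#' alone) are taken to represent one single contiguous domain spanning from
#' the first to the last part. The merged domain carries the minimum
#' independent E-value of its parts and records how many parts were merged.
#'
#' @param hits Data frame of domain hits; may cover many proteins.
#' @param cfg A [pipeline_config()] (not used by the merge rule itself but
#'   accepted for interface uniformity).
#' @return A placed-domain data frame with columns `protein_id`, `family`,
#'   `start`, `end` (1-based inclusive amino acids), `i_evalue` and
#'   `merged_from`, ordered by protein then start.
#' @export
merge_partial_domains <- function(hits, cfg = pipeline_config()) {
  if (nrow(hits) == 0L) return(.empty_placed())
  key <- paste(hits$protein_id, hits$family, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(hits)), key), function(ii) {
    .merge_group(hits[ii, , drop = FALSE])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$protein_id, out$start, out$end, out$family), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_placed <- function() {
  data.frame(protein_id = character(), family = character(),
             start = integer(), end = integer(), i_evalue = numeric(),
             merged_from = integer(), stringsAsFactors = FALSE)
}

# Merge one (protein, family) group of hits. Greedy left-to-right chaining:
# a hit joins the open chain when it is amino-acid-disjoint from the chain
# span and adds profile coverage the chain lacks (and vice versa).
.merge_group <- function(h) {
  o <- order(h$ali_start, h$ali_end)
  h <- h[o, , drop = FALSE]
  n <- nrow(h)
  group_id <- integer(n)
  g <- 1L
  group_id[1L] <- g
  cur_end <- h$ali_end[1L]
  cur_hs <- h$hmm_start[1L]
  cur_he <- h$hmm_end[1L]
  if (n > 1L) for (i in 2:n) {
    joint <- interval_union_length(c(cur_hs, h$hmm_start[i]),
                                   c(cur_he, h$hmm_end[i]))
    chain_cov <- interval_union_length(cur_hs, cur_he)
    hit_cov <- h$hmm_end[i] - h$hmm_start[i] + 1L
    complementary <- h$ali_start[i] > cur_end &&
      joint > chain_cov && joint > hit_cov
    if (complementary) {
      cur_end <- max(cur_end, h$ali_end[i])
      cur_hs <- c(cur_hs, h$hmm_start[i])
      cur_he <- c(cur_he, h$hmm_end[i])
    } else {
      g <- g + 1L
      cur_end <- h$ali_end[i]
      cur_hs <- h$hmm_start[i]
      cur_he <- h$hmm_end[i]
    }
    group_id[i] <- g
  }
  parts <- split(seq_len(n), group_id)
  do.call(rbind, lapply(parts, function(ii) {
    data.frame(protein_id = h$protein_id[ii[1L]],
               family = h$family[ii[1L]],
               start = min(h$ali_start[ii]),
               end = max(h$ali_end[ii]),
               i_evalue = min(h$i_evalue[ii]),
               merged_from = length(ii),
               stringsAsFactors = FALSE)
  }))
}

#' Resolve overlapping placed domains
#'
#' Applies the pairwise overlap rule: two domains overlapping by at most
#' `cfg$overlap_frac_max` of the shorter domain's length are both retained;
#' above that, the domain with the lower independent E-value wins.
#' Resolution is greedy: domains are visited in ascending E-value order
#' (ties broken by smaller start, then family name) and accepted unless they
#' overlap an already-accepted domain by more than the threshold. The greedy
#' order makes the outcome deterministic and independent of input order.
#'
#' @param domains Placed-domain data frame (may cover several proteins, in
#'   which case resolution is applied per protein).
#' @param cfg A [pipeline_config()].
#' @return The retained domains, ordered by protein then start.
#' @export
resolve_overlaps <- function(domains, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  if (nrow(domains) == 0L) return(domains)
  if (length(unique(domains$protein_id)) > 1L) {
    parts <- lapply(split(domains, domains$protein_id),
                    resolve_overlaps, cfg = cfg)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    return(out)
  }
  d <- domains
  o <- order(d$i_evalue, d$start, d$family)
  acc <- integer(0)
  for (i in o) {
    ok <- TRUE
    for (j in acc) {
      if (overlap_fraction(d$start[i], d$end[i], d$start[j], d$end[j]) >
            cfg$overlap_frac_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, i)
  }
  out <- d[acc[order(d$start[acc], d$end[acc], d$family[acc])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise overlap fraction between two domains
#'
#' Shared residues divided by the length of the shorter of the two domains
#' (1-based inclusive coordinates). Zero when the domains are disjoint.
#'
#' @param s1,e1,s2,e2 Start/end coordinates of the two domains.
#' @return Overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(s1, e1, s2, e2) {
  shared <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  shorter <- min(e1 - s1 + 1L, e2 - s2 + 1L)
  shared / shorter
}

#' Construct a domain architecture
#'
#' An architecture is the ordered N-to-C arrangement of placed domains on
#' one protein, identified by its canonical key: the family names joined by
#' `"|"` (e.g. `"Trypsin|ShK|ShK"`). The key regenerates deterministically
#' from the domain table.
#'
#' @param protein_id Protein identifier.
#' @param domains Placed-domain data frame for this protein (possibly empty).
#' @return An object of class `architecture`: a list with elements
#'   `protein_id`, `domains` (sorted by start) and `key`.
#' @export
architecture <- function(protein_id, domains = .empty_placed()) {
  if (nrow(domains)) {
    domains <- domains[order(domains$start, domains$end, domains$family), ,
                       drop = FALSE]
    rownames(domains) <- NULL
  }
  structure(list(protein_id = protein_id,
                 domains = domains,
                 key = paste(domains$family, collapse = "|")),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("<architecture> %s: %s (%d domains)\n", x$protein_id,
              if (nzchar(x$key)) x$key else "(empty)", nrow(x$domains)))
  invisible(x)
}

#' Build curated domain architectures from a hit table
#'
#' Composes the full curation chain: tryptome protein selection
#' ([select_trypsin_proteins()]), independent E-value gating of every
#' domain, merging of split partial hits ([merge_partial_domains()]) and
#' greedy overlap resolution ([resolve_overlaps()]). Associated (non-trypsin)
#' domains with independent E-value above `cfg$domain_ievalue_max` never
#' appear in an architecture.
#'
#' @param hits Data frame of domain hits for a whole proteome.
#' @param cfg A [pipeline_config()].
#' @return A named list of [architecture()] objects, one per selected
#'   protein, in protein-identifier order. A selected protein for which no
#'   domain survives gating yields an architecture with an empty domain
#'   table plus a warning.
#' @examples
#' sim <- sim_domain_hits(n_proteins = 5, n_decoys = 2, seed = 7)
#' archs <- build_architectures(sim$hits)
#' architecture_keys(archs)
#' @export
build_architectures <- function(hits, cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  selected <- select_trypsin_proteins(hits, cfg)
  h <- hits[hits$protein_id %in% selected &
              hits$i_evalue <= cfg$domain_ievalue_max, , drop = FALSE]
  placed <- merge_partial_domains(h, cfg)
  archs <- lapply(selected, function(p) {
    d <- placed[placed$protein_id == p, , drop = FALSE]
    d <- resolve_overlaps(d, cfg)
    if (nrow(d) == 0L) {
      warning("protein ", p, " selected but no domain survives E-value gating",
              call. = FALSE)
    }
    architecture(p, d)
  })
  names(archs) <- selected
  archs
}

#' Architecture keys of a set of architectures
#'
#' @param archs A list of [architecture()] objects.
#' @return Named character vector of canonical keys.
#' @export
architecture_keys <- function(archs) {
  vapply(archs, function(a) a$key, character(1))
}

#' Flatten architectures to a placed-domain table
#'
#' @param archs A list of [architecture()] objects.
#' @return Data frame with one row per placed domain (columns as in
#'   [merge_partial_domains()], plus the architecture `key`).
#' @export
placed_domains <- function(archs) {
  rows <- lapply(archs, function(a) {
    if (nrow(a$domains) == 0L) return(NULL)
    cbind(a$domains, key = a$key, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- cbind(.empty_placed(), key = character())
  }
  rownames(out) <- NULL
  out
}

#' Write an architecture report
#'
#' One row per placed domain, with the protein's canonical key repeated;
#' proteins with empty architectures are written with a single row of
#' missing domain fields so that every selected protein appears.
#'
#' @param archs A list of [architecture()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_architectures <- function(archs, path) {
  rows <- lapply(archs, function(a) {
    if (nrow(a$domains) == 0L) {
      data.frame(protein_id = a$protein_id, key = a$key, family = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 i_evalue = NA_real_, merged_from = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = a$protein_id, key = a$key,
                 family = a$domains$family, start = a$domains$start,
                 end = a$domains$end, i_evalue = a$domains$i_evalue,
                 merged_from = a$domains$merged_from,
                 stringsAsFactors = FALSE)
    }
  })
  write_tsv(do.call(rbind, rows), path)
}
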