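# Builders for tiny in-code fixtures and independent brute-force oracles.

hit_row <- function(protein_id, family, ali_start, ali_end,
                    hmm_start = 1L, hmm_end = ali_end - ali_start + 1L,
                    i_evalue = 1e-10, full_evalue = i_evalue / 100,
                    hmm_len = max(hmm_end, 100L), protein_len = 1000L,
                    family_acc = "PF00000.1") {
  data.frame(protein_id = protein_id, family = family,
             family_acc = family_acc, protein_len = protein_len,
             hmm_len = hmm_len, full_evalue = full_evalue,
             i_evalue = i_evalue, hmm_start = as.integer(hmm_start),
             hmm_end = as.integer(hmm_end),
             ali_start = as.integer(ali_start),
             ali_end = as.integer(ali_end),
             stringsAsFactors = FALSE)
}

hits_tbl <- function(...) do.call(rbind, list(...))

placed_tbl <- function(starts, ends, ies,
                       families = paste0("fam", seq_along(starts)),
                       protein_id = "p1") {
  data.frame(protein_id = protein_id, family = families,
             start = as.integer(starts), end = as.integer(ends),
             i_evalue = ies, merged_from = 1L, stringsAsFactors = FALSE)
}

random_placed <- function(n_domains, protein_id = "p1") {
  starts <- sample(1:400, n_domains, replace = TRUE)
  lens <- sample(20:150, n_domains, replace = TRUE)
  placed_tbl(starts, starts + lens - 1L,
             signif(10^-runif(n_domains, 0, 20), 6),
             families = sample(paste0("fam", 1:5), n_domains,
                               replace = TRUE),
             protein_id = protein_id)
}

# exhaustive pairwise check of the overlap rule on a resolved set
no_overlap_violation <- function(d, frac_max = 0.20) {
  n <- nrow(d)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (overlap_fraction(d$start[i], d$end[i], d$start[j], d$end[j]) >
          frac_max) {
      return(FALSE)
    }
  }
  TRUE
}

# tip labels under a node, computed independently of package internals
tips_of <- function(tree, nd) {
  if (nd <= ape::Ntip(tree)) return(tree$tip.label[nd])
  ape::extract.clade(tree, nd)$tip.label
}

# brute-force origin: deepest node whose subtree contains all presence taxa
oracle_origin <- function(tree, taxa) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  nodes <- seq_len(ntip + tree$Nnode)
  cand <- nodes[vapply(nodes, function(nd) all(taxa %in% tips_of(tree, nd)),
                       logical(1))]
  depth <- vapply(cand, function(nd) {
    length(ape::nodepath(tree, root, nd)) - 1L
  }, integer(1))
  cand[which.max(depth)]
}

# exhaustive clade enumeration oracle for representation criteria: every
# clade is tested, then satisfying clades containing another satisfying
# clade are discarded (minimal satisfying clades)
oracle_clades <- function(tree, meta, criterion) {
  nodes <- seq_len(ape::Ntip(tree) + tree$Nnode)
  leafsets <- lapply(nodes, function(nd) tips_of(tree, nd))
  ok <- vapply(nodes, function(nd) {
    leaves <- leafsets[[nd]]
    m <- meta[match(leaves, meta$leaf), ]
    all(vapply(names(criterion), function(g) {
      length(unique(m$taxon[m$group == g])) >= criterion[[g]]
    }, logical(1)))
  }, logical(1))
  sat <- nodes[ok]
  minimal <- Filter(function(nd) {
    !any(vapply(sat, function(other) {
      other != nd && all(leafsets[[other]] %in% leafsets[[nd]]) &&
        length(leafsets[[other]]) < length(leafsets[[nd]])
    }, logical(1)))
  }, sat)
  lapply(minimal, function(nd) sort(leafsets[[nd]]))
}

# toy aligned sequences around a 3-site catalytic triad
toy_triad_alignment <- function() {
  c(ref  = "GGHXX-DGGSPX",
    good = "AAHYY-DAASPA",
    noS  = "AAHYY-DAAAPA",
    noHD = "AAAYY-EAASPA",
    gapS = "AAHYY-DAA-PA")
}

toy_triad_spec <- function() {
  triad_spec("ref", positions = c(3L, 6L, 9L),
             required_residues = c("H", "D", "S"))
}
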