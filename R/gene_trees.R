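# Gene-tree inferences: taxon-representation clades, same-scaffold sister
# pairs (tandem-duplication candidates), and monophyly checks.

#' Gene tree with per-leaf metadata
#'
#' @param tree An `ape::phylo` gene tree.
#' @param meta Data frame with one row per leaf: columns `leaf`, `taxon`
#'   (required), and optionally `group` (taxon group used by
#'   representation criteria), `scaffold`, `start`, `end` (genomic
#'   coordinates). Every tree leaf must appear.
#' @param outgroup Optional leaf (or leaves) to root an unrooted tree on.
#' @return An object of class `gene_tree_info`.
#' @export
gene_tree_info <- function(tree, meta, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"),
            all(c("leaf", "taxon") %in% names(meta)))
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup, resolve.root = TRUE)
  }
  missing <- setdiff(tree$tip.label, meta$leaf)
  if (length(missing)) {
    stop("leaves without metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(tree$tip.label, meta$leaf), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(tree = tree, meta = meta), class = "gene_tree_info")
}

#' @export
print.gene_tree_info <- function(x, ...) {
  cat(sprintf("<gene_tree_info> %d leaves, %d taxa%s\n",
              ape::Ntip(x$tree), length(unique(x$meta$taxon)),
              if (ape::is.rooted(x$tree)) ", rooted" else ", unrooted"))
  invisible(x)
}

#' Read leaf metadata from a sidecar TSV
#'
#' @param path TSV with columns `leaf`, `taxon` and optionally `group`,
#'   `scaffold`, `start`, `end`.
#' @return Data frame.
#' @export
read_leaf_metadata <- function(path) read_tsv(path)

#' Clades satisfying a taxon-representation criterion
#'
#' Finds the smallest (most tipward) clades whose leaves include at least
#' the required number of distinct taxa from every named group: for
#' instance, at least two anthozoan and two medusozoan lineages, the
#' signature of a gene already present in the stem cnidarian. Because any
#' ancestor of a satisfying clade also satisfies the criterion, the
#' reported minimal clades are pairwise disjoint and their count estimates
#' the number of independent ancestral lineages.
#'
#' @param gt A [gene_tree_info()] (tree must be rooted, or supply
#'   `outgroup` to [gene_tree_info()]).
#' @param criterion Named integer vector, group name -> minimum count of
#'   distinct taxa required from that group.
#' @param by Metadata column holding the group labels (default
#'   `"group"`); distinct representatives are counted on the `taxon`
#'   column.
#' @return List of clade calls, each a list with `node` (ape node number),
#'   `leaves`, `taxon_counts` (distinct taxa per required group) and
#'   `support` (node label, if any). Empty when no clade satisfies the
#'   criterion.
#' @export
representation_clades <- function(gt, criterion, by = "group") {
  stopifnot(inherits(gt, "gene_tree_info"), length(criterion) >= 1,
            !is.null(names(criterion)))
  tree <- gt$tree
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it or supply an outgroup to gene_tree_info()")
  }
  if (!by %in% names(gt$meta)) {
    stop("metadata column '", by, "' not found")
  }
  groups <- gt$meta[[by]]
  taxa <- gt$meta$taxon
  ntip <- ape::Ntip(tree)
  tipsets <- .node_tips(tree)
  n_nodes <- ntip + tree$Nnode
  satisfied <- vapply(seq_len(n_nodes), function(nd) {
    .criterion_met(tipsets[[nd]], groups, taxa, criterion)
  }, logical(1))
  children <- .children(tree)
  # postorder flag: does any strict descendant satisfy?
  desc_sat <- logical(n_nodes)
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(post))) {
    p <- post[k, 1L]; ch <- post[k, 2L]
    desc_sat[p] <- desc_sat[p] || satisfied[ch] || desc_sat[ch]
  }
  keep <- which(satisfied & !desc_sat)
  lapply(keep, function(nd) {
    tips <- tipsets[[nd]]
    counts <- vapply(names(criterion), function(g) {
      length(unique(taxa[tips][groups[tips] == g]))
    }, integer(1))
    list(node = nd,
         leaves = tree$tip.label[tips],
         taxon_counts = counts,
         support = if (nd > ntip) .node_label(tree, nd) else NA_character_)
  })
}

.criterion_met <- function(tips, groups, taxa, criterion) {
  for (g in names(criterion)) {
    in_g <- tips[groups[tips] %in% g]
    if (length(unique(taxa[in_g])) < criterion[[g]]) return(FALSE)
  }
  TRUE
}

#' Same-scaffold sister pairs (tandem-duplication candidates)
#'
#' Finds cherries (two-leaf sister clades) whose members both come from the
#' focal taxon and lie on the same scaffold -- the gene-tree signature of a
#' tandem duplication. The genomic gap is the distance between the nearest
#' feature ends (0 when the features overlap, `NA` when coordinates are
#' missing).
#'
#' @param gt A [gene_tree_info()] with `scaffold` (and ideally `start`,
#'   `end`) metadata for focal-taxon leaves.
#' @param focal_taxon The taxon whose duplicates are sought.
#' @return Data frame (`leaf1`, `leaf2`, `scaffold`, `gap_bp`) sorted by
#'   increasing gap, undefined gaps last.
#' @export
sister_same_scaffold <- function(gt, focal_taxon) {
  stopifnot(inherits(gt, "gene_tree_info"))
  if (!"scaffold" %in% names(gt$meta)) {
    stop("metadata lacks a 'scaffold' column")
  }
  tree <- gt$tree
  meta <- gt$meta
  ntip <- ape::Ntip(tree)
  children <- .children(tree)
  out <- list()
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    ch <- children[[nd]]
    if (length(ch) != 2L || any(ch > ntip)) next
    m1 <- meta[ch[1L], ]; m2 <- meta[ch[2L], ]
    if (!identical(m1$taxon, focal_taxon) ||
          !identical(m2$taxon, focal_taxon)) next
    if (is.na(m1$scaffold) || is.na(m2$scaffold) ||
          m1$scaffold != m2$scaffold) next
    gap <- NA_integer_
    if (all(c("start", "end") %in% names(meta)) &&
          !anyNA(c(m1$start, m1$end, m2$start, m2$end))) {
      gap <- max(0L, max(m1$start, m2$start) - min(m1$end, m2$end))
    }
    leaves <- sort(c(m1$leaf, m2$leaf))
    out[[length(out) + 1L]] <- data.frame(
      leaf1 = leaves[1L], leaf2 = leaves[2L],
      scaffold = m1$scaffold, gap_bp = gap, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(leaf1 = character(), leaf2 = character(),
                      scaffold = character(), gap_bp = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gap_bp, res$leaf1, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Is a set of leaves monophyletic?
#'
#' True iff the subtree under the most recent common ancestor of the leaf
#' subset contains exactly that subset. Singletons and the full leaf set
#' are monophyletic by convention.
#'
#' @param gt A [gene_tree_info()] or a rooted `ape::phylo` tree.
#' @param leaf_subset Character vector of leaf labels.
#' @return Logical scalar.
#' @export
monophyly <- function(gt, leaf_subset) {
  tree <- if (inherits(gt, "gene_tree_info")) gt$tree else gt
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  unknown <- setdiff(leaf_subset, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaves: ", paste(unknown, collapse = ", "))
  }
  leaf_subset <- unique(leaf_subset)
  if (length(leaf_subset) <= 1L ||
        length(leaf_subset) == ape::Ntip(tree)) {
    return(TRUE)
  }
  mrca <- ape::getMRCA(tree, leaf_subset)
  tips <- .node_tips(tree)[[mrca]]
  setequal(tree$tip.label[tips], leaf_subset)
}
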