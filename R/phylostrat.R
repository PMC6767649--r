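# Phylostratigraphy: origin-node assignment of domains and trypsin-domain
# associations on a rooted species tree under a single-gain (Dollo)
# assumption, inferred losses, and the domain-age vs association-age
# relationship.

# children adjacency list indexed by node number
.children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2L])
  }
  ch
}

# tip numbers under each node (list over all node numbers)
.node_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  tips <- vector("list", n_nodes)
  for (i in seq_len(ntip)) tips[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]
    tips[[p]] <- c(tips[[p]], tips[[edges[k, 2L]]])
  }
  tips
}

#' Stratum rank of every node in a rooted tree
#'
#' The stratum rank is the number of edges separating a node from the root
#' (root = 0 = oldest). It serves as the ordinal age proxy in
#' phylostratigraphic dating: larger rank means younger origin.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @return Integer vector over node numbers (tips `1..Ntip`, then internal
#'   nodes in `ape` numbering).
#' @export
node_strata <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tr <- ape::reorder.phylo(tree, "cladewise")
  depth <- integer(ape::Ntip(tree) + tree$Nnode)
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + 1L
  }
  depth
}

.node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label
  if (!is.null(lab) && nzchar(lab[node - ntip] %||% "")) {
    return(lab[node - ntip])
  }
  paste0("node", node)
}

#' Build a presence matrix from per-taxon architectures
#'
#' Features are all domain families observed anywhere plus all trypsin
#' associations `"trypsin+X"`, where an association is present in a taxon
#' iff some protein there carries both a trypsin domain and the partner
#' domain X.
#'
#' @param per_taxon_archs Named list (taxon -> list of [architecture()]
#'   objects, or character vector of architecture keys).
#' @param cfg A [pipeline_config()] (supplies `trypsin_families`).
#' @return Logical matrix, features as rows, taxa as columns.
#' @export
presence_from_architectures <- function(per_taxon_archs,
                                        cfg = pipeline_config()) {
  cfg <- as_pipeline_config(cfg)
  stopifnot(length(per_taxon_archs) >= 1, !is.null(names(per_taxon_archs)))
  per_taxon_feats <- lapply(per_taxon_archs, function(x) {
    keys <- if (is.character(x)) x else architecture_keys(x)
    fam_lists <- strsplit(keys, "|", fixed = TRUE)
    fams <- unique(unlist(fam_lists))
    pairs <- unique(unlist(lapply(fam_lists, function(f) {
      if (!any(f %in% cfg$trypsin_families)) return(character())
      partners <- setdiff(unique(f), cfg$trypsin_families)
      if (length(partners) == 0L) return(character())
      paste0("trypsin+", partners)
    })))
    c(fams, pairs)
  })
  feats <- sort(unique(unlist(per_taxon_feats)))
  m <- vapply(per_taxon_feats, function(f) feats %in% f,
              logical(length(feats)))
  matrix(m, nrow = length(feats),
         dimnames = list(feats, names(per_taxon_archs)))
}

#' Assign origin nodes to features on a species tree
#'
#' Under the single-gain (Dollo) assumption, the origin of a feature is the
#' most recent common ancestor of all taxa possessing it; the minimum age
#' of the feature is the stratum rank of that node. Maximal clades below
#' the origin with no presence are reported as inferred losses. Features
#' with many inferred losses are flagged (`multi_gain_note`), since
#' repeated loss and independent gain cannot be distinguished by parsimony
#' alone.
#'
#' @param pm Logical presence matrix (features x taxa); all presence taxa
#'   must be tree leaves.
#' @param tree Rooted `ape::phylo` species tree with unique tip labels.
#' @param max_losses_note Loss count at or above which a feature is flagged
#'   as a possible repeated-gain case.
#' @return Data frame with one row per feature: `feature`, `origin_node`
#'   (ape node number), `origin_label`, `stratum`, `n_losses`, `losses`
#'   (list column of loss-clade tip sets) and `multi_gain_note`. Features
#'   with zero presence are skipped with a warning.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' pm <- rbind(f1 = c(A = TRUE, B = FALSE, C = TRUE, D = FALSE))
#' assign_origin(pm, tr)
#' @export
assign_origin <- function(pm, tree, max_losses_note = 3L) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  if (anyDuplicated(tree$tip.label)) stop("tree tip labels must be unique")
  taxa <- colnames(pm)
  unknown <- setdiff(taxa[colSums(pm) > 0], tree$tip.label)
  if (length(unknown)) {
    stop("presence taxa not on tree: ", paste(unknown, collapse = ", "))
  }
  depth <- node_strata(tree)
  children <- .children(tree)
  tipsets <- .node_tips(tree)
  ntip <- ape::Ntip(tree)
  rows <- lapply(rownames(pm), function(feat) {
    pres <- taxa[pm[feat, ]]
    if (length(pres) == 0L) {
      warning("feature '", feat, "' has no presence; skipped", call. = FALSE)
      return(NULL)
    }
    tip_idx <- match(pres, tree$tip.label)
    node <- if (length(tip_idx) == 1L) tip_idx else {
      ape::getMRCA(tree, tip_idx)
    }
    losses <- .loss_clades(node, children, tipsets, tip_idx)
    loss_sets <- lapply(losses, function(nd) tree$tip.label[tipsets[[nd]]])
    data.frame(feature = feat,
               origin_node = node,
               origin_label = .node_label(tree, node),
               stratum = depth[node],
               n_losses = length(losses),
               losses = I(list(loss_sets)),
               multi_gain_note = length(losses) >= max_losses_note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(), origin_node = integer(),
                      origin_label = character(), stratum = integer(),
                      n_losses = integer(), losses = I(list()),
                      multi_gain_note = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# maximal all-absent clades strictly below `node`
.loss_clades <- function(node, children, tipsets, present_tips) {
  out <- integer(0)
  recurse <- function(nd) {
    for (ch in children[[nd]]) {
      if (!any(tipsets[[ch]] %in% present_tips)) {
        out <<- c(out, ch)
      } else {
        recurse(ch)
      }
    }
  }
  recurse(node)
  out
}

#' Relationship between domain age and association age
#'
#' Pairs each trypsin association `"trypsin+X"` with its partner domain
#' `X` and correlates the two stratum ranks by Spearman rank correlation
#' (tie-corrected, asymptotic p-value). Because an association cannot
#' predate the partner domain itself, any pair where the association is
#' assigned an older stratum than the domain is reported as an error: it
#' signals inconsistent presence data.
#'
#' @param domain_assignments,association_assignments Data frames from
#'   [assign_origin()] for the plain domain features and for the
#'   `"trypsin+X"` association features respectively.
#' @return A list with `pairs` (data frame `family`, `domain_stratum`,
#'   `association_stratum`), `rho`, `p_value` and `n`.
#' @export
age_relationship <- function(domain_assignments, association_assignments) {
  assoc <- association_assignments[
    startsWith(association_assignments$feature, "trypsin+"), , drop = FALSE]
  fam <- sub("^trypsin\\+", "", assoc$feature)
  i <- match(fam, domain_assignments$feature)
  if (anyNA(i)) {
    stop("association without matching domain feature: ",
         paste(assoc$feature[is.na(i)], collapse = ", "))
  }
  ds <- domain_assignments$stratum[i]
  as_ <- assoc$stratum
  bad <- which(as_ < ds)
  if (length(bad)) {
    stop("association older than its domain (inconsistent presence data): ",
         paste(assoc$feature[bad], collapse = ", "))
  }
  pairs <- data.frame(family = fam, domain_stratum = ds,
                      association_stratum = as_,
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3L || stats::sd(ds) == 0 || stats::sd(as_) == 0) {
    return(list(pairs = pairs, rho = NA_real_, p_value = NA_real_,
                n = nrow(pairs)))
  }
  ct <- suppressWarnings(stats::cor.test(ds, as_, method = "spearman",
                                         exact = FALSE))
  list(pairs = pairs, rho = unname(ct$estimate), p_value = ct$p.value,
       n = nrow(pairs))
}

#' Prune a tree to a subset of taxa
#'
#' Returns the induced subtree on `keep_taxa` with unbranched internal
#' nodes suppressed (the usual pruning semantics, as in Phyutility-style
#' tree thinning).
#'
#' @param tree An `ape::phylo` tree.
#' @param keep_taxa Nonempty subset of the tip labels.
#' @return The pruned `phylo` tree.
#' @export
prune_tree <- function(tree, keep_taxa) {
  stopifnot(inherits(tree, "phylo"), length(keep_taxa) >= 1)
  unknown <- setdiff(keep_taxa, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (setequal(keep_taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep_taxa)
}

#' Write / read a presence matrix as TSV
#'
#' @param pm Logical matrix (features x taxa).
#' @param path TSV path.
#' @return `path` invisibly for the writer; the matrix for the reader.
#' @export
write_presence <- function(pm, path) {
  df <- data.frame(feature = rownames(pm),
                   ifelse(pm, 1L, 0L),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_presence
#' @export
read_presence <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE]) == 1L
  rownames(m) <- df[[1L]]
  m
}
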