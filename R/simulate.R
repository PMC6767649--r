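# Synthetic-data generators with planted ground truth. Every generator is
# deterministic given its seed and writes/returns the same formats the
# pipeline reads, so all downstream stages are testable with no downloads.

# Typical Pfam model lengths (amino acids) for the families used by the
# generators; unlisted families fall back to 60 aa.
.family_lengths <- c(
  Trypsin = 220L, Trypsin_2 = 108L, ShK = 35L, MAM = 160L, PDZ = 85L,
  Sushi = 56L, SRCR = 100L, CUB = 110L, EGF_CA = 40L, DIM = 40L,
  Lustrin_cystein = 45L, WSC = 90L, Astacin = 200L, FXa_inhibition = 40L,
  TSP_1 = 50L, Death = 85L, LDLa = 37L, Kringle = 79L
)

.family_length <- function(fam) {
  unname(ifelse(fam %in% names(.family_lengths),
                .family_lengths[fam], 60L))
}

#' Default architecture catalog for the synthetic proteome
#'
#' Seventy-two proteins whose key frequencies mirror a sea-anemone-like
#' tryptome: 28 trypsin-only proteins and 44 multi-domain proteins drawing
#' on the commonly trypsin-associated families (ShK, MAM, PDZ, Sushi,
#' SRCR, CUB, ...), including a triple-trypsin protein and a Trypsin_2
#' representative.
#'
#' @return Named integer vector: architecture key -> protein count.
#' @export
sim_architecture_catalog <- function() {
  c("Trypsin" = 28L,
    "Trypsin|ShK" = 8L,
    "Trypsin|ShK|ShK" = 4L,
    "Trypsin|MAM" = 6L,
    "Trypsin|MAM|MAM" = 2L,
    "Trypsin|PDZ" = 4L,
    "Trypsin|Sushi" = 4L,
    "Trypsin|SRCR" = 3L,
    "Trypsin|CUB" = 3L,
    "Trypsin|EGF_CA" = 2L,
    "Trypsin|Lustrin_cystein" = 1L,
    "Trypsin|WSC" = 1L,
    "Trypsin|DIM" = 1L,
    "Trypsin|Astacin" = 2L,
    "Trypsin_2|ShK" = 2L,
    "Trypsin|Trypsin|Trypsin" = 1L)
}

#' Simulate a domtblout hit table with planted architectures
#'
#' Each synthetic protein receives hits realising its planted architecture
#' key, drawn from `catalog`. With probability `split_prob` a trypsin
#' domain is emitted as two complementary partial hits (amino-acid
#' disjoint, jointly covering the profile), emulating fragmented gene
#' models. Decoy material straddles both E-value thresholds so boundary
#' behaviour is always exercised: `n_decoys` extra proteins carry only a
#' trypsin hit with full-sequence E-value above the 1e-5 selection cutoff,
#' and with probability `decoy_hit_rate` a real protein gains a noise
#' domain whose independent E-value is log-uniform across the 0.05 gate.
#' Noise hits that land below the gate are genuine domains and are
#' incorporated into the planted truth key; hits above it must be removed
#' by the pipeline.
#'
#' @param n_proteins Number of tryptome proteins. When it equals
#'   `sum(catalog)` the catalog is realised exactly; otherwise keys are
#'   sampled with probability proportional to the catalog weights.
#' @param catalog Named vector of architecture-key weights.
#' @param split_prob Probability that a trypsin domain is split in two.
#' @param n_decoys Number of decoy proteins above the selection threshold.
#' @param decoy_hit_rate Per-protein probability of a noise domain hit.
#' @param cfg A [pipeline_config()]; supplies the thresholds the decoys
#'   straddle.
#' @param seed RNG seed (the generator is deterministic given the seed).
#' @return A list with `hits` (data frame in [parse_domtblout()] layout)
#'   and `truth` (data frame `protein_id`, `key` of planted keys).
#' @export
sim_domain_hits <- function(n_proteins = 72L,
                            catalog = sim_architecture_catalog(),
                            split_prob = 0.2,
                            n_decoys = 20L,
                            decoy_hit_rate = 0.25,
                            cfg = pipeline_config(),
                            seed = 1L) {
  stopifnot(length(catalog) >= 1, !is.null(names(catalog)),
            split_prob >= 0, split_prob <= 1,
            decoy_hit_rate >= 0, decoy_hit_rate <= 1)
  cfg <- as_pipeline_config(cfg)
  local_seed(seed, {
    keys <- if (n_proteins == sum(catalog)) {
      rep(names(catalog), catalog)
    } else {
      sample(names(catalog), n_proteins, replace = TRUE,
             prob = catalog / sum(catalog))
    }
    noise_pool <- setdiff(names(.family_lengths), cfg$trypsin_families)
    rows <- list()
    truth <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      pid <- sprintf("prot_%04d", i)
      fams <- strsplit(keys[i], "|", fixed = TRUE)[[1L]]
      planted <- .plant_protein(pid, fams, split_prob, cfg)
      truth_fams <- fams
      if (stats::runif(1) < decoy_hit_rate) {
        nf <- sample(noise_pool, 1L)
        ie <- signif(10^stats::runif(1, -3, 1), 6)
        len <- .family_length(nf)
        s <- planted$cursor + sample(10:30, 1L)
        noise <- data.frame(
          protein_id = pid, family = nf, family_acc = .fam_acc(nf),
          protein_len = 0L, hmm_len = len,
          full_evalue = signif(ie / 100, 6), i_evalue = ie,
          hmm_start = 1L, hmm_end = len,
          ali_start = s, ali_end = s + len - 1L,
          stringsAsFactors = FALSE)
        planted$hits <- rbind(planted$hits, noise)
        planted$cursor <- s + len - 1L
        if (ie <= cfg$domain_ievalue_max) truth_fams <- c(truth_fams, nf)
      }
      planted$hits$protein_len <- planted$cursor + 40L
      rows[[i]] <- planted$hits
      truth[i] <- paste(truth_fams, collapse = "|")
    }
    for (j in seq_len(n_decoys)) {
      pid <- sprintf("decoy_%04d", j)
      fam <- sample(cfg$trypsin_families, 1L)
      len <- .family_length(fam)
      # full-sequence E-value log-uniform above the selection cutoff
      fe <- signif(10^stats::runif(1, log10(cfg$protein_evalue_max) + 0.1,
                                   -0.1), 6)
      rows[[n_proteins + j]] <- data.frame(
        protein_id = pid, family = fam, family_acc = .fam_acc(fam),
        protein_len = len + 60L, hmm_len = len,
        full_evalue = fe, i_evalue = signif(fe * 10, 6),
        hmm_start = 1L, hmm_end = len,
        ali_start = 30L, ali_end = 30L + len - 1L,
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    # full-sequence E-value is shared by all hits of one (protein, family)
    grp <- paste(hits$protein_id, hits$family, sep = "\r")
    shared <- tapply(hits$full_evalue, grp, min)
    hits$full_evalue <- as.numeric(shared[grp])
    rownames(hits) <- NULL
    list(hits = hits,
         truth = data.frame(protein_id = sprintf("prot_%04d",
                                                 seq_len(n_proteins)),
                            key = truth, stringsAsFactors = FALSE))
  })
}

.fam_acc <- function(fam) {
  known <- c(Trypsin = "PF00089.26", Trypsin_2 = "PF13365.6")
  ifelse(fam %in% names(known), known[fam],
         sprintf("PF%05d.1", 10000L + (utf8ToInt(substr(fam, 1, 1)) %% 999L)))
}

# Emit the hits realising one protein's family list; returns hits + cursor.
.plant_protein <- function(pid, fams, split_prob, cfg) {
  cursor <- sample(5:20, 1L)
  rows <- list()
  for (fam in fams) {
    len <- .family_length(fam)
    s <- cursor
    e <- cursor + len - 1L
    ie <- signif(10^-stats::runif(1, 6, 30), 6)
    if (fam %in% cfg$trypsin_families && stats::runif(1) < split_prob) {
      cut <- len %/% 2L
      e1 <- s + floor(0.45 * len)
      s2 <- s + ceiling(0.55 * len)
      ie2 <- signif(10^-stats::runif(1, 4, 15), 6)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, family = fam, family_acc = .fam_acc(fam),
        protein_len = 0L, hmm_len = len,
        full_evalue = signif(ie / 100, 6),
        i_evalue = c(ie, ie2),
        hmm_start = c(1L, cut + 4L), hmm_end = c(cut, len),
        ali_start = c(s, s2), ali_end = c(e1, e),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, family = fam, family_acc = .fam_acc(fam),
        protein_len = 0L, hmm_len = len,
        full_evalue = signif(ie / 100, 6), i_evalue = ie,
        hmm_start = 1L, hmm_end = len,
        ali_start = s, ali_end = e,
        stringsAsFactors = FALSE)
    }
    cursor <- e + sample(10:30, 1L)
  }
  list(hits = do.call(rbind, rows), cursor = cursor)
}

#' Simulate gene models with planted exon structure
#'
#' Writes a GFF3 file of single-transcript gene models and returns the
#' planted truth. Multi-exon genes carry a domain whose coding span crosses
#' the first exon boundary by exactly 8 or exactly 11 nucleotides,
#' straddling the 10-nt overhang rule; every multi-exon layout is emitted
#' on both strands (the minus-strand gene is a mirrored copy with identical
#' transcription-order exon lengths). `n_intronless` genes have a single
#' CDS segment.
#'
#' @param n_intronless Number of planted intronless genes.
#' @param n_multiexon Number of multi-exon genes; strand and overhang
#'   (8/11 nt) alternate across them.
#' @param path Optional output path for the GFF3 file.
#' @param seed RNG seed (placement jitter only; layouts are fixed).
#' @return A list with `gff` (the path, or NULL when not written),
#'   `models` (data frame of gene-model rows) and `truth` (data frame
#'   `protein_id`, `strand`, `intronless`, `scaffold`, `domain_start`,
#'   `domain_end` (aa), `overhang_nt`, `expected_exons`).
#' @export
sim_gff <- function(n_intronless = 2L, n_multiexon = 8L, path = NULL,
                    seed = 1L) {
  stopifnot(n_intronless >= 0, n_multiexon >= 0,
            n_intronless + n_multiexon >= 1)
  local_seed(seed, {
    truth <- list()
    feats <- list()
    g <- 0L
    add_gene <- function(pid, scaf, strand, exon_lens, intron,
                         dom, overhang, expected) {
      # exon_lens are in transcription order
      offset <- 1000L + sample(0:50, 1L)
      n <- length(exon_lens)
      if (strand == "+") {
        starts <- offset + cumsum(c(0L, head(exon_lens, -1L) + intron))
        ends <- starts + exon_lens - 1L
      } else {
        # transcription runs right to left: first exon has the largest start
        ends_rev <- offset + cumsum(c(0L, head(rev(exon_lens), -1L) +
                                        intron)) + rev(exon_lens) - 1L
        starts_rev <- ends_rev - rev(exon_lens) + 1L
        starts <- rev(starts_rev)
        ends <- rev(ends_rev)
      }
      phase <- (3L - (cumsum(c(0L, head(exon_lens, -1L))) %% 3L)) %% 3L
      feats[[length(feats) + 1L]] <<- data.frame(
        seqid = scaf, type = c("gene", "mRNA", rep("CDS", n)),
        start = c(min(starts), min(starts), starts),
        end = c(max(ends), max(ends), ends),
        strand = strand,
        phase = c(NA_integer_, NA_integer_, phase),
        id = c(paste0("gene_", pid), pid, rep(NA_character_, n)),
        parent = c(NA_character_, paste0("gene_", pid), rep(pid, n)),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        protein_id = pid, strand = strand, intronless = n == 1L,
        scaffold = scaf, domain_start = dom[1L], domain_end = dom[2L],
        overhang_nt = overhang, expected_exons = expected,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_intronless)) {
      g <- g + 1L
      strand <- if (i %% 2L == 1L) "+" else "-"
      add_gene(sprintf("prot_%04d", g), sprintf("scaf_%02d", g), strand,
               exon_lens = 300L, intron = 0L, dom = c(10L, 80L),
               overhang = NA_integer_, expected = 1L)
    }
    for (i in seq_len(n_multiexon)) {
      g <- g + 1L
      strand <- if (i %% 2L == 1L) "+" else "-"
      overhang <- if (((i - 1L) %/% 2L) %% 2L == 0L) 8L else 11L
      # exon 1 is 100 nt; a domain from aa 4 to aa (100 + overhang)/3
      # reaches exactly `overhang` nt into exon 2
      dom_end_aa <- (100L + overhang) %/% 3L
      stopifnot((100L + overhang) %% 3L == 0L)
      add_gene(sprintf("prot_%04d", g), sprintf("scaf_%02d", g), strand,
               exon_lens = c(100L, 200L), intron = 400L,
               dom = c(4L, dom_end_aa), overhang = overhang,
               expected = if (overhang <= 10L) 1L else 2L)
    }
    models <- do.call(rbind, feats)
    truth <- do.call(rbind, truth)
    if (!is.null(path)) .write_gff3(models, path)
    list(gff = path, models = models, truth = truth)
  })
}

.write_gff3 <- function(models, path) {
  attrs <- ifelse(
    !is.na(models$id) & !is.na(models$parent),
    paste0("ID=", models$id, ";Parent=", models$parent),
    ifelse(!is.na(models$id), paste0("ID=", models$id),
           paste0("Parent=", models$parent)))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                   models$seqid, "tryptome_sim", models$type,
                   models$start, models$end, models$strand,
                   ifelse(is.na(models$phase), ".",
                          as.character(models$phase)),
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Simulate a single-cell count matrix with planted co-expression structure
#'
#' Builds a cell-by-gene trypsin count matrix whose per-gene ubiquity
#' (cells expressing the gene) and co-expression count (cells sharing it
#' with another trypsin) realise a planted positive correlation, and whose
#' trypsins-per-cell histogram has the characteristic mode at one:
#' single-trypsin cells plus a geometric tail of co-expressing cells.
#'
#' The construction first draws each gene's ubiquity uniformly on
#' `u_range` and a co-expressed fraction from a Beta distribution whose
#' variance is solved so that the expected Pearson correlation between
#' ubiquity and co-expression equals `rho`; it then realises the resulting
#' degree sequence exactly, with co-expressing cells of size
#' `2 + Geometric(cocell_geom_p)` and one solo cell per remaining
#' expression incidence. Counts of expressed entries are
#' `1 + Geometric(1/count_mean)`; magnitudes carry no signal, only the
#' presence threshold matters.
#'
#' @param n_genes Number of trypsin genes.
#' @param rho Planted ubiquity-co-expression Pearson correlation.
#' @param u_range Integer range of per-gene ubiquities.
#' @param cocell_geom_p Geometric parameter of co-expressing cell sizes.
#' @param count_mean Mean read count of an expressed entry.
#' @param seed RNG seed.
#' @return A list with `counts` (sparse cell x gene matrix),
#'   `trypsin_genes`, and `truth`: `n_expressing_cells`, `histogram`
#'   (named vector over trypsins per cell), `per_gene` (data frame `gene`,
#'   `ubiquity`, `co_cells`) and `planted_rho`.
#' @export
sim_cell_matrix <- function(n_genes = 60L, rho = 0.9,
                            u_range = c(10L, 100L), cocell_geom_p = 0.55,
                            count_mean = 2, seed = 1L) {
  stopifnot(n_genes >= 3, rho > 0, rho <= 1, u_range[1] >= 1,
            u_range[2] > u_range[1], count_mean >= 1)
  local_seed(seed, {
    u <- sample(seq(u_range[1L], u_range[2L]), n_genes, replace = TRUE)
    co <- .plant_co_counts(u, rho)
    alloc <- .allocate_cocells(u, co, cocell_geom_p)
    co <- alloc$co
    cells <- alloc$cells
    solo <- u - co
    genes <- sprintf("tryp_%02d", seq_len(n_genes))
    solo_genes <- rep(seq_len(n_genes), solo)
    n_cells <- length(cells) + length(solo_genes)
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))
    i <- c(rep(seq_along(cells), lengths(cells)),
           length(cells) + seq_along(solo_genes))
    j <- c(unlist(cells), solo_genes)
    x <- 1L + stats::rgeom(length(i), prob = 1 / count_mean)
    counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                   dims = c(n_cells, n_genes),
                                   dimnames = list(cell_ids, genes))
    sizes <- lengths(cells)
    hist_k <- sort(unique(c(1L, sizes)))
    hist <- vapply(hist_k, function(k) {
      if (k == 1L) length(solo_genes) else sum(sizes == k)
    }, integer(1))
    names(hist) <- hist_k
    hist <- hist[hist > 0L]
    list(counts = counts, trypsin_genes = genes,
         truth = list(n_expressing_cells = n_cells,
                      histogram = hist,
                      per_gene = data.frame(gene = genes,
                                            ubiquity = as.integer(u),
                                            co_cells = as.integer(co),
                                            stringsAsFactors = FALSE),
                      planted_rho = rho))
  })
}

# Draw co-expression counts co_g = round(u_g * f_g) with f ~ Beta(a, a),
# the variance of f solved so that cor(u, co) has expectation `rho` for
# the drawn ubiquities u.
.plant_co_counts <- function(u, rho) {
  var_u <- stats::var(u)
  if (var_u == 0) var_u <- 1
  e_u2 <- mean(u^2)
  var_f <- 0.25 * var_u / e_u2 * (1 / rho^2 - 1)
  var_f <- min(var_f, 0.2)
  a <- max(0.5, (1 / (4 * var_f) - 1) / 2)
  f <- stats::rbeta(length(u), a, a)
  pmin(u, pmax(0L, as.integer(round(u * f))))
}

# Realise the co-expression degree sequence: cells of size 2+Geom(p), each
# containing distinct genes, with gene g appearing in exactly co[g] cells.
.allocate_cocells <- function(u, co, p) {
  S <- sum(co)
  if (S == 0L) return(list(co = co, cells = list()))
  sizes <- integer(0)
  tot <- 0L
  while (tot < S) {
    s <- 2L + stats::rgeom(1L, p)
    sizes <- c(sizes, s)
    tot <- tot + s
  }
  surplus <- tot - S
  # absorb the surplus by raising co for genes with headroom (co < u)
  while (surplus > 0L) {
    head_idx <- which(co < u)
    if (length(head_idx) == 0L) {
      # no headroom anywhere: shrink the last oversized cell instead
      k <- which(sizes > 2L)
      if (length(k) == 0L) stop("cannot realise co-expression degrees")
      sizes[k[length(k)]] <- sizes[k[length(k)]] - 1L
      surplus <- surplus - 1L
      next
    }
    g <- if (length(head_idx) == 1L) head_idx else sample(head_idx, 1L)
    co[g] <- co[g] + 1L
    surplus <- surplus - 1L
  }
  slots <- sample(rep.int(seq_along(co), co))
  cells <- split(slots, rep(seq_along(sizes), sizes))
  cells <- .fix_duplicate_slots(cells)
  list(co = co, cells = cells)
}

# Swap slots between cells until no cell contains the same gene twice.
.fix_duplicate_slots <- function(cells) {
  for (pass in 1:1000) {
    dup <- which(vapply(cells, anyDuplicated, integer(1)) > 0L)
    if (length(dup) == 0L) return(cells)
    for (ci in dup) {
      x <- cells[[ci]]
      # an earlier swap in this pass may already have fixed this cell
      if (anyDuplicated(x) == 0L) next
      g <- x[duplicated(x)][1L]
      pos <- which(x == g)[2L]
      for (cj in sample(seq_along(cells))) {
        if (cj == ci) next
        y <- cells[[cj]]
        cand <- which(!(y %in% x))
        if (length(cand) && !(g %in% y)) {
          cells[[ci]][pos] <- y[cand[1L]]
          cells[[cj]][cand[1L]] <- g
          break
        }
      }
    }
  }
  dup <- which(vapply(cells, anyDuplicated, integer(1)) > 0L)
  if (length(dup)) stop("could not realise co-expression degree sequence")
  cells
}

#' Simulate presence/absence evolution on a species tree
#'
#' Each feature gains at a planted node (sampled uniformly over nodes, or
#' restricted to internal nodes) and is then lost independently on every
#' descendant edge with probability `loss_prob`; a loss removes the whole
#' subtree below the edge. Features losing all presence are discarded and
#' reported.
#'
#' @param n_leaves Number of leaves when growing a new tree.
#' @param n_features Number of features to evolve.
#' @param loss_prob Per-edge loss probability.
#' @param tree Optional `ape::phylo` tree to reuse (must be rooted).
#' @param shape `"random"` (Yule-like via `ape::rtree`) or `"balanced"`.
#' @param gains_at Sample gain nodes from `"any"` node or `"internal"`
#'   nodes only.
#' @param seed RNG seed.
#' @return A list with `tree`, `presence` (logical feature x taxon
#'   matrix), `truth` (data frame `feature`, `gain_node`, `gain_label`)
#'   and `n_dropped` (features extinguished by loss).
#' @export
sim_presence <- function(n_leaves = 16L, n_features = 200L,
                         loss_prob = 0.2, tree = NULL,
                         shape = c("random", "balanced"),
                         gains_at = c("any", "internal"), seed = 1L) {
  shape <- match.arg(shape)
  gains_at <- match.arg(gains_at)
  stopifnot(loss_prob >= 0, loss_prob < 1)
  local_seed(seed, {
    if (is.null(tree)) {
      tree <- if (shape == "balanced") {
        ape::stree(n_leaves, type = "balanced")
      } else {
        ape::rtree(n_leaves)
      }
    }
    stopifnot(ape::is.rooted(tree))
    ntip <- ape::Ntip(tree)
    if (is.null(tree$node.label) || !any(nzchar(tree$node.label))) {
      tree$node.label <- paste0("n", (ntip + 1L):(ntip + tree$Nnode))
    }
    children <- .children(tree)
    nodes <- if (gains_at == "any") {
      seq_len(ntip + tree$Nnode)
    } else {
      (ntip + 1L):(ntip + tree$Nnode)
    }
    pm <- matrix(FALSE, nrow = n_features, ncol = ntip,
                 dimnames = list(sprintf("feat_%03d", seq_len(n_features)),
                                 tree$tip.label))
    gain <- integer(n_features)
    alive <- logical(n_features)
    for (f in seq_len(n_features)) {
      gain[f] <- if (length(nodes) == 1L) nodes else sample(nodes, 1L)
      pres <- .evolve_presence(gain[f], children, ntip, loss_prob)
      if (length(pres)) {
        pm[f, pres] <- TRUE
        alive[f] <- TRUE
      }
    }
    truth <- data.frame(feature = rownames(pm)[alive],
                        gain_node = gain[alive],
                        gain_label = vapply(gain[alive], .node_label,
                                            character(1), tree = tree),
                        stringsAsFactors = FALSE)
    list(tree = tree, presence = pm[alive, , drop = FALSE],
         truth = truth, n_dropped = sum(!alive))
  })
}

# surviving tip numbers below `node` after independent per-edge losses
.evolve_presence <- function(node, children, ntip, loss_prob) {
  if (node <= ntip) return(node)
  out <- integer(0)
  for (ch in children[[node]]) {
    if (stats::runif(1) >= loss_prob) {
      out <- c(out, .evolve_presence(ch, children, ntip, loss_prob))
    }
  }
  out
}

#' Simulate a gene tree with planted same-scaffold sister pairs
#'
#' Grows a random gene tree over several taxa, then grafts
#' `n_tandem_pairs` cherries of focal-taxon leaves; the two members of each
#' cherry share a scaffold with a known genomic gap, while every other
#' focal leaf sits on its own scaffold. Group labels (anthozoan,
#' medusozoan, bilaterian, outgroup) come from a small built-in taxon
#' table.
#'
#' @param n_background Number of non-planted leaves.
#' @param n_tandem_pairs Number of planted same-scaffold cherries.
#' @param focal_taxon Focal taxon for the planted pairs.
#' @param seed RNG seed.
#' @return A list with `gt` (a [gene_tree_info()]) and `truth` (data frame
#'   `leaf1`, `leaf2`, `scaffold`, `gap_bp`).
#' @export
sim_gene_tree <- function(n_background = 32L, n_tandem_pairs = 4L,
                          focal_taxon = "Nvectensis", seed = 1L) {
  stopifnot(n_background >= 3, n_tandem_pairs >= 0)
  taxon_table <- data.frame(
    taxon = c("Nvectensis", "Elineata", "Adigitifera", "Rrenilla",
              "Hmagnipapillata", "Aalata", "Avanhoeffeni",
              "Ccruxmelitensis", "Hsapiens", "Cteleta", "Mleidyi",
              "Tadhaerens"),
    group = c(rep("anthozoan", 4L), rep("medusozoan", 4L),
              rep("bilaterian", 2L), rep("outgroup", 2L)),
    stringsAsFactors = FALSE)
  local_seed(seed, {
    n_host <- n_background + n_tandem_pairs
    tree <- ape::rtree(n_host)
    tree$tip.label <- sprintf("leaf_%03d", seq_len(n_host))
    taxa <- sample(taxon_table$taxon, n_host, replace = TRUE)
    hosts <- sample(tree$tip.label, n_tandem_pairs)
    nwk <- ape::write.tree(tree)
    meta <- data.frame(leaf = tree$tip.label, taxon = taxa,
                       stringsAsFactors = FALSE)
    truth <- list()
    for (k in seq_len(n_tandem_pairs)) {
      a <- sprintf("nv_pair%02d_a", k)
      b <- sprintf("nv_pair%02d_b", k)
      nwk <- sub(paste0(hosts[k], ":"),
                 sprintf("(%s:0.05,%s:0.05):", a, b), nwk, fixed = TRUE)
      meta <- meta[meta$leaf != hosts[k], , drop = FALSE]
      gap <- 1000L * k
      scaf <- sprintf("scaf_pair%02d", k)
      meta <- rbind(meta,
                    data.frame(leaf = c(a, b), taxon = focal_taxon,
                               stringsAsFactors = FALSE))
      truth[[k]] <- data.frame(leaf1 = a, leaf2 = b, scaffold = scaf,
                               gap_bp = gap, stringsAsFactors = FALSE)
    }
    tree <- ape::read.tree(text = nwk)
    meta$group <- taxon_table$group[match(meta$taxon, taxon_table$taxon)]
    # scaffolds: planted pairs share one, everything else is unique
    meta$scaffold <- paste0("scaf_bg_", seq_len(nrow(meta)))
    meta$start <- NA_integer_
    meta$end <- NA_integer_
    for (k in seq_len(n_tandem_pairs)) {
      tr <- truth[[k]]
      i1 <- match(tr$leaf1, meta$leaf)
      i2 <- match(tr$leaf2, meta$leaf)
      meta$scaffold[c(i1, i2)] <- tr$scaffold
      meta$start[i1] <- 1000L
      meta$end[i1] <- 1900L
      meta$start[i2] <- 1900L + tr$gap_bp
      meta$end[i2] <- 2800L + tr$gap_bp
    }
    truth <- if (length(truth)) do.call(rbind, truth) else {
      data.frame(leaf1 = character(), leaf2 = character(),
                 scaffold = character(), gap_bp = integer(),
                 stringsAsFactors = FALSE)
    }
    list(gt = gene_tree_info(tree, meta), truth = truth)
  })
}
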