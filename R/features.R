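# Per-protein functional annotation: catalytic-triad scan on an alignment
# anchored to a chymotrypsin-numbering reference, secretion/membrane flags
# from external predictor tables, and exon structure of placed domains.

#' Catalytic-triad specification
#'
#' Serine proteases of the trypsin fold require a His/Asp/Ser catalytic
#' triad; by convention the sites are numbered on chymotrypsin as H-57,
#' D-102 and S-195. The scan needs an explicit reference sequence inside
#' the alignment that carries this numbering.
#'
#' @param reference_id Identifier of the reference sequence in the MSA.
#' @param positions The three residue numbers on the ungapped reference
#'   (strictly increasing).
#' @param required_residues One-letter amino acids required at each site.
#' @return An object of class `triad_spec`.
#' @export
triad_spec <- function(reference_id, positions = c(57L, 102L, 195L),
                       required_residues = c("H", "D", "S")) {
  stopifnot(length(positions) == length(required_residues),
            all(diff(positions) > 0),
            all(toupper(required_residues) %in% LETTERS))
  structure(list(reference_id = reference_id,
                 positions = as.integer(positions),
                 required_residues = toupper(required_residues)),
            class = "triad_spec")
}

#' Scan an alignment for the catalytic triad
#'
#' Locates the alignment columns holding the reference's triad positions
#' (via the reference's ungapped coordinates) and tests every sequence for
#' the required residue at each column. Matching is case-insensitive; a gap
#' or any other residue fails the site. Conservative substitutions are
#' deliberately counted as failures: only the exact catalytic residue
#' letters pass.
#'
#' @param msa An aligned `Biostrings::AAStringSet` (equal widths), or a
#'   named character vector of aligned sequences, or a path to an aligned
#'   FASTA file.
#' @param spec A [triad_spec()].
#' @return Data frame with columns `protein_id`, `has_triad` and
#'   `missing_triad_sites` (comma-separated site numbers, empty when the
#'   triad is complete).
#' @examples
#' aln <- c(ref = "AH-DXS", p1 = "GH-DXS", p2 = "GH-DXA")
#' triad_scan(aln, triad_spec("ref", positions = c(2, 3, 5),
#'                            required_residues = c("H", "D", "S")))
#' @export
triad_scan <- function(msa, spec) {
  stopifnot(inherits(spec, "triad_spec"))
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    msa <- Biostrings::readAAStringSet(msa)
  }
  nm <- names(msa)
  seqs <- toupper(as.character(msa))
  names(seqs) <- nm
  if (is.null(names(seqs))) stop("alignment sequences must be named")
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences are not aligned (unequal widths)")
  }
  if (!spec$reference_id %in% names(seqs)) {
    stop("reference sequence '", spec$reference_id, "' not found in alignment")
  }
  ref <- strsplit(seqs[[spec$reference_id]], "", fixed = TRUE)[[1L]]
  ungapped_cols <- which(!ref %in% c("-", "."))
  if (length(ungapped_cols) < max(spec$positions)) {
    stop("reference sequence too short: has ", length(ungapped_cols),
         " residues, triad needs position ", max(spec$positions))
  }
  cols <- ungapped_cols[spec$positions]
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  site_mat <- chars[, cols, drop = FALSE]
  pass <- sweep(site_mat, 2L, spec$required_residues, FUN = "==")
  missing <- apply(pass, 1L, function(p) {
    paste(spec$positions[!p], collapse = ",")
  })
  data.frame(protein_id = names(seqs),
             has_triad = !nzchar(missing),
             missing_triad_sites = missing,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a SignalP v4.1 short-format table
#'
#' @param path Path to the predictor's short output (comment lines start
#'   with `#`; the 10th field is the Y/N D-score decision).
#' @return Data frame with columns `protein_id` and `has_signal_peptide`.
#' @export
read_signalp <- function(path) {
  lines <- readLines(path)
  idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(idx) == 0L) {
    return(data.frame(protein_id = character(),
                      has_signal_peptide = logical()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stop("unparseable SignalP line ", idx[which(nf < 10L)[1L]],
         ": expected at least 10 fields")
  }
  dec <- vapply(fields, `[`, character(1), 10L)
  if (!all(dec %in% c("Y", "N"))) {
    bad <- idx[which(!dec %in% c("Y", "N"))[1L]]
    stop("unparseable SignalP line ", bad, ": decision field is not Y/N")
  }
  data.frame(protein_id = vapply(fields, `[`, character(1), 1L),
             has_signal_peptide = dec == "Y",
             stringsAsFactors = FALSE)
}

#' Read a TMHMM v2.0 short-format table
#'
#' @param path Path to the predictor's one-line-per-protein short output
#'   (`name len=... ExpAA=... PredHel=N Topology=...`).
#' @return Data frame with columns `protein_id`, `n_tm_helices`, `has_tm`.
#' @export
read_tmhmm <- function(path) {
  lines <- readLines(path)
  idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(idx) == 0L) {
    return(data.frame(protein_id = character(), n_tm_helices = integer(),
                      has_tm = logical()))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  hel <- vapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    ph <- grep("^PredHel=", f, value = TRUE)
    if (length(ph) != 1L) {
      stop("unparseable TMHMM line ", idx[k], ": missing PredHel field")
    }
    v <- suppressWarnings(as.integer(sub("^PredHel=", "", ph)))
    if (is.na(v)) stop("unparseable TMHMM line ", idx[k],
                       ": non-integer PredHel value")
    v
  }, integer(1))
  data.frame(protein_id = vapply(fields, `[`, character(1), 1L),
             n_tm_helices = hel,
             has_tm = hel > 0L,
             stringsAsFactors = FALSE)
}

#' Combine signal-peptide and transmembrane predictor tables
#'
#' Proteins absent from a table default to `FALSE` with a warning, matching
#' the convention that predictors only report what they were run on.
#'
#' @param signalp_path,tmhmm_path Paths to the predictor short outputs.
#' @param protein_ids Optional identifiers defining the output universe;
#'   defaults to the union of proteins seen in either table.
#' @return Data frame with columns `protein_id`, `has_signal_peptide`,
#'   `has_tm`.
#' @export
read_predictor_tables <- function(signalp_path, tmhmm_path,
                                  protein_ids = NULL) {
  sp <- read_signalp(signalp_path)
  tm <- read_tmhmm(tmhmm_path)
  ids <- protein_ids %||% sort(unique(c(sp$protein_id, tm$protein_id)))
  miss_sp <- setdiff(ids, sp$protein_id)
  miss_tm <- setdiff(ids, tm$protein_id)
  if (length(miss_sp)) {
    warning(length(miss_sp), " protein(s) absent from SignalP table; ",
            "defaulting has_signal_peptide to FALSE", call. = FALSE)
  }
  if (length(miss_tm)) {
    warning(length(miss_tm), " protein(s) absent from TMHMM table; ",
            "defaulting has_tm to FALSE", call. = FALSE)
  }
  data.frame(protein_id = ids,
             has_signal_peptide = ids %in% sp$protein_id[sp$has_signal_peptide],
             has_tm = ids %in% tm$protein_id[tm$has_tm],
             stringsAsFactors = FALSE)
}

#' Read gene models from GFF3 into a CDS segment table
#'
#' Parses a GFF3 file (via `rtracklayer`) and extracts CDS segments grouped
#' by parent transcript, ordered in transcription order (ascending genomic
#' start on the plus strand, descending on the minus strand).
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `tx` (transcript identifier), `seqid`,
#'   `start`, `end`, `strand`, in transcription order within transcript.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    return(data.frame(tx = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  parent <- vapply(cds$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1))
  out <- data.frame(tx = parent,
                    seqid = as.character(cds$seqnames),
                    start = cds$start, end = cds$end,
                    strand = as.character(cds$strand),
                    stringsAsFactors = FALSE)
  .order_cds(out)
}

.order_cds <- function(cds) {
  sgn <- ifelse(cds$strand == "-", -1L, 1L)
  out <- cds[order(cds$tx, sgn * cds$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cds_for <- function(cds, tx) cds[cds$tx == tx, , drop = FALSE]

#' Count coding exons spanned by each placed domain
#'
#' Maps each domain's amino-acid span onto the coding sequence of its gene
#' model and counts the CDS segments that contain more than `overhang_nt`
#' nucleotides of the domain's coding span. A domain that reaches into a
#' neighbouring exon by `overhang_nt` or fewer nucleotides is treated as
#' encoded by a single exon; the count is never below 1. Because the walk
#' follows CDS segments in transcription order, plus- and minus-strand
#' genes behave identically.
#'
#' @param cds CDS segment table from [read_gene_models()] (or a GFF3 path).
#' @param domains Placed-domain data frame with columns `protein_id`,
#'   `family`, `start`, `end` (amino acids), e.g. from [placed_domains()].
#' @param tx_map Optional named character vector mapping protein identifier
#'   to transcript identifier; defaults to the identity mapping.
#' @param overhang_nt Overhang tolerance in nucleotides (default 10).
#' @return `domains` with an added integer column `n_exons` (NA for
#'   proteins without a gene model, which are reported with a warning).
#' @export
domain_exon_mapping <- function(cds, domains, tx_map = NULL,
                                overhang_nt = 10L) {
  if (is.character(cds) && length(cds) == 1L) cds <- read_gene_models(cds)
  stopifnot(overhang_nt >= 0)
  n_exons <- rep(NA_integer_, nrow(domains))
  missing_model <- character()
  for (i in seq_len(nrow(domains))) {
    p <- domains$protein_id[i]
    tx <- unname(tx_map[p] %||% p)
    if (is.na(tx)) tx <- p
    segs <- .cds_for(cds, tx)
    if (nrow(segs) == 0L) {
      missing_model <- c(missing_model, p)
      next
    }
    widths <- segs$end - segs$start + 1L
    cum <- cumsum(widths)
    nt1 <- 3L * (domains$start[i] - 1L) + 1L
    nt2 <- 3L * domains$end[i]
    if (nt2 > cum[length(cum)]) {
      stop("domain span ", domains$start[i], "-", domains$end[i],
           " on protein ", p, " exceeds coding length ",
           cum[length(cum)] %/% 3L, " aa")
    }
    lo <- c(1L, head(cum, -1L) + 1L)
    ov <- pmax(0L, pmin(nt2, cum) - pmax(nt1, lo) + 1L)
    n_exons[i] <- max(1L, sum(ov > overhang_nt))
  }
  if (length(missing_model)) {
    warning("no gene model for protein(s): ",
            paste(unique(missing_model), collapse = ", "), call. = FALSE)
  }
  domains$n_exons <- n_exons
  domains
}

#' Detect intronless genes
#'
#' Returns the proteins whose transcript is encoded by exactly one CDS
#' segment, the signature expected of recent retrotransposition.
#'
#' @param cds CDS segment table from [read_gene_models()] (or a GFF3 path).
#' @param protein_ids Optional identifiers to restrict the result to.
#' @param tx_map Optional protein-to-transcript mapping (named character
#'   vector); defaults to identity.
#' @return Sorted character vector of intronless protein identifiers.
#' @export
detect_intronless <- function(cds, protein_ids = NULL, tx_map = NULL) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
    cds <- read_gene_models(cds)
  }
  n_seg <- table(cds$tx)
  single_tx <- names(n_seg)[n_seg == 1L]
  if (is.null(tx_map)) {
    prots <- single_tx
  } else {
    prots <- names(tx_map)[tx_map %in% single_tx]
  }
  if (!is.null(protein_ids)) prots <- intersect(protein_ids, prots)
  sort(prots)
}

#' Assemble the per-protein feature report
#'
#' Joins triad status, predictor flags, intronless status and scaffold of
#' origin into one table, one row per tryptome protein.
#'
#' @param archs Tryptome architectures (list of [architecture()]).
#' @param triad Data frame from [triad_scan()] (optional).
#' @param predictors Data frame from [read_predictor_tables()] (optional).
#' @param cds CDS segment table (optional; supplies `intronless` and
#'   `scaffold`).
#' @param tx_map Optional protein-to-transcript mapping.
#' @return Data frame with one row per protein.
#' @export
feature_report <- function(archs, triad = NULL, predictors = NULL,
                           cds = NULL, tx_map = NULL) {
  ids <- vapply(archs, function(a) a$protein_id, character(1))
  out <- data.frame(protein_id = unname(ids), stringsAsFactors = FALSE)
  if (!is.null(triad)) {
    i <- match(out$protein_id, triad$protein_id)
    out$has_triad <- triad$has_triad[i]
    out$missing_triad_sites <- triad$missing_triad_sites[i]
  }
  if (!is.null(predictors)) {
    i <- match(out$protein_id, predictors$protein_id)
    out$has_signal_peptide <- predictors$has_signal_peptide[i]
    out$has_tm <- predictors$has_tm[i]
  }
  if (!is.null(cds)) {
    intronless <- detect_intronless(cds, tx_map = tx_map)
    out$intronless <- out$protein_id %in% intronless
    tx <- if (is.null(tx_map)) out$protein_id else {
      unname(tx_map[out$protein_id])
    }
    out$scaffold <- vapply(tx, function(t) {
      s <- .cds_for(cds, t)
      if (nrow(s)) s$seqid[1L] else NA_character_
    }, character(1))
  }
  out
}
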