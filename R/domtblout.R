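# HMMER3 per-domain tabular output ("domtblout") is whitespace-delimited with
# 22 fixed fields followed by a free-text description. hmmscan and hmmsearch
# swap the roles of target and query (profile vs sequence), so the parser
# takes the program as an argument and maps columns accordingly.

.domtbl_columns <- function(program) {
  # index of each quantity among the 22 fixed fields
  if (program == "hmmscan") {
    list(family = 1L, family_acc = 2L, hmm_len = 3L,
         protein_id = 4L, protein_len = 6L)
  } else { # hmmsearch
    list(protein_id = 1L, protein_len = 3L,
         family = 4L, family_acc = 5L, hmm_len = 6L)
  }
}

#' Parse an HMMER3 per-domain table (domtblout)
#'
#' Reads the tabular per-domain output written by `hmmscan --domtblout` or
#' `hmmsearch --domtblout` into a data frame of domain hits. Comment lines
#' (starting with `#`) are skipped and data-row order is preserved.
#'
#' @param path Path to a domtblout file.
#' @param program Which HMMER program wrote the file: `"hmmscan"` (proteins
#'   as queries against profiles; the default, matching a Pfam-A scan of a
#'   proteome) or `"hmmsearch"` (profiles as queries against proteins).
#'
#' @return A data frame with one row per domain hit and columns
#'   `protein_id`, `family`, `family_acc`, `protein_len`, `hmm_len`,
#'   `full_evalue` (full-sequence E-value), `i_evalue` (independent,
#'   domain-specific E-value), `hmm_start`/`hmm_end` (profile coordinates)
#'   and `ali_start`/`ali_end` (alignment coordinates on the protein,
#'   1-based inclusive amino acids).
#' @examples
#' hits <- sim_domain_hits(n_proteins = 3, n_decoys = 0, seed = 1)$hits
#' f <- tempfile(fileext = ".domtblout")
#' write_domtblout(hits, f)
#' parse_domtblout(f)[1:3, c("protein_id", "family", "ali_start", "ali_end")]
#' @seealso [write_domtblout()], [build_architectures()]
#' @export
parse_domtblout <- function(path, program = c("hmmscan", "hmmsearch")) {
  program <- match.arg(program)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(.empty_hits())
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 22L)) {
    bad <- idx[which(nf < 22L)[1L]]
    stop("malformed domtblout row at line ", bad,
         ": expected at least 22 fields, got ", nf[which(nf < 22L)[1L]])
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:22))
  cols <- .domtbl_columns(program)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- idx[which(is.na(v))[1L]]
      stop("malformed domtblout row at line ", bad,
           ": non-numeric value in ", what, " column")
    }
    v
  }
  hits <- data.frame(
    protein_id  = m[, cols$protein_id],
    family      = m[, cols$family],
    family_acc  = m[, cols$family_acc],
    protein_len = as.integer(num(cols$protein_len, "sequence length")),
    hmm_len     = as.integer(num(cols$hmm_len, "profile length")),
    full_evalue = num(7L, "full-sequence E-value"),
    i_evalue    = num(13L, "independent E-value"),
    hmm_start   = as.integer(num(16L, "hmm from")),
    hmm_end     = as.integer(num(17L, "hmm to")),
    ali_start   = as.integer(num(18L, "ali from")),
    ali_end     = as.integer(num(19L, "ali to")),
    stringsAsFactors = FALSE
  )
  bad <- which(hits$ali_start > hits$ali_end | hits$hmm_start > hits$hmm_end |
                 hits$full_evalue <= 0 | hits$i_evalue <= 0)
  if (length(bad)) {
    stop("malformed domtblout row at line ", idx[bad[1L]],
         ": inverted coordinates or non-positive E-value")
  }
  hits
}

.empty_hits <- function() {
  data.frame(protein_id = character(), family = character(),
             family_acc = character(), protein_len = integer(),
             hmm_len = integer(), full_evalue = numeric(),
             i_evalue = numeric(), hmm_start = integer(),
             hmm_end = integer(), ali_start = integer(),
             ali_end = integer(), stringsAsFactors = FALSE)
}

#' Write domain hits as an HMMER3 domtblout file
#'
#' Serialises a hit table (as returned by [parse_domtblout()] or
#' [sim_domain_hits()]) back into the HMMER3 per-domain tabular dialect, so
#' that generated fixtures are read through exactly the same parser as real
#' scanner output. E-values are written with six significant digits; scores
#' and posterior accuracies are filled with placeholders.
#'
#' @param hits Data frame of hits (see [parse_domtblout()] for columns).
#' @param path Output path.
#' @param program Column orientation to write (`"hmmscan"` default).
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path, program = c("hmmscan", "hmmsearch")) {
  program <- match.arg(program)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con)
  if (nrow(hits) == 0L) return(invisible(path))
  acc <- hits$family_acc %||% "-"
  fmt_e <- function(x) sprintf("%.6g", x)
  # per (protein, family) domain numbering
  grp <- paste(hits$protein_id, hits$family, sep = "\r")
  of <- ave(seq_len(nrow(hits)), grp, FUN = length)
  no <- ave(seq_len(nrow(hits)), grp, FUN = seq_along)
  for (i in seq_len(nrow(hits))) {
    if (program == "hmmscan") {
      lead <- sprintf("%-20s %-10s %5d %-20s %-10s %5d",
                      hits$family[i], acc[i], hits$hmm_len[i],
                      hits$protein_id[i], "-", hits$protein_len[i])
    } else {
      lead <- sprintf("%-20s %-10s %5d %-20s %-10s %5d",
                      hits$protein_id[i], "-", hits$protein_len[i],
                      hits$family[i], acc[i], hits$hmm_len[i])
    }
    writeLines(sprintf(
      "%s %9s %6.1f %5.1f %3d %3d %9s %9s %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f %s",
      lead, fmt_e(hits$full_evalue[i]), 100.0, 0.1, no[i], of[i],
      fmt_e(hits$i_evalue[i]), fmt_e(hits$i_evalue[i]), 90.0, 0.1,
      hits$hmm_start[i], hits$hmm_end[i],
      hits$ali_start[i], hits$ali_end[i],
      hits$ali_start[i], hits$ali_end[i],
      0.95, "-"), con)
  }
  invisible(path)
}
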