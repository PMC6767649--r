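test_that("triad scan anchors sites on the reference and matches exact residues", {
  aln <- toy_triad_alignment()
  spec <- toy_triad_spec()
  res <- triad_scan(aln, spec)
  res <- res[match(names(aln), res$protein_id), ]
  expect_true(res$has_triad[res$protein_id == "ref"])
  expect_true(res$has_triad[res$protein_id == "good"])
  expect_equal(res$missing_triad_sites[res$protein_id == "noS"], "9")
  expect_equal(res$missing_triad_sites[res$protein_id == "noHD"], "3,6")
  # a gap at the site fails it
  expect_equal(res$missing_triad_sites[res$protein_id == "gapS"], "9")
  expect_false(res$has_triad[res$protein_id == "gapS"])
  # case-insensitive matching
  low <- c(ref = aln[["ref"]], lc = tolower(aln[["good"]]))
  expect_true(triad_scan(low, spec)$has_triad[2])
})

test_that("triad scan is invariant to all-gap columns and validates the reference", {
  aln <- toy_triad_alignment()
  spec <- toy_triad_spec()
  base <- triad_scan(aln, spec)
  # splice an all-gap column into every sequence
  gapped <- vapply(aln, function(s) {
    paste0(substr(s, 1, 4), "-", substr(s, 5, nchar(s)))
  }, character(1))
  expect_equal(triad_scan(gapped, spec), base)
  expect_error(triad_scan(aln, triad_spec("nope", c(3, 6, 9))),
               "not found")
  expect_error(triad_scan(aln, triad_spec("ref", c(3, 6, 90))),
               "too short")
})

test_that("predictor tables parse and absent proteins default to FALSE", {
  sp <- withr::local_tempfile()
  writeLines(c(
    "# SignalP-4.1 euk predictions",
    "p1  0.5 22 0.6 22 0.7 10 0.55 0.70 Y 0.45 SignalP-noTM",
    "p2  0.1 12 0.1 12 0.2 10 0.11 0.12 N 0.45 SignalP-noTM"), sp)
  tm <- withr::local_tempfile()
  writeLines(c(
    "p1\tlen=300\tExpAA=0.1\tFirst60=0.0\tPredHel=0\tTopology=o",
    "p3\tlen=250\tExpAA=44\tFirst60=0.1\tPredHel=2\tTopology=o10-29i35-54o"),
    tm)
  expect_warning(
    expect_warning(
      pred <- read_predictor_tables(sp, tm, protein_ids = c("p1", "p2", "p3")),
      "SignalP"),
    "TMHMM")
  expect_equal(pred$has_signal_peptide, c(TRUE, FALSE, FALSE))
  expect_equal(pred$has_tm, c(FALSE, FALSE, TRUE))
  # round trip for generator-style tables with planted flags
  set.seed(3)
  ids <- sprintf("prot_%02d", 1:10)
  sp_flag <- sample(c(TRUE, FALSE), 10, replace = TRUE)
  tm_n <- sample(0:3, 10, replace = TRUE)
  writeLines(sprintf("%s 0.5 22 0.6 22 0.7 10 0.55 0.70 %s 0.45 net",
                     ids, ifelse(sp_flag, "Y", "N")), sp)
  writeLines(sprintf("%s len=300 ExpAA=1 First60=0 PredHel=%d Topology=o",
                     ids, tm_n), tm)
  pred2 <- read_predictor_tables(sp, tm)
  pred2 <- pred2[match(ids, pred2$protein_id), ]
  expect_equal(pred2$has_signal_peptide, sp_flag)
  expect_equal(pred2$has_tm, tm_n > 0)
  # unparseable lines name the line number
  writeLines(c("p1 ok-not-really"), sp)
  expect_error(read_signalp(sp), "line 1")
  writeLines(c("p1 len=300 ExpAA=1"), tm)
  expect_error(read_tmhmm(tm), "line 1")
})

test_that("exon counting honours the 10-nt overhang boundary on both strands", {
  g <- sim_gff(n_intronless = 0, n_multiexon = 8, seed = 2,
               path = withr::local_tempfile(fileext = ".gff3"))
  cds <- read_gene_models(g$gff)
  dom <- data.frame(protein_id = g$truth$protein_id, family = "planted",
                    start = g$truth$domain_start, end = g$truth$domain_end,
                    stringsAsFactors = FALSE)
  mapped <- domain_exon_mapping(cds, dom)
  expect_equal(mapped$n_exons, g$truth$expected_exons)
  # 8-nt overhang -> one exon; 11-nt -> two
  expect_true(all(mapped$n_exons[g$truth$overhang_nt == 8] == 1L))
  expect_true(all(mapped$n_exons[g$truth$overhang_nt == 11] == 2L))
  # reverse-strand mirrors call identically to forward-strand twins
  for (ov in c(8L, 11L)) {
    calls <- split(mapped$n_exons[g$truth$overhang_nt == ov],
                   g$truth$strand[g$truth$overhang_nt == ov])
    expect_equal(unique(calls$`+`), unique(calls$`-`))
  }
  # counts are monotone non-increasing in the overhang tolerance
  for (ov in c(0L, 5L, 10L, 12L, 50L)) {
    m2 <- domain_exon_mapping(cds, dom, overhang_nt = ov)
    if (ov > 0L) expect_true(all(m2$n_exons <= prev$n_exons))
    prev <- m2
  }
  # a domain fully inside exon 1 is single-exon regardless
  dom1 <- transform(dom[1, ], start = 4L, end = 30L)
  expect_equal(domain_exon_mapping(cds, dom1)$n_exons, 1L)
  # out-of-range spans error; missing models warn
  expect_error(domain_exon_mapping(cds, transform(dom[1, ], end = 5000L)),
               "exceeds coding length")
  expect_warning(
    domain_exon_mapping(cds, transform(dom[1, ],
                                       protein_id = "ghost")),
    "no gene model")
})

test_that("intronless detection recovers exactly the planted single-CDS genes", {
  g <- sim_gff(n_intronless = 3, n_multiexon = 5, seed = 4,
               path = withr::local_tempfile(fileext = ".gff3"))
  cds <- read_gene_models(g$gff)
  found <- detect_intronless(cds)
  expect_setequal(found, g$truth$protein_id[g$truth$intronless])
  # a multi-exon gene is never returned
  expect_false(any(g$truth$protein_id[!g$truth$intronless] %in% found))
  # restriction to a protein subset
  sub <- g$truth$protein_id[g$truth$intronless][1]
  expect_equal(detect_intronless(cds, protein_ids = sub), sub)
})
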