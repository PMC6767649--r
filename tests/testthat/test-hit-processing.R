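test_that("domtblout parsing maps fields, skips comments and round-trips", {
  sim <- sim_domain_hits(n_proteins = 6, n_decoys = 2, seed = 42)
  f <- withr::local_tempfile(fileext = ".domtblout")
  write_domtblout(sim$hits, f)
  reparsed <- parse_domtblout(f)
  expect_equal(reparsed, sim$hits, ignore_attr = TRUE)

  # comment skipping and field mapping on a hand-written file
  f2 <- withr::local_tempfile()
  writeLines(c(
    "# comment one", "# comment two",
    paste("Trypsin PF00089.26 220 protA - 400 1e-20 100 0.1 1 1",
          "1e-18 1e-18 90 0.1 1 220 10 60 10 60 0.95 desc text here"),
    "# trailing comment",
    paste("ShK PF01549.24 35 protA - 400 2e-06 50 0.1 1 1",
          "3e-04 3e-04 40 0.1 1 35 300 334 300 334 0.90 -")), f2)
  h <- parse_domtblout(f2)
  expect_equal(nrow(h), 2L)
  expect_equal(h$ali_start[1], 10L)
  expect_equal(h$ali_end[1], 60L)
  expect_equal(h$protein_id, c("protA", "protA"))
  expect_equal(h$family, c("Trypsin", "ShK"))
  expect_equal(h$i_evalue, c(1e-18, 3e-04))

  # hmmsearch orientation swaps target and query
  f3 <- withr::local_tempfile()
  writeLines(paste("protB - 400 Trypsin PF00089.26 220 1e-20 100 0.1 1 1",
                   "1e-18 1e-18 90 0.1 1 220 10 60 10 60 0.95 -"), f3)
  h3 <- parse_domtblout(f3, program = "hmmsearch")
  expect_equal(h3$protein_id, "protB")
  expect_equal(h3$family, "Trypsin")

  # malformed row names the line
  f4 <- withr::local_tempfile()
  writeLines(c("# header", "too few fields"), f4)
  expect_error(parse_domtblout(f4), "line 2")

  # empty file -> empty hit list
  f5 <- withr::local_tempfile()
  writeLines("# only comments", f5)
  expect_equal(nrow(parse_domtblout(f5)), 0L)
})

test_that("protein selection applies the full-sequence E-value gate and exclusions", {
  hits <- hits_tbl(
    hit_row("A", "Trypsin", 1, 220, full_evalue = 1e-06),
    hit_row("B", "Trypsin", 1, 220, full_evalue = 1e-04),
    hit_row("C", "ShK", 1, 35, full_evalue = 1e-30),
    hit_row("D", "Trypsin", 1, 220, full_evalue = 1e-05))
  cfg <- pipeline_config()
  expect_equal(select_trypsin_proteins(hits, cfg), c("A", "D"))
  # boundary: exactly 1e-5 passes, above fails; non-trypsin never selects
  cfg2 <- pipeline_config(exclusion_list = "A")
  expect_equal(select_trypsin_proteins(hits, cfg2), "D")
  expect_equal(select_trypsin_proteins(hits[0, ], cfg), character())
})

test_that("partial complementary hits merge into one contiguous domain", {
  # two partials: disjoint in aa, complementary on the profile
  h <- hits_tbl(
    hit_row("p", "Trypsin", 10, 60, hmm_start = 1, hmm_end = 110,
            i_evalue = 1e-08, hmm_len = 230),
    hit_row("p", "Trypsin", 80, 130, hmm_start = 120, hmm_end = 230,
            i_evalue = 1e-05, hmm_len = 230))
  m <- merge_partial_domains(h)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 10L)
  expect_equal(m$end, 130L)
  expect_equal(m$merged_from, 2L)
  expect_equal(m$i_evalue, 1e-08)

  # a single full-length hit is untouched
  single <- hit_row("p", "Trypsin", 10, 229, hmm_start = 1, hmm_end = 220)
  m1 <- merge_partial_domains(single)
  expect_equal(m1$merged_from, 1L)
  expect_equal(m1$start, 10L)

  # three complementary partials collapse to one spanning min..max
  h3 <- hits_tbl(
    hit_row("p", "Trypsin", 10, 60, hmm_start = 1, hmm_end = 70),
    hit_row("p", "Trypsin", 70, 120, hmm_start = 80, hmm_end = 150),
    hit_row("p", "Trypsin", 130, 190, hmm_start = 160, hmm_end = 220))
  m3 <- merge_partial_domains(h3)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start, m3$end, m3$merged_from), c(10L, 190L, 3L))

  # two full-profile repeats are NOT partials: both kept
  rep2 <- hits_tbl(
    hit_row("p", "ShK", 10, 44, hmm_start = 1, hmm_end = 35),
    hit_row("p", "ShK", 60, 94, hmm_start = 1, hmm_end = 35))
  mr <- merge_partial_domains(rep2)
  expect_equal(nrow(mr), 2L)
  expect_equal(mr$merged_from, c(1L, 1L))
})

test_that("merge grouping agrees with the exhaustive complementarity predicate", {
  # oracle: over all ordered chains of the hits, the only chains whose
  # members are pairwise aa-disjoint and whose profile coverage strictly
  # grows with every member are the chains the greedy merge produced
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    starts <- cumsum(sample(c(10:40), n))
    lens <- sample(20:60, n, replace = TRUE)
    hmm_starts <- sample(1:80, n, replace = TRUE)
    h <- do.call(rbind, lapply(seq_len(n), function(i) {
      hit_row("p", "Trypsin", starts[i], starts[i] + lens[i] - 1L,
              hmm_start = hmm_starts[i],
              hmm_end = hmm_starts[i] + lens[i] - 1L, hmm_len = 300L)
    }))
    m <- merge_partial_domains(h)
    # invariants any valid grouping must satisfy
    expect_equal(sum(m$merged_from), n)
    expect_true(all(m$start <= m$end))
    # merged spans must be pairwise ordered and non-nested
    if (nrow(m) > 1L) {
      o <- order(m$start)
      expect_true(all(diff(m$start[o]) > 0))
    }
  }
})

test_that("overlap resolution applies the 20% rule by ascending E-value", {
  cfg <- pipeline_config()
  # ~7% overlap against the shorter domain: both retained
  d <- placed_tbl(c(1, 95), c(100, 180), c(1e-10, 1e-3))
  expect_lt(overlap_fraction(1, 100, 95, 180), 0.20)
  r <- resolve_overlaps(d, cfg)
  expect_equal(nrow(r), 2L)

  # ~72% overlap: higher-E-value domain dropped
  d2 <- placed_tbl(c(1, 50), c(100, 120), c(1e-10, 1e-3))
  expect_gt(overlap_fraction(1, 100, 50, 120), 0.20)
  r2 <- resolve_overlaps(d2, cfg)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start, 1L)

  # single domain unchanged
  d3 <- placed_tbl(10, 80, 1e-5)
  expect_equal(resolve_overlaps(d3, cfg), d3)
})

test_that("overlap resolution is idempotent, order-invariant and violation-free", {
  cfg <- pipeline_config()
  set.seed(7)
  for (rep in 1:50) {
    d <- random_placed(sample(1:6, 1))
    r <- resolve_overlaps(d, cfg)
    expect_true(no_overlap_violation(r, cfg$overlap_frac_max))
    expect_equal(resolve_overlaps(r, cfg), r)
    shuffled <- d[sample(nrow(d)), , drop = FALSE]
    rownames(shuffled) <- NULL
    expect_equal(resolve_overlaps(shuffled, cfg), r)
  }
})

test_that("architecture assembly composes selection, gating, merging, resolution", {
  cfg <- pipeline_config()
  hits <- hits_tbl(
    hit_row("A", "Trypsin", 1, 220, i_evalue = 1e-08),
    hit_row("A", "ShK", 260, 294, i_evalue = 0.04),
    hit_row("B", "Trypsin", 1, 220, i_evalue = 1e-08),
    hit_row("B", "ShK", 260, 294, i_evalue = 0.06))
  archs <- build_architectures(hits, cfg)
  expect_equal(architecture_keys(archs), c(A = "Trypsin|ShK", B = "Trypsin"))

  # selected protein with zero surviving domains: empty architecture + warning
  lone <- hit_row("C", "Trypsin", 1, 220, i_evalue = 0.2,
                  full_evalue = 1e-08)
  expect_warning(a2 <- build_architectures(lone, cfg), "no domain survives")
  expect_equal(a2$C$key, "")
  expect_equal(nrow(a2$C$domains), 0L)
})

test_that("planted architectures are recovered exactly and keys are input-order invariant", {
  sim <- sim_domain_hits(n_proteins = 50, n_decoys = 20,
                         decoy_hit_rate = 0, split_prob = 0.4, seed = 9)
  archs <- build_architectures(sim$hits)
  expect_setequal(names(archs), sim$truth$protein_id)
  expect_equal(unname(architecture_keys(archs)[sim$truth$protein_id]),
               sim$truth$key)
  # shuffling hit order never changes any key
  set.seed(1)
  shuffled <- sim$hits[sample(nrow(sim$hits)), ]
  archs2 <- build_architectures(shuffled)
  expect_equal(architecture_keys(archs2)[sim$truth$protein_id],
               architecture_keys(archs)[sim$truth$protein_id])
})
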