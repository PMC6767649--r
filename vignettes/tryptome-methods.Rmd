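---
title: "Methods: curating and dating a trypsin-domain proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and dating a trypsin-domain proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tryptome)
```

This vignette explains the models and procedures implemented by the
package, the tunable parameters and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the design
decisions taken where the underlying protocol leaves room.

## From profile-HMM hits to architectures

The input is HMMER3 per-domain tabular output (`domtblout`) for a proteome
scanned against Pfam-A profiles. Three thresholds govern curation, all
collected in `pipeline_config()`:

* `protein_evalue_max = 1e-5` — a protein joins the tryptome when some
  trypsin-family hit (`Trypsin` or `Trypsin_2` by default) has
  full-sequence E-value at or below this. The full-sequence E-value is
  used deliberately: the selection is phrased per protein, and the
  full-sequence statistic aggregates evidence over all domains of the
  family on that protein. The independent (domain-specific) E-value gates
  individual domains instead (below). Users who prefer a best-domain gate
  can study the sensitivity by filtering the hit table before
  `build_architectures()`.
* `domain_ievalue_max = 0.05` — every domain retained in an architecture,
  trypsin or associated, must have independent E-value at or below this.
* `overlap_frac_max = 0.20` — the pairwise overlap tolerance.

**Merging split hits.** Divergent or fragmented sequences often yield one
domain as several partial hits. Per protein and family, hits are chained
left to right and merged when they are (i) disjoint in amino-acid
coordinates and (ii) complementary on the profile: the union of profile
coverage strictly exceeds the coverage of the chain and of the candidate
hit alone. Condition (ii) is what distinguishes a split domain from a
genuine tandem repeat — two full-profile repeats add no mutual profile
coverage and are never merged. The merged domain spans min(start) to
max(end) and carries the minimum independent E-value of its parts.

**Overlap resolution.** Two domains overlapping by at most 20% of the
*shorter* domain's length are both kept; above that, the lower E-value
wins. The protocol states only the pairwise preference, so the package
makes the outcome deterministic with a greedy pass: domains are visited in
ascending independent E-value (ties: smaller start, then lexicographic
family name) and accepted unless they overlap an already-accepted domain by
more than the tolerance. The shorter-domain denominator is the symmetric
convention standard in domain-annotation practice, and makes the rule
strict for a short domain nested in a long one. Greedy resolution is
idempotent and input-order invariant, and the test suite verifies with an
exhaustive pairwise oracle that no retained pair ever violates the rule.

The architecture of a protein is its placed domains in N→C order; its
canonical key is the family names joined with `|` (e.g.
`Trypsin|ShK|ShK`). Keys are compared as ordered sequences with
multiplicity, because a rearranged architecture is biologically a distinct
protein organisation; `architecture_sharing(as_set = TRUE)` provides the
unordered sensitivity mode. Manual curation of gene models (pseudogenes,
duplicated predictions, transcript corrections) is represented only as an
exclusion list of protein identifiers — the package never re-derives it.

A selected protein can end with an empty architecture when no domain
survives the independent-E gate; this is reported with a warning rather
than dropped, since the protein did pass tryptome selection.

## Census statistics

`classify_tryptome()` partitions architectures by the presence of at least
one non-trypsin domain. `domain_abundance()` compares, for each associated
family, instance counts inside the tryptome against the remaining proteome
(`background = total − tryptome`), and sets two descriptive flags:
high abundance when the tryptome fraction is ≥ 10%, strong association at
≥ 15%. These thresholds are descriptive, not inferential — no test is
attached by default, matching their original use; an optional
hypergeometric enrichment p-value (`hypergeom = TRUE`) is available but
off by default. The background table should come from the same
post-processing as the tryptome (use `proteome_domain_table()` on the
full-proteome scan) so instance counting is consistent.

## Feature annotation

**Catalytic triad.** Serine-protease activity requires His-57, Asp-102 and
Ser-195 in chymotrypsin numbering. `triad_scan()` anchors those positions
on an explicit, user-supplied reference sequence inside the alignment (the
protocol does not fix a reference, so the package requires one), maps them
through the reference's ungapped coordinates to alignment columns, and
requires the exact residue letter (case-insensitive) in each column. Gaps
and conservative substitutions both fail: the call is about the canonical
catalytic chemistry, and any substitution at these positions is treated as
loss of the site. The scan is invariant to all-gap columns.

**Secretion and membrane flags** are consumed from SignalP v4.1 and TMHMM
v2.0 short-format tables, never re-predicted. Proteins absent from a table
default to `FALSE` with a warning.

**Exon structure.** `domain_exon_mapping()` converts a domain's amino-acid
span to coding-nucleotide coordinates (aa *i* occupies nt 3(i−1)+1 … 3i),
walks the transcript's CDS segments in transcription order, and counts the
segments containing more than `overhang_nt = 10` nt of the domain's coding
span (minimum one). The 10-nt tolerance means a domain poking marginally
across a junction still counts as single-exon — the signature used when
arguing for exon shuffling. Because the walk is in transcription order,
plus- and minus-strand genes behave identically; counts are monotone
non-increasing in the tolerance. `detect_intronless()` returns proteins
whose transcript has exactly one CDS segment, the expected footprint of
recent retrotransposition.

## Single-cell co-expression

The observation unit is whatever the input matrix rows are — cells or
metacells; the package is deliberately agnostic, and both modes are run
the same way. Expression uses a permissive threshold of `min_reads = 1`:
the question is co-occurrence, not level, and any stricter cutoff only
removes incidences (the expressing-cell count is monotone non-increasing
in the threshold, a tested invariant). For each gene, ubiquity *u* is the
number of expressing cells and *c* the number of those shared with at
least one other trypsin; 0 ≤ c ≤ u always, and the per-cell histogram
satisfies Σₖ k·hist[k] = Σ_g u_g. Both Pearson and Spearman correlations
of (u, c) are computed (Pearson reported by default; the underlying claim
is a monotone positive association, so the two should agree). With fewer
than three genes or constant vectors the correlation is flagged undefined
rather than computed.

## Phylostratigraphy

Origins are assigned under single-gain (Dollo) parsimony: the origin node
of a feature — a domain family, or an association `trypsin+X` meaning some
protein carries both — is the MRCA of the taxa possessing it. Age is the
ordinal *stratum rank*, the node's edge distance from the root (0 = root =
oldest): the underlying ages are ordinal node identities, not years, so
absolute dates are annotations only, and rank statistics are used
downstream. A feature present in an outgroup and any ingroup taxon dates
to the root. Maximal all-absent clades below the origin are reported as
inferred losses; when a feature needs many losses (default ≥ 3) it is
flagged as a possible repeated-gain case rather than resolved — parsimony
alone cannot distinguish the two, and known hard cases (WAP-like or
DIM-like patchy distributions) should be read from the flag, not the
origin. `age_relationship()` pairs each association's stratum with its
partner domain's stratum and computes tie-corrected Spearman correlation;
an association assigned an older stratum than its own domain is
impossible and raises an error naming the feature, as it signals
inconsistent presence data.

`assign_origin()` is verified against a brute-force oracle (deepest node
whose subtree contains all presence taxa) on hundreds of random trees of
up to 32 leaves.

## Gene-tree screens

`representation_clades()` formalises "clades with representatives of at
least N lineages from each required group". Lineages are counted as
distinct species within the group (a by-genus mode would be a
straightforward metadata change). Because the criterion is monotone —
any ancestor of a satisfying clade also satisfies it — the informative
clades are the *minimal* satisfying ones (no satisfying proper
descendant), which are pairwise disjoint; their count estimates the number
of independent ancestral lineages. The package returns those, matching
exhaustive clade enumeration on random trees in the tests. Node support
values are carried through but never used as filters.

`sister_same_scaffold()` restricts tandem-duplication candidates to
cherries (two-leaf sister clades) of the focal taxon sharing a scaffold;
the genomic gap is the distance between the nearest feature ends (0 for
overlapping features, `NA` when coordinates are missing — the pair is
still reported). Larger same-scaffold clades are deliberately not folded
into this call. `monophyly()` is the plain MRCA-subtree test, cross-checked
in the tests against both brute force and an independent library
implementation.

## What the generators emulate — and what they do not

The generators produce every input format the pipeline reads, with known
ground truth, deterministically per seed (byte-identical files):

* `sim_domain_hits()` plants a 72-protein catalog whose key frequencies
  mirror a sea-anemone-like tryptome (28 trypsin-only / 44 multi-domain,
  including a triple-trypsin protein), splits trypsin domains into
  complementary partials with configurable probability, and places decoys
  straddling *both* E-value thresholds: decoy proteins whose trypsin hit
  sits above the 1e-5 selection cutoff, and noise domains with log-uniform
  independent E-values across the 0.05 gate (noise landing below the gate
  is a genuine domain and joins the planted truth key).
* `sim_gff()` plants intronless genes and domains overhanging an exon
  junction by exactly 8 and exactly 11 nt — either side of the 10-nt
  rule — with every layout mirrored on the minus strand.
* `sim_cell_matrix()` plants the per-gene ubiquity/co-expression
  correlation directly: ubiquities are uniform on 10–100, the co-expressed
  fraction is Beta-distributed with its variance solved so the expected
  Pearson correlation equals the planted ρ (default 0.9), and the
  resulting degree sequence is realised exactly with co-expressing cells
  of size 2 + Geometric(0.55) and one solo cell per remaining incidence —
  giving the characteristic mode-at-one histogram with a decaying tail.
  Read counts of expressed entries are 1 + Geometric with mean 2: the
  analysis only thresholds presence, so magnitudes are free.
* `sim_presence()` evolves features by one gain at a known node followed
  by independent per-edge losses (default probability 0.2), discarding
  extinguished features.
* `sim_gene_tree()` grafts same-scaffold cherries with known gaps into a
  random multi-taxon gene tree.

They do **not** emulate realistic sequence content, read-level sampling
noise, metacell clustering, alignment error, or correlated loss; passing
the planted-truth tests therefore demonstrates correctness of the
*computations*, not robustness of the upstream predictions those
computations consume on real data.

## Problem sizes and numerical choices

The validation suite runs the overlap-rule property on 1,000 random
synthetic proteins of up to 6 domains, the origin oracle on 500 random
trees of up to 32 leaves, the clade-enumeration oracle on 500 random trees
of up to 20 leaves, the planted-correlation recovery over 100 seeds at 60
genes, and the null age-relationship over 200 replicates of 24 pairs —
sizes chosen so the whole suite completes in well under a minute while
exercising every boundary (exact-threshold E-values, 8/11-nt overhangs,
ties in E-value and partner ranking). Ties are always broken
deterministically (position, then lexicographic identifiers), so all
outputs are invariant to input order; equalities at thresholds are
inclusive (E-value *at* the cutoff passes; overlap of exactly 20% keeps
both domains; one read at `min_reads = 1` is expressed). Degenerate inputs
are defined rather than rejected: empty hit tables give empty results,
zero expressing cells give an empty histogram with the correlation flagged
undefined, and zero-presence features are skipped with a warning.

One statistical caveat is worth stating: with only 24 pairs, the null
distribution of Spearman's ρ has standard deviation ≈ 1/√23 ≈ 0.21, so
even truly independent ages produce |ρ| ≥ 0.3 in roughly 15% of
replicates. "No relationship" at this sample size is best read from the
mean |ρ| and the p-value, not from any single replicate.

## Orchestration

`run_all()` drives the stages from one YAML configuration (thresholds
mirror the defaults above and every one is overridable), writes per-stage
TSV reports and a `run.log`, and captures a `manifest.json` with the
configuration snapshot, input checksums, per-stage row counts and output
checksums. Warnings (e.g. proteins missing from predictor tables) are
logged, never fatal; missing inputs fail before any stage runs, naming the
key or file. Stage outputs are pure functions of inputs and configuration,
so checksums are stable across reruns — a tested property. The package's
interface is the R functions themselves (plus `scripts/acceptance.R` for
the headline numbers); no shell command-line wrapper is shipped, as the
intended users work from R.

## Known limitations

* The merge rule chains partials left-to-right; pathological interleaved
  splits of two same-family domains could in principle be mis-grouped,
  though they do not arise from the generators nor from typical scans.
* Dollo parsimony gives *minimum* ages; horizontal transfer, annotation
  gaps in sparse proteomes, or genuine repeated gains all bias origins
  rootward, and only the loss-count flag hints at the latter.
* Exact-key architecture sharing treats any rearrangement as novel;
  figure-specific poolings of related keys must be done by the caller.
* The exon mapping assumes consistent CDS phases and a single transcript
  per protein; alternative isoforms must be resolved to one transcript via
  `tx_map`.
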