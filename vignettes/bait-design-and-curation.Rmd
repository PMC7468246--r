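---
title: "Bait design and post-capture curation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bait design and post-capture curation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented in **coralbaits**: the
homology model every screen rests on, the meaning and defaults of the
tunable thresholds, what the synthetic-data generator does and does not
emulate, and the design choices made where published descriptions of
such pipelines leave the behavior open.

## The homology engine

Every filtering decision in both workflows — genome anchoring,
contaminant-transcript removal, bin assignment, symbiont screening,
barcode identity — reduces to scored local alignments. The engine is a
classic seeded search:

* **Seeding.** A subject is considered only if it shares an exact word
  with the query: 11 nt in nucleotide mode (both strands), 4 aa in
  amino-acid mode. A pair with no shared word cannot produce a hit.
* **Extension.** Seeded pairs get an affine-gap Smith–Waterman
  alignment (match +2, mismatch −3, gap of length $L$ costing
  $5 + 2L$ in nucleotide mode; BLOSUM62 with the same gap costs in
  amino-acid mode), computed inside a diagonal band of half-width 32
  around the union of seed diagonals. If the traced optimal path
  touches the band boundary the alignment is recomputed without the
  band, so banding is a pure optimization: the reported alignment is
  always the true optimum whenever the optimal alignment contains a
  seed word. This property is asserted against an independent,
  unseeded Smith–Waterman implementation on hundreds of random pairs
  in the test suite.
* **Statistics.** Raw scores $S$ convert to bit scores
  $(\lambda S - \ln K)/\ln 2$ and e-values $K m n e^{-\lambda S}$ with
  $m$ the query length and $n$ the *total* subject-set length.
  Nucleotide mode uses $\lambda = 0.625$, $K = 0.41$; amino-acid mode
  uses the published gapped BLOSUM62 values $\lambda = 0.267$,
  $K = 0.041$. The screens below depend only on score *ranking* and on
  thresholds quoted as identities, lengths and e-values, so any fixed
  consistent $(\lambda, K)$ pair preserves their semantics.
* **Identity** is measured over all alignment columns *including gap
  columns*, matching the "sequence similarity across an alignment
  length" reading used by the screens; one best alignment is reported
  per query × subject × strand (no multi-HSP sum statistics, no
  composition-based adjustment — the filters only consult single best
  local alignments).

A consequence worth knowing: the e-value criterion of the symbiont
screen (any hit at $e \le 10^{-4}$) is expected to fire on roughly
$10^{-4}$ chance matches per bait search. Across several thousand baits
a handful of short near-exact chance matches (≈ 20 bp) to the symbiont
references are therefore *correct* screen behavior, not false
positives; the acceptance script scores this screen against an
independent aligner applying the same thresholds rather than against
the planted-anomaly list alone.

## Design-time thresholds

| parameter | default | meaning |
|---|---|---|
| `min_taxa` | 6 | distinct scleractinian taxa required per orthogroup |
| `min_per_clade` | 2 | distinct taxa required from each of Robust and Complex (set 0 to relax one side; the even-representation goal argues for the both-clades reading) |
| `min_bit_score` | 50 | gene-model anchoring threshold (inclusive) |
| contaminant rule | ≥ 80% identity over ≥ 100 columns | removal of a transcript whose *single best* nucleotide hit is non-cnidarian |
| windows | 240, 200, 160, 120 bp | tried longest-first inside one exon span |
| bait length / offset | 120 / 20 bp | gives 7/5/3/1 tiled baits per window |
| symbiont mapping rule | ≥ 70% identity over ≥ 84 bait positions | 84 = ⌈0.70 × 120⌉; the length fraction is read bait-relative, as mapping semantics are read-relative |
| symbiont blast rule | e ≤ 1e-4 | any hit suffices |
| region prune | ≥ 3 removed, or ≤ 1 remaining | kills the whole region |
| `min_rc_match` | 21 nt | exact reverse-complementary run treated as self-hybridization risk; about one seed word plus extension under default nucleotide scoring |

All comparisons are inclusive at the stated boundary (≥ / ≤), and the
boundary cases are pinned by tests (80%/100 bp, 70%/84 bp, 98%/200 bp).

Window validity uses a **strict gap rule** by default (no gap in any
row of the window; a tolerant ≤ 50%-gaps-per-column mode is available,
under which gapped rows simply skip affected tiles). Among valid
windows of the longest feasible length, the window maximizing **mean
pairwise identity** over its columns wins (ties leftmost): conservation
is the natural proxy for capture efficiency across divergent taxa, and
the identity is computed from per-column character counts so the result
is invariant under row order.

**Exon projection.** Exon coordinates live on the reference gene-model
coding sequence; the gene model's amino-acid row is carried inside each
locus alignment, its residues inherit their exon, and insertion columns
inherit the preceding reference position's exon, so every projected
span is contiguous and windows can never cross an intron. Exon
boundaries inside a codon are rounded inward to whole codons
(conservative: a window never leaves its exon). By default one region
is designed per hosting exon (`multi_exon = TRUE`), reproducing the
several-regions-per-locus structure typical of exon-aware designs; a
single-best-region mode implements the longest-window → highest
identity → leftmost selection.

**Self-hybridization.** Two baits are a risk pair when one contains an
exact run of ≥ 21 nt reverse-complementary to a run in the other
(equivalently: bait $i$ and the reverse complement of bait $j$ share a
21-mer). Only the later bait of a pair is removed by default
(`resolution = "later"`): removing both discards capture capacity
without need; a `both` mode exists. Palindromic runs within a single
bait flag that bait. The screen is equivalent to a brute-force
all-pairs reverse-complement substring scan, which the tests assert.

**Screen order** is fixed — symbiont → region prune → dedup →
self-hybridization → final region re-check — and the re-check applies
the same region rule to the *cumulative* losses, so the region
invariant survives dedup and self-hybridization losses. Ledger counts
conserve: input = survivors + removals at every stage, and re-running
the cascade on its own output removes nothing.

## Post-capture curation

**Barcode QC.** Contigs shorter than 200 bp are ignored; a qualifying
hit needs ≥ 98% identity over ≥ 200 columns against the barcode
references. The qualifying hit with the highest contig coverage is the
sample's call. Other-taxon qualifying hits with coverage at least
100-fold lower are reported as disregarded cross-contamination — they
do not fail the sample. An other-taxon hit *above* that ratio, with the
expected taxon still on top, keeps the verdict `VERIFIED` but is
reported at `WARNING` severity: the 100-fold rule only licenses
disregarding hits below it, and failing the sample would be stricter
than the decision it encodes. Coverage comes from a user-supplied
per-contig table (assembler k-mer coverage or mapped-read depth — the
rule only needs ratios), since assembly is outside this package's
scope.

**Gene-tree curation** proceeds per locus: collapse internal branches
below 10% bootstrap support (contracted edge lengths are added to their
children, preserving path lengths); drop the locus whole when some
bipartition splits the copies of ≥ 2 multi-copy taxa — the signature of
a duplication predating the sampled taxa (Type II); apply the
contamination criteria; resolve Type I paralogs per taxon
(`.main` > `0.0` > untagged); then drop loci with < 3 scleractinian
taxa or below the parsimony-informative floor.

The contamination criteria need each tip's *observed* major clade.
Published pipelines determine this by eye; an algorithmic stand-in has
to read the same local signal a person does without inheriting the
pathologies of any particular tree shape. The package uses the **k
nearest other tips by patristic distance** (k = 3, including every tip
tied at the k-th distance) and makes a call only when their expected
clades are **unanimous**. Two alternatives were rejected: the smallest
enclosing clade with ≥ 3 tips systematically miscalls every member of a
clade that is small relative to its sister (the first informative
ancestor is dominated by the sister clade), and any simple-majority
variant inherits the same imbalance. Unanimity makes mixed
neighborhoods — tips of small or partly sampled groups, zones near the
root — *uninformative* rather than evidence, which is the conservative
direction for a removal rule. Patristic distances are root-invariant,
so no rooting step is needed. Criterion (a) removes the wrong-clade
copy of a multi-copy taxon whose copies disagree; (b) removes
wrong-clade single-copy tips; (c) removes tips whose pendant branch
exceeds 5× the median pendant length, computed on the pre-removal tree
so removals cannot interact. "Spurious topology" judgments are not
automated — a quarantine list excludes loci by id.

**Supermatrix.** Surviving loci are aligned (externally via `mafft`
when rows are not already equal-length), trimmed by a transparent
per-column census (columns with > 80% gaps removed — a deliberately
simple, versionless stand-in for heuristic trimmers), concatenated in
input order with `?` padding for absent taxa, and written as FASTA,
relaxed PHYLIP and a 1-based-inclusive partition file. Missing data
counts both `?` (absent locus) and `-` (alignment gap), the usual
convention for concatenated matrices, and is configurable. A column is
parsimony-informative when ≥ 2 non-missing states each occur in ≥ 2
rows; the census is matrix-wide and checked against an exhaustive
per-column oracle.

## The synthetic-data generator

`make_fixture_workspace()` emulates the full input universe at desk
scale. Coding sequences evolve along a fixed
((Robust),(Complex),outgroup) topology under an equal-rates
substitution model with no indels at coding positions; gap structure
comes only from lineage-specific exon presence. Defaults: 8 + 8 + 4
taxa, 60 loci of 120–400 codons, root-to-tip depth 0.3
substitutions/site, 10% of loci with a planted non-cnidarian member
(95% identity to a labelled database record), 10% with a symbiont
120-mer shared verbatim with a reference, 10% with a Type I paralog
pair, 2 deep-duplication loci, 3 misplaced gene-tree tips, 10% capture
dropout, and one barcode cross-contaminant at 1/150 of the true
coverage — small enough to run in minutes, large enough that every
filter fires. Exon maps break genes at codon boundaries
(p = 0.05/boundary) with a guaranteed ≥ 240 nt exon in 80% of loci so
all four window lengths are exercised.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: multiple substitution rates or
among-site rate variation, indels within exons, sequencing error,
assembly artifacts, chimeric contigs, incomplete lineage sorting
(gene trees match the species topology except where anomalies are
planted), and base-composition heterogeneity. Recovery statistics on
fixtures are a correctness check of the decision rules, not a
field-performance estimate.

Determinism: one integer seed fixes every draw; two runs from the same
seed and configuration produce byte-identical outputs (asserted in the
tests, external aligner included).

## Numerical and degenerate-input choices

* Alignment ties break deterministically: diagonal > up > left in the
  dynamic programme; best-hit order is bit score ↓, e-value ↑,
  identity ↓, subject id ↑.
* Ambiguity codes never count as matches and score as mismatches
  (`N` in nucleotide mode, `X` in amino-acid mode); baits containing
  `N` are never emitted.
* Back-translation refuses mismatched translations (naming the taxon
  and codon) rather than auto-correcting: a silent frame error would
  corrupt every downstream bait.
* Empty inputs are errors where silence would hide a broken pipeline
  (no orthogroups, empty FASTA, empty reference set) and empty results
  where emptiness is informative (no hits, no valid window).
* Coordinates are 0-based half-open everywhere internally; only the
  partition-file writer emits 1-based inclusive coordinates, as that
  dialect requires.

## Problem sizes used by the test suite

The suite validates the engine on 500+ random 40–80-mers against the
exhaustive oracle, runs the full pipeline on the default 20-taxon,
60-locus workspace (seed 42) for planted-anomaly recovery, uses a
6-locus workspace for determinism and orchestration tests, and checks
the matrix statistics on 100 random matrices — sizes chosen so the
whole suite completes in a few minutes on one core while every rule
still fires.

## Known limitations

* The bait-window "best region" criterion (mean pairwise identity) and
  the gap rule are explicit stand-ins for the unpublished internals of
  dedicated bait-design tools; they are documented, configurable, and
  deliberately simple.
* Translated (protein-vs-nucleotide) searches, multi-HSP statistics
  and composition-based score adjustment are not implemented; no
  screen here needs them.
* Thermodynamic duplex prediction is out of scope: the
  self-hybridization rule is an exact-run criterion, not a ΔG model.
* Tip removal under criterion (c) is per-tip; removing whole multi-tip
  clades as a unit is left to the quarantine list.
* Orthology inference, read processing, assembly and tree inference
  are consumed as inputs, not reimplemented.
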