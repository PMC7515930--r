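---
title: "Methods: comparative mitogenome statistics in mitocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome statistics in mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

`mitocomp` implements the comparative battery that descriptions of new
insect mitochondrial genomes report: per-partition nucleotide composition,
codon usage, gene architecture, tRNA base-pair quality, control-region
structure, and supermatrix construction. This vignette documents the
statistical definitions, the parameters that matter, the design choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## Coordinates, strands, and the genome model

A genome is the circular major-strand (J-strand) nucleotide sequence;
features carry 0-based half-open spans on that strand, with a feature
crossing the origin represented as exactly two spans (never a negative
coordinate). Half-open arithmetic makes junction gaps and wraparound sums
exact: for consecutive features the spacer is simply
`next_start − this_end`, and feature lengths plus signed gaps tile the
circle. GenBank's 1-based inclusive coordinates, `complement()` strands and
`join()` locations are converted at the I/O boundary only.

Characters outside `{A,C,G,T,N}` are rejected at parse time; `N` is never
counted in any numerator or denominator. Heterogeneous gene naming
(COI/COX1/cox1, 16S/rrnL, trnL2/trnL(UUR)) is normalized onto one canonical
37-symbol vocabulary; the leucine and serine tRNAs are disambiguated by
their anticodon when the name alone cannot decide (the anticodon's reverse
complement is the codon read, whose family — UUR/CUN or AGN/UCN — names the
gene). An unmappable name is kept, flagged non-canonical, and warned about;
it is never silently guessed. If no control region is annotated, the
largest unannotated gap adjacent to `rrnS` is labeled `AT_rich` with a
warning, reflecting its conserved position between `rrnS` and `trnI`.

## Composition statistics

For base counts A, T, G, C:

* AT% = 100·(A+T)/(A+T+G+C)
* AT-skew = (A−T)/(A+T)
* GC-skew = (G−C)/(G+C)

A zero denominator yields `NA`, rendered `"NA"` — never a fabricated 0.
Reported precision follows the field's convention (AT% to 1 decimal, skews
to 3); raw values are always retained and available (`raw = TRUE` in
`run_stats()`).

**Strand policy.** The whole-genome, tRNA, rRNA and A+T-rich partitions are
measured on the major strand; protein-coding partitions (pooled genes and
the three codon positions) are measured on each gene's sense strand,
concatenated, with terminal stop codons removed. This choice is forced by
the arithmetic of strand asymmetry: sense-strand pooling is the only
convention under which the pooled protein-coding AT-skew can be strongly
negative (a T-excess driven by N-strand genes) while the whole major strand
is A-biased. Codon-position subsequences are taken from complete codons
only; a trailing incomplete codon is ignored, and `strip_stop` removes the
final codon only when it is TAA or TAG under translation table 5.

## Codon usage

The invertebrate mitochondrial genetic code (NCBI table 5) is taken from
Biostrings, not re-typed: AGA/AGG encode serine (an 8-codon family),
TGA tryptophan, ATA methionine, and the stop set is {TAA, TAG}. RSCU uses
the standard Sharp–Li definition — observed count divided by the mean count
of the synonymous family — so within each family the values sum to the
family size; a family with zero total yields `NA`. "Absent codons" are
sense codons with pooled count zero across the gene set, terminal stops
excluded. Start codons are reported as found (canonical means ATN;
non-canonical starts are reported, never "corrected"); a gene whose length
is not a multiple of three is reported with a truncated stop (e.g. `"T--"`).
Amino-acid rankings break ties by the one-letter code, making output
deterministic.

## Architecture

Junctions are formed between features consecutive in major-strand start
order regardless of coding strand, including the wraparound junction.
Negative gaps are overlaps; when several features mutually overlap, the
pairwise gaps of consecutive pairs are reported without merging. The
control region's two flanking junctions are listed, but junctions touching
it are excluded from intergenic min/max statistics, which it would
otherwise dominate.

Gene order is compared to the ancestral insect arrangement after rotating
both orders to a common anchor, so the comparison is invariant to where the
circle was linearized. Differences are classified greedily: two exchanged
neighbours are one `adjacent_swap`; a single symbol whose removal aligns
everything else is one `translocation`; same-position strand differences
are `strand_flip`s; anything else is reported as `other` rather than
forced into a category. The classifier is intentionally simple — it is
meant for the near-ancestral orders of real insect mitogenomes (e.g. the
trnD/trnK swap), not as a rearrangement-distance algorithm, which is out of
scope.

## tRNA structures

The primary contract is classification *given* a structure: every pair is
assigned exactly one class — canonical (A-U, G-C), wobble (G-U, orientation
ignored), or a mismatch subtype (A-A, A-G, A-C, U-C, U-U, other) — and
counts are additionally broken down per arm, so either convention on which
stems to include can be audited. Published non-canonical pair totals depend
on the exact structures an external predictor emits, so they are not
reproducible from classification alone; the bundled folder exists to keep
the pipeline self-contained, clearly as a best-effort heuristic.

The folder is deterministic: it anchors a 7-nt anticodon loop (from the
given anticodon, or by scanning for the best 5-bp anticodon stem, ties
resolved towards the molecule's centre then leftmost), builds a 7-bp
acceptor stem from the molecule ends, then searches for the DHU arm (3–4 bp
starting 1–4 nt after the acceptor arm) and the TΨC arm (3–5 bp whose 3'
arm abuts the acceptor 3' arm, with placements one or two nt short tried
only if that fails). Stems admit canonical and G-U pairs plus at most
`max_mismatch` (default 1) mismatched positions. Ties between equally good
stems are broken towards canonical cloverleaf geometry (D-stem starting two
nt after the acceptor arm, ~8-nt D-loop, ~7-nt T-loop), then leftmost.
Arms that cannot be formed are listed in `incomplete_arms` — a 58-nt
molecule, like the shortest real mitochondrial tRNAs, is reported with an
incomplete TΨC arm rather than given an invented one.

Conservation across genomes uses global Needleman–Wunsch alignment with
match +1, mismatch −1, gap −2 and a diagonal-preferring traceback — chosen
for simplicity and reproducibility, and cross-checked in the tests against
an independent alignment implementation at identical scoring.

## Control-region features

All detectors return coordinates within the control-region string, so every
report re-extracts a substring that satisfies its own defining predicate
(self-verifying output); the tests assert exactly that.

* **T-stretches** formalize "a poly-T run with insertions": a maximal
  window whose first and last bases are T, with at most
  `max_interruptions` internal non-T bases (default 2) and length at least
  `min_len` (default 9). Nested windows are suppressed.
* **Stem-loops** are inverted repeats found by scanning every loop
  placement (loop 3–8 nt by default) and extending the arms while they
  pair. Pairing defaults to Watson–Crick with G-T available by flag, since
  published pairing conventions for control-region hairpins vary; an
  optional per-stem mismatch budget (default 0) exists for scanning noisy
  sequence, with the outermost pair always required to pair.
* **Tandem repeats** play the role an external repeat finder plays in most
  annotation pipelines, without replicating any particular tool's scoring.
  For each candidate period the sequence is compared against itself
  shifted by the period; maximal segments whose shifted identity stays
  above threshold (mismatch runs longer than `max(2, period/3)` are never
  absorbed, so arrays end at real boundaries) are scored against a
  majority consensus of their copies, and trimmed one period at a time
  while an end copy falls below the identity threshold. Overlapping calls,
  including period harmonics, are resolved by the highest copies ×
  identity, ties to the smaller period then leftmost. Defaults
  (`min_period = 5`, `max_period = 200`, `min_copies = 2`,
  `min_identity = 70`) span the repeat sizes reported for insect control
  regions while remaining configurable; on A+T-rich sequence the
  70%-identity floor deliberately admits weak short calls, which the
  scoring field lets the caller filter.
* **Conserved blocks** are found by ungapped seed-and-extend: exact k-mer
  seeds (default k = 8) shared by all species anchor per-species offsets —
  anchored at the occurrence agreeing best with the reference locally,
  since any particular k-mer recurs many times in A+T-rich sequence — and
  are extended while the mean per-column majority identity stays at or
  above `min_identity` (default 90). Overlapping candidates are resolved
  longest-first. Blocks are labeled `E1`, `E2`, … left to right.
* The canonical flanking motifs ("TATA" at the 5' end, "G(A)nT" at the 3'
  end) are simple presence scans over a 50-bp window; absence is reported
  as absence.

## Supermatrix construction

Per-gene alignment is out of scope (a well-solved external step); the
module consumes aligned FASTA. Concatenation records half-open partition
bounds that provably tile the matrix; taxa missing a gene are gap-filled.
The terminal stop-codon column triplet of an in-frame protein-coding
alignment is removed only when every taxon with non-gap characters there
carries TAA or TAG; otherwise the alignment is left unchanged with a
warning. Output formats are relaxed PHYLIP (untruncated names), NEXUS with
a charset block, and RAxML-style partition lines, each in a by-gene and a
by-codon-position scheme, since downstream partitioning practice varies.

## The synthetic-data generator

The generator exists so that every stage has exact ground truth. Two
design decisions follow from that goal:

* **Exact-count realization.** Base sampling apportions the exact counts
  implied by the target (AT fraction, AT-skew, GC-skew) by largest
  remainder and then permutes them; codon sampling apportions codon counts
  to the bias weights the same way. Realized composition therefore equals
  the target up to rounding, the manifest records realized truth rather
  than an approximation, and parameter-recovery statements (e.g. RSCU
  within ±0.05 of the bias-implied values at 30,000 codons) are properties
  of counting, not of sampling luck. Under iid draws at these sizes the
  worst-case deviation across 62 codons would routinely exceed that
  tolerance; exact-count realization is what makes the generator a usable
  oracle.
* **Plant-then-record.** The control region is built at its composition
  target, then planted features (T-stretch, stem-loop, tandem repeat,
  shared conserved block) overwrite their footprint, and the manifest
  records post-overwrite coordinates and sequences. Detection tests need
  exact truth, not targets.

Defaults emulate a typical grasshopper mitogenome: 15,850 bp; the
ancestral insect order with trnD/trnK swapped; whole-genome A+T ≈ 76%;
codon bias built from position-specific base weights (G-rich first
positions, T-rich second positions, extremely A+T-rich third positions),
which reproduces the characteristic codon-position composition profile; a
~1 kb control region whose base target (87.5% A+T) is set slightly above
the intended realized value (≈86.5%) to offset the planted features'
lower A+T content; tRNAs of 66 bp (58 bp for trnP, mirroring the shortest
real tRNA); and a 16-bp spacer at the trnS(UCN)/ND1 junction. The
generator emulates composition and architecture, **not** biological
sequence: its tRNAs are composition-matched random sequence (not foldable
cloverleaves), its protein-coding genes encode random peptides, its
amino-acid usage ranking follows the bias arithmetic rather than real
mitochondrial proteomes, and the whole-genome AT-skew of the default
genome is near zero rather than the A-excess of real J-strands, because a
single codon bias is shared by genes on both strands. Tests passing on
synthetic data therefore validate the statistics and detectors, not any
biological claim.

## Recovery criteria and problem sizes in the tests

The planted-feature battery runs 200 noiseless and 200 noisy replicates
(5% per-position mutation) on 560-bp control regions with detector
settings chosen once for the scan: T-stretches at `min_len = 9`,
`max_interruptions = 4`; stem-loops at `min_stem = 10` with mismatch
budget 3; tandem repeats over periods 5–40; blocks at `min_block = 20`,
`min_identity = 85`, `k = 6`. A plant counts as recovered when a detection
of its kind overlaps at least 60% of its footprint (80% in both species
for blocks); for tandem repeats the period must match exactly and, on
noiseless data, the copy number over the planted footprint must agree
within ±0.5 — under noise, coverage of ≥70% of the footprint is required
instead, since a mutated edge copy is legitimately trimmed. Property
tests elsewhere use 1,000 random sequences for skew antisymmetry, 30,000
codons for RSCU recovery, and a 37-gene fixture for the supermatrix; these
sizes keep each statement statistically meaningful at interactive run
times.

## Known limitations

* The heuristic folder assumes a standard cloverleaf geometry; it is not a
  thermodynamic or covariance-model predictor, and structures for
  strongly aberrant tRNAs should come from dedicated tools.
* The tandem-repeat detector does not replicate any published tool's
  alignment weights; counts on real control regions will differ from
  tool-specific published counts whose parameters are unstated.
* The gene-order classifier reports simple event types and falls back to
  `other`; it does not compute rearrangement distances.
* Conserved-block discovery is ungapped; blocks interrupted by indels are
  reported as separate blocks.
* Composition statistics treat `N` as missing; records with many
  ambiguous bases will have correspondingly reduced denominators.
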