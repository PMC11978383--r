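---
title: "Methods: pairwise whole-genome alignment manipulation in wgakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise whole-genome alignment manipulation in wgakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgakit)
```

## The problem

Whole-genome aligners emit pairwise alignments in three text formats
that describe the same object with incompatible coordinate dialects:
MAF (block-based, gapped rows, strand-relative 0-based starts), PAF
(12 tab-separated columns, query interval always on the forward strand,
base-level detail in an optional `cg:Z:` CIGAR tag) and UCSC Chain
(ungapped blocks linked by `(size, dt, dq)` gap triples, coordinates
strand-relative, no base-level detail). Comparative-genomics pipelines
routinely need to move between them, cut alignments to regions, compute
identity and divergence summaries, project several pairwise alignments
onto one reference, and call variants directly from alignment
signatures. `wgakit` implements all of this over one canonical
in-memory model so that each format's quirks are confined to its reader
and writer.

## The canonical model

Every format round-trips through `pairwise_block()`:

* the **target is always on the forward strand**; a record with a
  minus-strand target is normalized on input by reverse-complementing
  both rows and flipping the query strand. PAF and chain tooling keep
  the target forward by convention, and a single frame removes the
  case explosion in conversions;
* **all coordinates are 0-based half-open on the forward strand** of
  their sequence — including the query interval of a minus-strand
  alignment. Strand-relative offsets exist only at format boundaries
  (MAF row starts, chain query coordinates);
* base-level detail is a normalized **CIGAR** over `=`, `X`, `I`, `D`,
  `M` (no two adjacent runs of the same kind), optionally accompanied
  by the gapped row strings in target-forward column order.

`M` is kept as an opaque match-or-mismatch operation. It is split into
`=`/`X` only when bases are available (from carried rows or fetched
FASTA), and any computation that needs the distinction without bases —
match counting, identity, variant calling — raises an error rather than
guessing. Base comparison is case-insensitive and `N` against anything
(including `N`) counts as a mismatch column: deterministic and simple,
at the cost of over-counting mismatches in hard-masked sequence.

## Conversions and the one lossy edge

MAF ↔ PAF is lossless: rows are rebuilt from the CIGAR by walking it
over sequences fetched from the two genomes, and the CIGAR is rederived
from rows by column classification. Chain cannot represent mismatch
positions or the internal order of a mixed indel run — maximal
`=`/`X`/`M` runs become block sizes, a gap run contributes `dt`
(deleted target bases) and `dq` (inserted query bases) to a single
triple. Consequently:

* PAF → Chain → PAF preserves all coordinates exactly, but an `=`/`X`
  CIGAR comes back as `M` runs with indel runs in a canonical
  D-before-I order, and `nmatch` falls back to the summed block sizes;
* a second pass through the genomes (`chain_to_maf()`, then
  `maf_to_paf()`) restores `=`/`X` and the exact match count.

A chain must begin and end with an ungapped block, so a CIGAR with a
leading or trailing indel is trimmed into the coordinates with a
warning. Chain scores: a carried score is written as-is; otherwise the
match count when `=`/`X` resolution is available, else the summed block
sizes. A MAF `a score=0` line is treated as "score unknown" on read,
because that is exactly what the writer emits when no score is carried
and no scoring matrix is in scope.

## Indexing, extraction, chunking

The MAF index is a per-block TSV sidecar (`name, start, end,
byte_offset` of the `a` line, target forward coordinates), written
atomically. Per-block granularity keeps the sidecar tiny; sub-block
cuts are computed on demand by projecting alignment columns onto the
target (`project_column_to_target()`): a consuming column maps to the
coordinate it consumes, an insertion column anchors at the last
previously consumed base. Slicing keeps the columns whose projection
falls in the region, including insertion columns anchored at the last
in-region base. CLI region strings are 1-based inclusive (the samtools
convention); BED input is 0-based half-open.

Chunking splits blocks at column boundaries into runs of at most
`max_columns` columns, recomputing every row's strand-relative start
by the non-gap count consumed in text order — which is correct for
both strands precisely because MAF starts are strand-relative.
Concatenating chunk row texts reproduces the input exactly; a row left
without bases (a window inside a long deletion) is kept with size 0 so
downstream coordinate arithmetic stays continuous.

## Statistics

* **Per-block stats** count matches, mismatches, indel events and
  bases; `matches + mismatches + ins_bases + del_bases == columns` is
  an enforced identity. Gap-compressed identity is
  `matches / (matches + mismatches)`; overall identity divides by all
  columns.
* **Coverage** reduces the aligned intervals per sequence
  (union semantics, via `IRanges::reduce`), so duplicated or
  overlapping records never double-count.
* **Gap divergence** assigns every alignment column to the target
  window containing its projected position (1 Mb default window) and
  reports `(mismatch_cols + gap_cols) / aligned_cols` per window. The
  quantity has no universally fixed definition; this gap-inclusive
  reading is this package's definition, with `include_gaps = FALSE`
  giving the mismatch-only variant for comparison. Windows with no
  aligned columns report `NA` rather than 0 — absence of evidence is
  not zero divergence. Because assignment partitions columns, the
  window sums reproduce whole-alignment totals at any window size; the
  tests exercise this at 100 bp, 1 kb and 1 Mb.

## Pseudo-MAF and conservation

`pseudo_maf()` projects one pairwise alignment set per sample onto a
reference interval: one column per reference base, insertions relative
to the reference dropped, `-` for a deleted reference base, `*` for an
unaligned position (a deliberate distinction: deletion is an observed
difference, absence of alignment is missing data). Overlapping blocks
within a sample are resolved most-matches-wins with ties to input
order — deterministic and biased toward the better alignment.
Conservation counts, per position, the samples matching the reference
base. The default denominator is the total number of samples, so an
unaligned sample counts against conservation; `aligned_only = TRUE`
switches the denominator to the aligned count. Both readings are
useful and the choice is explicit, since no single formula is
standard.

## Variant calling and normalization

Calls are read directly off the column walk: `X` columns are SNPs,
maximal `I`/`D` runs are insertions/deletions anchored at the last
consumed target base, with the VCF fallback (anchor on the following
base, with a warning) for a run at the very start of an alignment.
Indels with run length at or above `sv_min_len` (default 50 bp, the
community convention — the length classes themselves carry no other
semantics here) are additionally tagged `SVTYPE`/`SVLEN`/`END`.
Consecutive `X` columns stay individual SNPs; adjacent `I` and `D`
runs stay two records — the simplest VCF-valid representation.
Minus-strand blocks are called in target coordinates; the canonical
row orientation already holds reverse-complemented query bases.
`normalize_variants()` left-aligns indels by the standard rotation
(shift left while the last base of the event equals the reference base
at the anchor), is idempotent, and leaves SNPs untouched. QUAL is `.`,
FILTER `PASS`, genotype `1/1`: assembly-versus-assembly calls are
haploid statements, not genotype likelihoods.

## The simulator as ground truth

`simulate_pair()` draws a uniform-composition target and plants
substitutions, insertions and deletions per base at configured rates,
with geometric indel lengths (memoryless — the standard simulator
choice) and optional fixed-length planted SVs. The editing trace *is*
the alignment, so the emitted block, the three format files and the
truth variant table are exact by construction. Planted events are
forced non-adjacent (at least 2 bp of untouched sequence between
events, by rejection), so comparing calls to truth needs only
left-normalization, never haplotype realignment. The default study
conditions used throughout the tests are 100 kb pairs at
`snp_rate = 0.01`, `ins_rate = 0.002`, `del_rate = 0.002` over 20
seeds — divergence values typical of within-species assembly
comparisons — plus smaller 2–20 kb pairs for chunking and extraction
checks; the fixture alignment (10 columns, one mismatch, one
insertion) is asserted bit-exactly.

What the simulator does **not** emulate: repeats and segmental
duplications (so no ambiguous placements or mapping artifacts),
rearrangements, realistic mutation spectra, soft-masked or `N` bases,
multi-contig genomes, or alignment errors — the alignment is always
correct by construction. Passing the recovery suite therefore
demonstrates that the calling and normalization arithmetic is exact on
correct alignments; it says nothing about the upstream aligner's
quality on real genomes.

## Numerical and degenerate-input choices

* Coordinates are stored as doubles; spans up to 2^53 are exact, far
  beyond any genome.
* Parsers fail loudly with positions (byte offset in a CIGAR, record
  id for a chain sum-invariant violation); there is no silent repair.
* Empty inputs produce empty outputs of the right type; an empty
  segment table still renders an SVG frame with axes.
* Ties in pseudo-MAF overlap resolution go to input order; SV planting
  overrides colliding random events; chunk rows may carry size 0.
* The SVG writer emits fixed two-decimal geometry so identical input
  yields byte-identical output.

## Known limitations

Multi-row (>2 sequences) MAF algebra beyond what pseudo-MAF needs is
out of scope, as are Delta/HAL/SAM formats, liftover-style chain
netting, inversion and translocation inference, score recomputation
with substitution matrices, and random access into gzip-compressed
MAF (indexing requires a seekable plain-text file). `--threads` is
accepted for interface compatibility but processing is sequential in
input order; at the problem sizes this package targets the parsers,
not the arithmetic, dominate runtime.
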