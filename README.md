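# wgakit

Tools for **pairwise whole-genome alignments** in R: lossless
interconversion among MAF, PAF and UCSC Chain; MAF indexing, region
extraction and chunking; alignment statistics and filtering;
reference-projected pseudo-MAF matrices with per-base conservation
scores; alignment-based variant calling to VCF; dotplot export; and a
deterministic simulator of genome pairs with exact truth sets.

It is written for comparative genomicists who sit between an aligner
(minimap2, wfmash, AnchorWave, ...) and downstream analysis, and keep
hitting the fact that every tool speaks a different alignment dialect.

## The model

Every format routes through one canonical block: target fixed on the
forward strand, all coordinates 0-based half-open forward-strand
intervals, base-level detail as a normalized CIGAR over
`{=, X, I, D, M}` with optional gapped rows. For a block *b* with
cigar runs *(op_i, ℓ_i)*:

* target span = Σ ℓ_i over `=,X,D,M`; query span = Σ ℓ_i over `=,X,I,M`
* gap-compressed identity = matches / (matches + mismatches)
* windowed gap divergence = (mismatch + indel columns) / columns in
  the window, each column assigned by projecting it onto the target
* variant calls: `X` → SNP, maximal `I`/`D` run → anchored INS/DEL,
  left-normalized by the standard VCF rotation; runs ≥ 50 bp are
  flagged structural

Chain is the one lossy edge (it stores no base-level detail): `=`/`X`
coarsens to `M` on the way in, and is restored exactly from FASTA on
the way back out.

## Worked example

```r
library(wgakit)

taln <- "ACGTTGCA-T"   # target row,  t.chr1 [0,9)
qaln <- "ACGATGCAGT"   # query row,   q.chr1 [0,10), '+'
b <- pairwise_block("t.chr1", 9, 0, 9, "q.chr1", 10, "+", 0, 10,
                    cig = cigar_from_aligned(taln, qaln),
                    taln = taln, qaln = qaln)

cigar_render(b$cigar)
#> [1] "3=1X4=1I1="

block_stats(list(b))[, c("columns", "matches", "mismatches",
                         "ins_bases", "identity_gap_compressed")]
#>   columns matches mismatches ins_bases identity_gap_compressed
#> 1      10       8          1         1               0.8888889

call_variants(list(b))[, c("chrom", "pos", "ref", "alt", "kind")]
#>    chrom pos ref alt kind
#> 1 t.chr1   4   T   A  SNP
#> 2 t.chr1   8   A  AG  INS
```

Ten alignment columns: eight match, one mismatches (a SNP at target
position 4, 1-based) and one is a query-only column (a `G` inserted
after target position 8, reported VCF-style as `A>AG` anchored on the
preceding base). Gap-compressed identity ignores the indel column:
8/9 ≈ 0.889.

Round-tripping the same block through the formats:

```r
paf <- blocks_to_paf(list(b))      # nmatch 8, block_len 10, cg 3=1X4=1I1=
chain <- paf_to_chain(paf)         # blocks (8,0,1), (1)
maf <- chain_to_maf(chain, c(t.chr1 = "ACGTTGCAT"),
                    c(q.chr1 = "ACGATGCAGT"))
cigar_render(maf_block_to_pairwise(maf[[1]])$cigar)
#> [1] "3=1X4=1I1="
```

The simulator generates test beds with exact truth:

```r
sim <- simulate_pair(sim_config(100000, snp_rate = 0.01,
                                ins_rate = 0.002, del_rate = 0.002,
                                seed = 1))
emit_formats(sim, "pair")   # pair.{t.fa,q.fa,maf,paf,chain,truth.tsv}
```

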