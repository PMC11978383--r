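#' Format conversions over the canonical pairwise model
#'
#' The six pairwise conversions MAF/PAF/Chain all route through
#' [pairwise_block()]. Base-level detail flows losslessly between MAF
#' and PAF (`cg:Z:` with `=`/`X`/`I`/`D`); a chain cannot represent
#' mismatch positions, so the `=`/`X` to `M` coarsening on the way into
#' Chain is the one lossy edge, and [chain_to_maf()] /
#' a second pass of [paf_to_maf()] recovers `=`/`X` exactly from the
#' genome sequences.
#'
#' @param maf a `maf` object from [read_maf()].
#' @return [maf_to_paf()]: a `paf` data frame, one record per block,
#'   with `nmatch` the `=` column count and `block_len` the total
#'   column count.
#' @seealso [read_maf()], [read_paf()], [read_chain()]
#' @export
maf_to_paf <- function(maf) {
  blocks_to_paf(lapply(maf, maf_block_to_pairwise))
}

#' @rdname maf_to_paf
#' @param paf a `paf` data frame; every record needs a `cg` tag.
#' @param target_fasta,query_fasta genomes (paths, named character
#'   vectors or `DNAStringSet`s) used to reconstruct aligned rows.
#' @return [paf_to_maf()]: a `maf` object with aligned rows rebuilt by
#'   walking each CIGAR over the fetched sequences (`M` re-split into
#'   `=`/`X` from the bases).
#' @export
paf_to_maf <- function(paf, target_fasta, query_fasta) {
  target_fasta <- as_fasta(target_fasta)
  query_fasta <- as_fasta(query_fasta)
  blocks <- lapply(paf_to_blocks(paf), block_ensure_aligned,
                   target_fasta = target_fasta, query_fasta = query_fasta)
  structure(lapply(blocks, pairwise_to_maf_block), class = "maf")
}

#' @rdname maf_to_paf
#' @return [paf_to_chain()]: a `chain` object; maximal `=`/`X`/`M` runs
#'   become ungapped blocks, `I` contributes `dq`, `D` contributes
#'   `dt`, ids are assigned 1, 2, 3, ... in input order.
#' @export
paf_to_chain <- function(paf) {
  blocks_to_chain(paf_to_blocks(paf))
}

#' @rdname maf_to_paf
#' @param chain a `chain` object from [read_chain()].
#' @return [chain_to_paf()]: a `paf` data frame with `M`-run CIGARs;
#'   `nmatch` falls back to the summed block sizes since bases are
#'   unknown.
#' @export
chain_to_paf <- function(chain) {
  blocks_to_paf(lapply(chain, chain_record_to_block))
}

#' @rdname maf_to_paf
#' @return [maf_to_chain()]: a `chain` object, single pass through the
#'   canonical model (no intermediate PAF text).
#' @export
maf_to_chain <- function(maf) {
  blocks_to_chain(lapply(maf, maf_block_to_pairwise))
}

#' @rdname maf_to_paf
#' @return [chain_to_maf()]: a `maf` object with rows reconstructed
#'   from the genomes, `M` split into `=`/`X`.
#' @export
chain_to_maf <- function(chain, target_fasta, query_fasta) {
  target_fasta <- as_fasta(target_fasta)
  query_fasta <- as_fasta(query_fasta)
  blocks <- lapply(lapply(chain, chain_record_to_block), block_ensure_aligned,
                   target_fasta = target_fasta, query_fasta = query_fasta)
  structure(lapply(blocks, pairwise_to_maf_block), class = "maf")
}
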