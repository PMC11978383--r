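#' Call variants from pairwise alignment signatures
#'
#' Walks each block's columns left to right in target coordinates:
#' every `X` column becomes a SNP at the consumed target base; every
#' maximal `I` run becomes an insertion anchored at the last consumed
#' target base (REF = anchor base, ALT = anchor + inserted query
#' bases); every maximal `D` run a deletion anchored at the base before
#' the run (REF = anchor + deleted bases, ALT = anchor). A leading
#' indel with no left anchor falls back to anchoring on the following
#' target base, with a warning. Indel runs of at least `sv_min_len`
#' bases are flagged as structural (SVTYPE/SVLEN/END INFO in the VCF).
#' Minus-strand query blocks are called in target coordinates with
#' query bases reverse-complemented (the canonical `qaln` orientation),
#' and consecutive `X` columns are emitted as individual SNPs.
#'
#' @param blocks see [block_stats()]. Blocks need aligned strings, or
#'   an `=`/`X` cigar plus `target_fasta` and `query_fasta` to fetch
#'   bases; `M` runs without bases are an error.
#' @param target_fasta,query_fasta optional genomes used to reconstruct
#'   bases when the blocks carry only a cigar.
#' @param sv_min_len indel length at or above which a call is flagged
#'   structural (default 50 bp, the community convention).
#' @param emit variant kinds to keep.
#' @param qname_info annotate each call with the query name and the
#'   1-based forward-strand query position of the variant.
#' @return Data frame of class `variants`, sorted by `(chrom, pos)`:
#'   `chrom, pos, ref, alt, kind, svlen, end, is_sv, qname, qpos` with
#'   `pos`/`end` 1-based and `svlen` signed (+ins/-del, 0 for SNP).
#' @export
call_variants <- function(blocks, target_fasta = NULL, query_fasta = NULL,
                          sv_min_len = 50, emit = c("SNP", "INS", "DEL"),
                          qname_info = TRUE) {
  stopifnot(sv_min_len >= 1)
  emit <- match.arg(emit, c("SNP", "INS", "DEL"), several.ok = TRUE)
  blocks <- as_block_list(blocks)
  out <- lapply(blocks, function(b) {
    if (is.null(b$taln)) {
      if (is.null(target_fasta) || is.null(query_fasta)) {
        if (!is.null(block_ensure_cigar(b)$cigar) && any(b$cigar$op == "M")) {
          stop("cigar has M runs and no bases; supply FASTAs to call variants")
        }
        stop("blocks carry no bases; supply target_fasta and query_fasta")
      }
      b <- block_ensure_aligned(b, target_fasta, query_fasta)
    } else {
      b <- block_ensure_cigar(b)
      b$cigar <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
    }
    call_block(b, sv_min_len = sv_min_len)
  })
  x <- do.call(rbind, out)
  if (is.null(x) || nrow(x) == 0L) return(empty_variants())
  x <- x[x$kind %in% emit, , drop = FALSE]
  x <- x[order(x$chrom, x$pos, x$ref, x$alt), , drop = FALSE]
  rownames(x) <- NULL
  if (!qname_info) x$qname <- x$qpos <- NULL
  class(x) <- c("variants", "data.frame")
  x
}

empty_variants <- function() {
  x <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), kind = character(), svlen = numeric(),
                  end = numeric(), is_sv = logical(), qname = character(),
                  qpos = numeric(), stringsAsFactors = FALSE)
  class(x) <- c("variants", "data.frame")
  x
}

# op-level walk over one block with a resolved (=,X,I,D) cigar and bases
call_block <- function(b, sv_min_len) {
  op <- b$cigar$op
  len <- b$cigar$len
  tcons <- op != "I"
  qcons <- op != "D"
  tcum <- cumsum(ifelse(tcons, len, 0))   # target bases consumed through op i
  qcum <- cumsum(ifelse(qcons, len, 0))
  ccum <- cumsum(len)                      # columns through op i
  tseq <- gsub("-", "", b$taln, fixed = TRUE)
  qaln_c <- NULL
  # forward-strand 1-based query position of the alignment-frame offset q0
  qfwd <- function(q0) {
    if (b$qstrand == "+") b$qstart + q0 + 1 else b$qend - q0
  }
  recs <- list()
  add <- function(df) recs[[length(recs) + 1L]] <<- df
  xi <- which(op == "X")
  if (length(xi)) {
    if (is.null(qaln_c)) qaln_c <- strsplit(b$qaln, "", fixed = TRUE)[[1L]]
    taln_c <- strsplit(b$taln, "", fixed = TRUE)[[1L]]
    cols <- unlist(lapply(xi, function(i) (ccum[i] - len[i] + 1L):ccum[i]))
    toff <- unlist(lapply(xi, function(i) (tcum[i] - len[i]):(tcum[i] - 1L)))
    qoff <- unlist(lapply(xi, function(i) (qcum[i] - len[i]):(qcum[i] - 1L)))
    add(data.frame(
      chrom = b$tname, pos = b$tstart + toff + 1,
      ref = taln_c[cols], alt = qaln_c[cols], kind = "SNP",
      svlen = 0, end = b$tstart + toff + 1, is_sv = FALSE,
      qname = b$qname, qpos = vapply(qoff, qfwd, numeric(1L)),
      stringsAsFactors = FALSE))
  }
  qseq <- gsub("-", "", b$qaln, fixed = TRUE)
  for (i in which(op == "I")) {
    ins <- substr(qseq, qcum[i] - len[i] + 1L, qcum[i])
    anchor_rel <- tcum[i]  # target bases consumed before the run
    if (anchor_rel >= 1L) {
      ref <- substr(tseq, anchor_rel, anchor_rel)
      add(data.frame(chrom = b$tname, pos = b$tstart + anchor_rel,
                     ref = ref, alt = paste0(ref, ins), kind = "INS",
                     svlen = len[i], end = b$tstart + anchor_rel,
                     is_sv = len[i] >= sv_min_len, qname = b$qname,
                     qpos = qfwd(qcum[i] - len[i]),
                     stringsAsFactors = FALSE))
    } else {
      warning("leading insertion with no left anchor; anchoring on the ",
              "following target base")
      ref <- substr(tseq, 1L, 1L)
      add(data.frame(chrom = b$tname, pos = b$tstart + 1,
                     ref = ref, alt = paste0(ins, ref), kind = "INS",
                     svlen = len[i], end = b$tstart + 1,
                     is_sv = len[i] >= sv_min_len, qname = b$qname,
                     qpos = qfwd(qcum[i] - len[i]),
                     stringsAsFactors = FALSE))
    }
  }
  for (i in which(op == "D")) {
    del <- substr(tseq, tcum[i] - len[i] + 1L, tcum[i])
    anchor_rel <- tcum[i] - len[i]  # base before the run
    if (anchor_rel >= 1L) {
      anc <- substr(tseq, anchor_rel, anchor_rel)
      add(data.frame(chrom = b$tname, pos = b$tstart + anchor_rel,
                     ref = paste0(anc, del), alt = anc, kind = "DEL",
                     svlen = -len[i], end = b$tstart + anchor_rel + len[i],
                     is_sv = len[i] >= sv_min_len, qname = b$qname,
                     qpos = qfwd(qcum[i]),
                     stringsAsFactors = FALSE))
    } else {
      warning("leading deletion with no left anchor; anchoring on the ",
              "following target base")
      anc <- substr(tseq, len[i] + 1L, len[i] + 1L)
      add(data.frame(chrom = b$tname, pos = b$tstart + 1,
                     ref = paste0(del, anc), alt = anc, kind = "DEL",
                     svlen = -len[i], end = b$tstart + len[i] + 1,
                     is_sv = len[i] >= sv_min_len, qname = b$qname,
                     qpos = qfwd(qcum[i]),
                     stringsAsFactors = FALSE))
    }
  }
  if (length(recs)) do.call(rbind, recs) else NULL
}

#' Left-normalize indel representations
#'
#' Shifts each indel to its leftmost equivalent VCF representation:
#' while the last base of the inserted/deleted sequence equals the
#' reference base at the anchor, the event is rotated one base left.
#' SNPs are unchanged and the operation is idempotent.
#'
#' @param variants a `variants` data frame ([call_variants()]) or any
#'   data frame with `chrom, pos, ref, alt, kind` columns.
#' @param target_fasta the target genome.
#' @return The variants with updated `pos`, `ref`, `alt` (and `end`
#'   when present), re-sorted by `(chrom, pos)`.
#' @export
normalize_variants <- function(variants, target_fasta) {
  if (nrow(variants) == 0L) return(variants)
  target_fasta <- as_fasta(target_fasta)
  seqs <- lapply(stats::setNames(nm = unique(variants$chrom)), function(nm) {
    fasta_fetch(target_fasta, nm, 0, fasta_sizes(target_fasta)[[nm]], "+")
  })
  for (r in seq_len(nrow(variants))) {
    kind <- variants$kind[r]
    if (kind == "SNP") next
    g <- seqs[[variants$chrom[r]]]
    p <- variants$pos[r]           # 1-based anchor
    s <- if (kind == "INS") substr(variants$alt[r], 2L, nchar(variants$alt[r]))
         else substr(variants$ref[r], 2L, nchar(variants$ref[r]))
    L <- nchar(s)
    while (p > 1 && substr(s, L, L) == substr(g, p, p)) {
      s <- paste0(substr(g, p, p), substr(s, 1L, L - 1L))
      p <- p - 1
    }
    anc <- substr(g, p, p)
    variants$pos[r] <- p
    if (kind == "INS") {
      variants$ref[r] <- anc
      variants$alt[r] <- paste0(anc, s)
      if ("end" %in% names(variants)) variants$end[r] <- p
    } else {
      variants$ref[r] <- paste0(anc, s)
      variants$alt[r] <- anc
      if ("end" %in% names(variants)) variants$end[r] <- p + L
    }
  }
  variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                             variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  variants
}

#' Write variants as VCF 4.2
#'
#' Header carries `fileformat`, one `contig` line per sequence, the
#' `SVTYPE`/`SVLEN`/`END` INFO definitions (plus `QNAME`/`QPOS` when
#' present) and a `GT` FORMAT line. Records are 1-based; QUAL is `.`,
#' FILTER `PASS`, and the single query sample is written `1/1`
#' (haploid assembly-vs-assembly semantics). Input must be sorted by
#' `(chrom, pos)`.
#'
#' @param variants a `variants` data frame.
#' @param contigs named vector of contig lengths.
#' @param sample sample column name.
#' @param path output file, or `""` for stdout.
#' @export
write_vcf <- function(variants, contigs, sample = "sample", path = "") {
  if (nrow(variants) > 0L) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(nrow(variants)))) {
      stop("variants must be sorted by (chrom, pos)")
    }
  }
  has_q <- all(c("qname", "qpos") %in% names(variants))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%s>", names(contigs), fmt_num(contigs)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position on the reference\">",
    if (has_q) c(
      "##INFO=<ID=QNAME,Number=1,Type=String,Description=\"Query sequence name\">",
      "##INFO=<ID=QPOS,Number=1,Type=Integer,Description=\"1-based forward-strand query position\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  body <- character(0)
  if (nrow(variants) > 0L) {
    info <- rep("", nrow(variants))
    sv <- variants$is_sv %in% TRUE
    info[sv] <- sprintf("SVTYPE=%s;SVLEN=%s;END=%s", variants$kind[sv],
                        fmt_num(variants$svlen[sv]), fmt_num(variants$end[sv]))
    if (has_q) {
      qinfo <- sprintf("QNAME=%s;QPOS=%s", variants$qname, fmt_num(variants$qpos))
      info <- ifelse(nzchar(info), paste(info, qinfo, sep = ";"), qinfo)
    }
    info[!nzchar(info)] <- "."
    body <- paste(variants$chrom, fmt_num(variants$pos), ".", variants$ref,
                  variants$alt, ".", "PASS", info, "GT", "1/1", sep = "\t")
  }
  write_text_lines(c(hdr, body), path)
}
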