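#' Canonical pairwise alignment block
#'
#' Every format in the package round-trips through this one in-memory
#' representation. The frame is fixed by construction: the target is
#' always on the forward strand, and all coordinates are 0-based
#' half-open intervals on the forward strand of their sequence — the
#' query interval in particular is on the query *forward* strand even
#' when `qstrand == "-"`. Strand-relative offsets exist only inside the
#' format readers and writers. The optional gapped strings `taln`/`qaln`
#' are laid out in target-forward column order, so for a minus-strand
#' query `qaln` holds reverse-complemented query bases.
#'
#' @param tname,tsize target sequence name and length (bp).
#' @param tstart,tend target interval, 0-based half-open, forward strand.
#' @param qname,qsize query sequence name and length (bp).
#' @param qstrand `"+"` or `"-"`.
#' @param qstart,qend query interval, 0-based half-open, forward strand.
#' @param cig optional [cigar()].
#' @param taln,qaln optional equal-length gapped aligned strings.
#' @param score optional numeric alignment score.
#' @param validate check all invariants (span agreement, string
#'   consistency); disable only on a hot path that constructs
#'   already-checked blocks.
#' @return An object of class `pairwise_block`.
#' @export
pairwise_block <- function(tname, tsize, tstart, tend,
                           qname, qsize, qstrand, qstart, qend,
                           cig = NULL, taln = NULL, qaln = NULL,
                           score = NA_real_, validate = TRUE) {
  b <- structure(
    list(tname = as.character(tname), tsize = as.numeric(tsize),
         tstart = as.numeric(tstart), tend = as.numeric(tend),
         qname = as.character(qname), qsize = as.numeric(qsize),
         qstrand = match.arg(qstrand, c("+", "-")),
         qstart = as.numeric(qstart), qend = as.numeric(qend),
         cigar = cig, taln = taln, qaln = qaln, score = as.numeric(score)),
    class = "pairwise_block")
  if (validate) validate_block(b)
  b
}

#' Validate a pairwise block's invariants
#'
#' Checks interval sanity, cigar span agreement, and (when aligned
#' strings are present) equal lengths, absence of doubly-gapped columns,
#' non-gap counts matching the coordinate spans, and cigar/string
#' consistency.
#'
#' @param b a [pairwise_block()].
#' @return `b`, invisibly; errors describe the violated invariant.
#' @export
validate_block <- function(b) {
  with(b, {
    if (!(tstart >= 0 && tstart < tend && tend <= tsize)) {
      stop("bad target interval [", tstart, ",", tend, ") for size ", tsize)
    }
    if (!(qstart >= 0 && qstart < qend && qend <= qsize)) {
      stop("bad query interval [", qstart, ",", qend, ") for size ", qsize)
    }
  })
  if (!is.null(b$cigar)) {
    if (cigar_target_span(b$cigar) != b$tend - b$tstart) {
      stop("cigar target span ", cigar_target_span(b$cigar),
           " != target interval width ", b$tend - b$tstart)
    }
    if (cigar_query_span(b$cigar) != b$qend - b$qstart) {
      stop("cigar query span ", cigar_query_span(b$cigar),
           " != query interval width ", b$qend - b$qstart)
    }
  }
  if (!is.null(b$taln) || !is.null(b$qaln)) {
    if (is.null(b$taln) || is.null(b$qaln)) stop("need both aligned strings or neither")
    derived <- cigar_from_aligned(b$taln, b$qaln)  # errors on bad columns
    if (cigar_target_span(derived) != b$tend - b$tstart ||
        cigar_query_span(derived) != b$qend - b$qstart) {
      stop("aligned string non-gap counts disagree with the coordinate spans")
    }
    if (!is.null(b$cigar) && !cigar_consistent(b$cigar, derived)) {
      stop("cigar is inconsistent with the aligned strings")
    }
  }
  invisible(b)
}

# TRUE when `cig` (possibly holding opaque M runs) matches the =/X-resolved
# cigar derived from the aligned strings.
cigar_consistent <- function(cig, derived) {
  a <- cigar_expand(cig)
  d <- cigar_expand(derived)
  length(a) == length(d) && all(a == d | (a == "M" & d %in% c("=", "X")))
}

#' @export
print.pairwise_block <- function(x, ...) {
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  cat(sprintf("<pairwise_block> %s:[%s,%s) %s %s:[%s,%s) (%s)\n",
              x$tname, fmt(x$tstart), fmt(x$tend), x$qstrand,
              x$qname, fmt(x$qstart), fmt(x$qend),
              if (is.null(x$cigar)) "no cigar" else cigar_render(x$cigar)))
  invisible(x)
}

#' Ensure a block carries a cigar
#'
#' Derives the cigar from the aligned strings when absent.
#' @param b a [pairwise_block()].
#' @return The block, with `$cigar` non-NULL.
#' @export
block_ensure_cigar <- function(b) {
  if (is.null(b$cigar)) {
    if (is.null(b$taln)) stop("block has neither cigar nor aligned strings")
    b$cigar <- cigar_from_aligned(b$taln, b$qaln)
  }
  b
}

#' Reconstruct aligned strings for a block from genome sequences
#'
#' Walks the cigar over the fetched target and query sub-sequences to
#' rebuild the gapped rows; any opaque `M` runs are re-split into `=`/`X`
#' from the bases. For a minus-strand query the fetched query segment is
#' reverse-complemented so that rows are in target-forward column order.
#'
#' @param b a [pairwise_block()] with a cigar.
#' @param target_fasta,query_fasta sequence sets (see [read_fasta()]) or
#'   file paths.
#' @return The block with `taln`, `qaln` set and `M`-free cigar.
#' @export
block_ensure_aligned <- function(b, target_fasta, query_fasta) {
  if (!is.null(b$taln) && !is.null(b$qaln)) {
    b$cigar <- cigar_resolve_m(block_ensure_cigar(b)$cigar, b$taln, b$qaln)
    return(b)
  }
  if (is.null(b$cigar)) stop("block has neither cigar nor aligned strings")
  target_fasta <- as_fasta(target_fasta)
  query_fasta <- as_fasta(query_fasta)
  tseq <- fasta_fetch(target_fasta, b$tname, b$tstart, b$tend, "+")
  qseq <- fasta_fetch(query_fasta, b$qname, b$qstart, b$qend, b$qstrand)
  if (nchar(tseq) != cigar_target_span(b$cigar) ||
      nchar(qseq) != cigar_query_span(b$cigar)) {
    stop("corrupt input: fetched sequence lengths disagree with CIGAR spans")
  }
  opv <- cigar_expand(b$cigar)
  tcons <- opv != "I"
  qcons <- opv != "D"
  tcol <- rep("-", length(opv))
  qcol <- rep("-", length(opv))
  tcol[tcons] <- strsplit(tseq, "", fixed = TRUE)[[1L]]
  qcol[qcons] <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  b$taln <- paste(tcol, collapse = "")
  b$qaln <- paste(qcol, collapse = "")
  b$cigar <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
  b
}

#' Project one alignment column onto the target
#'
#' @param b a [pairwise_block()] with cigar or aligned strings.
#' @param column 0-based column index.
#' @return A list: `pos`, the 0-based forward target coordinate consumed
#'   at the column (for insertion columns, the coordinate of the last
#'   previously consumed base, or `tstart - 1` when none — the
#'   "before-start" anchor); `insertion`, `TRUE` for `I` columns.
#' @export
project_column_to_target <- function(b, column) {
  b <- block_ensure_cigar(b)
  n <- cigar_columns(b$cigar)
  if (column < 0 || column >= n) {
    stop("column ", column, " out of range [0,", n, ")")
  }
  m <- cigar_column_targets(b$cigar, b$tstart)
  list(pos = m$pos[column + 1L], insertion = !m$consumes[column + 1L])
}

#' Number of match (`=`) columns of a block
#'
#' Requires `=`/`X` resolution: a cigar containing `M` without aligned
#' strings is an error rather than a guess.
#' @param b a [pairwise_block()].
#' @return Count of `=` columns.
#' @export
block_matches <- function(b) {
  b <- block_ensure_cigar(b)
  if (any(b$cigar$op == "M")) {
    if (is.null(b$taln)) {
      stop("cannot count matches: cigar has M runs and no bases are available")
    }
    b$cigar <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
  }
  sum(b$cigar$len[b$cigar$op == "="])
}

# reverse-complement a gapped alignment row ('-' preserved)
revcomp_gapped <- function(x) {
  chartr("ACGTUNacgtun", "TGCAANtgcaan",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}
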