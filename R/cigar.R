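#' CIGAR run-length alignment encodings
#'
#' A `cigar` is the conversion currency of the package: an ordered
#' run-length list of alignment operations over the closed alphabet
#' `=` (match), `X` (mismatch), `I` (insertion, query-only column),
#' `D` (deletion, target-only column) and `M` (match-or-mismatch,
#' opaque until bases are available). A normalized cigar never holds
#' two consecutive runs of the same kind.
#'
#' @param op character vector of operation letters.
#' @param len integer vector of run lengths, parallel to `op`.
#' @param drop_zero drop zero-length runs instead of erroring.
#' @return An object of class `cigar`: a list with elements `op` and `len`.
#' @examples
#' cigar_parse("3=1X4=1I1=")
#' @export
cigar <- function(op, len, drop_zero = FALSE) {
  if (length(op) != length(len)) stop("op and len must have equal length")
  bad <- !op %in% CIGAR_OPS
  if (any(bad)) stop("unknown CIGAR op: ", op[which(bad)[1]])
  len <- as.numeric(len)
  if (drop_zero) {
    keep <- len > 0
    op <- op[keep]
    len <- len[keep]
  }
  if (any(len < 1)) stop("CIGAR run length must be >= 1")
  if (length(op) > 1L) {
    grp <- cumsum(c(TRUE, op[-1L] != op[-length(op)]))
    if (grp[length(grp)] < length(op)) {
      len <- as.numeric(rowsum(len, grp))
      op <- op[!duplicated(grp)]
    }
  }
  structure(list(op = op, len = len), class = "cigar")
}

CIGAR_OPS <- c("=", "X", "I", "D", "M")

#' Parse a CIGAR string
#'
#' Accepts the extended alphabet `=XIDM`. Runs are merged
#' (`"2=2="` parses to one 4-column match run); a zero-length run, an
#' unknown letter or an empty string is a parse error naming the byte
#' offset of the offending token.
#'
#' @param text a single CIGAR string.
#' @return A normalized [cigar()].
#' @export
cigar_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) stop("empty CIGAR string (byte offset 1)")
  m <- gregexpr("[0-9]+[=XIDM]", text)[[1L]]
  ml <- attr(m, "match.length")
  if (m[1L] == -1L || m[1L] != 1L || any(m + ml != c(m[-1L], nchar(text) + 1L))) {
    # first byte not covered by the contiguous token tiling
    covered <- if (m[1L] == -1L || m[1L] != 1L) 0L else {
      runs <- which(cumsum(m != c(1L, (m + ml)[-length(m)])) == 0L)
      sum(ml[runs])
    }
    stop("malformed CIGAR at byte offset ", covered + 1L, " in ", sQuote(text))
  }
  tok <- regmatches(text, list(m))[[1L]]
  op <- substr(tok, nchar(tok), nchar(tok))
  len <- as.numeric(substr(tok, 1L, nchar(tok) - 1L))
  if (any(len == 0)) {
    bad <- which(len == 0)[1L]
    stop("zero-length CIGAR run at byte offset ", m[bad])
  }
  cigar(op, len)
}

#' Render a cigar back to its string form
#' @param cig a [cigar()].
#' @return A single string such as `"3=1X4=1I1="`.
#' @export
cigar_render <- function(cig) {
  if (length(cig$op) == 0L) return("")
  paste0(format(cig$len, scientific = FALSE, trim = TRUE), cig$op, collapse = "")
}

#' @export
print.cigar <- function(x, ...) {
  cat("<cigar> ", cigar_render(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.cigar <- function(x, ...) cigar_render(x)

#' Target and query spans of a cigar
#'
#' The target span counts `=`, `X`, `D` and `M` columns; the query span
#' counts `=`, `X`, `I` and `M` columns.
#'
#' @param cig a [cigar()].
#' @return Number of bases consumed on that side.
#' @export
cigar_target_span <- function(cig) sum(cig$len[cig$op %in% c("=", "X", "D", "M")])

#' @rdname cigar_target_span
#' @export
cigar_query_span <- function(cig) sum(cig$len[cig$op %in% c("=", "X", "I", "M")])

#' Total alignment columns of a cigar
#' @param cig a [cigar()].
#' @export
cigar_columns <- function(cig) sum(cig$len)

#' Expand a cigar to one operation letter per alignment column
#' @param cig a [cigar()].
#' @return Character vector of length [cigar_columns()].
#' @export
cigar_expand <- function(cig) rep(cig$op, cig$len)

#' Derive a cigar from a pair of gapped aligned strings
#'
#' Column classification: both bases and equal (case-insensitive, and
#' neither `N`) gives `=`; both bases, unequal or involving `N`, gives
#' `X`; target gap gives `I`; query gap gives `D`. A column gapped on
#' both rows is a format error reporting the 1-based column.
#'
#' @param target_aln,query_aln equal-length gapped strings (`-` gaps).
#' @return A normalized [cigar()] using only `=`, `X`, `I`, `D`.
#' @export
cigar_from_aligned <- function(target_aln, query_aln) {
  tc <- strsplit(target_aln, "", fixed = TRUE)[[1L]]
  qc <- strsplit(query_aln, "", fixed = TRUE)[[1L]]
  if (length(tc) != length(qc)) {
    stop("aligned strings differ in length: ", length(tc), " vs ", length(qc))
  }
  if (length(tc) == 0L) stop("empty alignment")
  tg <- tc == "-"
  qg <- qc == "-"
  if (any(tg & qg)) {
    stop("column gapped in both rows at column ", which(tg & qg)[1L])
  }
  tu <- toupper(tc)
  qu <- toupper(qc)
  op <- ifelse(tg, "I", ifelse(qg, "D", ifelse(tu == qu & tu != "N", "=", "X")))
  r <- rle(op)
  cigar(r$values, r$lengths)
}

#' Split opaque M runs into =/X given the aligned strings
#'
#' @param cig a [cigar()] possibly containing `M`.
#' @param target_aln,query_aln the gapped strings consistent with `cig`.
#' @return A [cigar()] with every `M` resolved.
#' @keywords internal
cigar_resolve_m <- function(cig, target_aln, query_aln) {
  if (!any(cig$op == "M")) return(cig)
  cigar_from_aligned(target_aln, query_aln)
}

#' Per-column projection of alignment columns onto target coordinates
#'
#' For each column gives the 0-based forward target coordinate consumed
#' there (`=`, `X`, `D`, `M` columns), or for insertion columns the
#' coordinate of the last previously consumed target base; a leading
#' insertion with no consumed base anchors at `tstart - 1`
#' ("before-start").
#'
#' @param cig a [cigar()].
#' @param tstart 0-based target start of the alignment.
#' @return A list with `pos` (numeric, per column) and `consumes`
#'   (logical, `FALSE` for insertion columns).
#' @keywords internal
cigar_column_targets <- function(cig, tstart = 0) {
  opv <- cigar_expand(cig)
  consumes <- opv != "I"
  pos <- tstart + cumsum(consumes) - 1
  list(pos = pos, consumes = consumes)
}
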