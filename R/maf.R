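#' Read a MAF file
#'
#' Parses UCSC Multiple Alignment Format: `#` header lines, blocks
#' introduced by an `a` line with optional `score=`, and `s` rows
#' `src start size strand srcSize text` where `start` is a 0-based
#' strand-relative offset and `text` a gapped aligned string. `e`, `i`
#' and `q` lines are skipped with a warning (pairwise conversions do not
#' use them). Each row is validated: `size` must equal the non-gap
#' character count of `text`, `start + size` must fit in `srcSize`, and
#' all rows of a block must have equal text length.
#'
#' @param path MAF file (plain or gzip-compressed), or a connection.
#' @return An object of class `maf`: a list of `maf_block`s, each a list
#'   with `score` and a data frame `rows`
#'   (`src,start,size,strand,src_size,text`).
#' @export
read_maf <- function(path) {
  lines <- read_text_lines(path)
  parse_maf_lines(lines)
}

parse_maf_lines <- function(lines) {
  blocks <- list()
  cur_a <- NULL
  cur_rows <- list()
  skipped <- 0L
  flush <- function() {
    if (is.null(cur_a)) return()
    if (length(cur_rows) == 0L) stop("truncated MAF block: 'a' line with no 's' rows")
    rows <- do.call(rbind, cur_rows)
    if (length(unique(nchar(rows$text))) != 1L) {
      stop("MAF block rows differ in text length")
    }
    blocks[[length(blocks) + 1L]] <<- structure(
      list(score = cur_a, rows = rows), class = "maf_block")
    cur_a <<- NULL
    cur_rows <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    first <- substr(ln, 1L, 1L)
    if (first == "#") next
    if (first == "a") {
      flush()
      sc <- regmatches(ln, regexpr("score=[-0-9.eE+]+", ln))
      cur_a <- if (length(sc)) as.numeric(sub("score=", "", sc)) else NA_real_
    } else if (first == "s") {
      if (is.null(cur_a)) stop("MAF 's' line outside a block (missing 'a' line)")
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(f) != 7L) stop("malformed MAF 's' line: ", ln)
      row <- data.frame(src = f[2L], start = as.numeric(f[3L]),
                        size = as.numeric(f[4L]), strand = f[5L],
                        src_size = as.numeric(f[6L]), text = f[7L],
                        stringsAsFactors = FALSE)
      if (is.na(row$start) || is.na(row$size) || is.na(row$src_size)) {
        stop("non-numeric coordinate in MAF 's' line: ", ln)
      }
      if (!row$strand %in% c("+", "-")) stop("bad strand in MAF 's' line: ", ln)
      nongap <- nchar(row$text) - lengths(regmatches(row$text, gregexpr("-", row$text, fixed = TRUE)))
      if (nongap != row$size) {
        stop("MAF row size ", row$size, " != ", nongap,
             " non-gap characters for ", row$src)
      }
      if (row$start + row$size > row$src_size) {
        stop("MAF row extends past srcSize for ", row$src)
      }
      cur_rows[[length(cur_rows) + 1L]] <- row
    } else if (first %in% c("e", "i", "q")) {
      skipped <- skipped + 1L
    }
  }
  flush()
  if (skipped > 0L) {
    warning("skipped ", skipped, " MAF e/i/q line(s); only 's' rows are used")
  }
  structure(blocks, class = "maf")
}

#' Write MAF blocks
#'
#' Emits a `##maf version=1` header then one block per element. An
#' unknown score is written as `score=0` (the field is mandatory in the
#' format but no scoring scheme is attached to it here).
#'
#' @param maf a `maf` object, a list of `maf_block`s, or a list of
#'   [pairwise_block()]s with aligned strings.
#' @param path output file, or `""` for stdout.
#' @export
write_maf <- function(maf, path = "") {
  blocks <- lapply(unclass(maf), function(b) {
    if (inherits(b, "pairwise_block")) pairwise_to_maf_block(b) else b
  })
  out <- c("##maf version=1", unlist(lapply(blocks, format_maf_block)))
  write_text_lines(out, path)
}

format_maf_block <- function(b) {
  score <- if (is.na(b$score)) 0 else b$score
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  c(paste0("a score=", fmt(score)),
    sprintf("s %s %s %s %s %s %s",
            b$rows$src, fmt(b$rows$start), fmt(b$rows$size),
            b$rows$strand, fmt(b$rows$src_size), b$rows$text),
    "")
}

#' Convert a 2-row MAF block to the canonical pairwise model
#'
#' Row 1 is the target/reference. Strand-relative MAF starts are mapped
#' to forward coordinates (`forward_start = src_size - start - size` on
#' `-`); if the target row itself is on `-`, both rows are
#' reverse-complemented and the query strand flipped so that the target
#' is forward — the canonical frame. The cigar is derived from the
#' aligned texts.
#'
#' @param b a `maf_block` with exactly two rows.
#' @return A [pairwise_block()].
#' @export
maf_block_to_pairwise <- function(b) {
  if (nrow(b$rows) != 2L) {
    stop("pairwise required: MAF block has ", nrow(b$rows), " rows")
  }
  t <- b$rows[1L, ]
  q <- b$rows[2L, ]
  fwd <- function(r) {
    if (r$strand == "+") r$start else r$src_size - r$start - r$size
  }
  tfs <- fwd(t); qfs <- fwd(q)
  ttext <- t$text; qtext <- q$text
  qstrand <- q$strand
  if (t$strand == "-") {
    ttext <- revcomp_gapped(ttext)
    qtext <- revcomp_gapped(qtext)
    qstrand <- if (q$strand == "+") "-" else "+"
  }
  # score=0 is what the writer emits for "unknown" (no scoring scheme is
  # in scope), so it reads back as unknown
  score <- if (!is.na(b$score) && b$score == 0) NA_real_ else b$score
  pairwise_block(
    tname = t$src, tsize = t$src_size, tstart = tfs, tend = tfs + t$size,
    qname = q$src, qsize = q$src_size, qstrand = qstrand,
    qstart = qfs, qend = qfs + q$size,
    cig = cigar_from_aligned(ttext, qtext),
    taln = ttext, qaln = qtext, score = score)
}

#' Convert a canonical pairwise block to a 2-row MAF block
#'
#' Requires aligned strings (reconstruct them from FASTAs with
#' [block_ensure_aligned()] first if the block came from PAF or Chain).
#' The query row is written strand-relative per the MAF convention; its
#' text is the canonical `qaln`, which is already in target-forward
#' column order.
#'
#' @param b a [pairwise_block()] with `taln`/`qaln`.
#' @return A `maf_block`.
#' @export
pairwise_to_maf_block <- function(b) {
  if (is.null(b$taln) || is.null(b$qaln)) {
    stop("aligned strings required to write MAF; see block_ensure_aligned()")
  }
  qsize_aln <- b$qend - b$qstart
  qstart_rel <- if (b$qstrand == "+") b$qstart else b$qsize - b$qend
  rows <- data.frame(
    src = c(b$tname, b$qname),
    start = c(b$tstart, qstart_rel),
    size = c(b$tend - b$tstart, qsize_aln),
    strand = c("+", b$qstrand),
    src_size = c(b$tsize, b$qsize),
    text = c(b$taln, b$qaln),
    stringsAsFactors = FALSE)
  structure(list(score = b$score, rows = rows), class = "maf_block")
}

#' @export
print.maf <- function(x, ...) {
  cat("<maf> ", length(x), " block(s)\n", sep = "")
  invisible(x)
}
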