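#' Read a UCSC chain file
#'
#' Each record is a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id`
#' followed by ungapped block lines `size [dt dq]` with a final
#' size-only line; records are blank-line separated. Coordinates are
#' strand-relative: for a `-` strand they are offsets into the
#' reverse-complemented sequence. Both sum invariants
#' (`sum(size) + sum(dt) == tEnd - tStart` and
#' `sum(size) + sum(dq) == qEnd - qStart`) are verified on read — no
#' silent repair. A minus-strand *target* is normalized to `+` (UCSC
#' convention) by reversing the walk.
#'
#' @param path chain file (plain or gzip-compressed), `"-"` for stdin,
#'   or a connection.
#' @return An object of class `chain`: a list of `chain_record`s, each
#'   a list of the header fields plus a data frame
#'   `blocks(size, dt, dq)` whose final row has `dt = dq = 0`.
#' @export
read_chain <- function(path) {
  lines <- read_text_lines(path)
  recs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i])) || startsWith(lines[i], "#")) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain")) stop("expected chain header, got: ", lines[i])
    h <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(h) != 13L) stop("chain header must have 13 fields: ", lines[i])
    i <- i + 1L
    sizes <- numeric(); dts <- numeric(); dqs <- numeric()
    repeat {
      if (i > n || !nzchar(trimws(lines[i]))) stop("truncated chain record ", h[13L])
      f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (anyNA(f) || !length(f) %in% c(1L, 3L)) {
        stop("malformed chain data line in record ", h[13L], ": ", lines[i])
      }
      sizes <- c(sizes, f[1L])
      i <- i + 1L
      if (length(f) == 1L) { dts <- c(dts, 0); dqs <- c(dqs, 0); break }
      dts <- c(dts, f[2L]); dqs <- c(dqs, f[3L])
    }
    rec <- structure(list(
      score = as.numeric(h[2L]), tname = h[3L], tsize = as.numeric(h[4L]),
      tstrand = h[5L], tstart = as.numeric(h[6L]), tend = as.numeric(h[7L]),
      qname = h[8L], qsize = as.numeric(h[9L]), qstrand = h[10L],
      qstart = as.numeric(h[11L]), qend = as.numeric(h[12L]), id = h[13L],
      blocks = data.frame(size = sizes, dt = dts, dq = dqs)), class = "chain_record")
    validate_chain_record(rec)
    if (rec$tstrand == "-") rec <- chain_flip_target(rec)
    recs[[length(recs) + 1L]] <- rec
  }
  structure(recs, class = "chain")
}

validate_chain_record <- function(rec) {
  bl <- rec$blocks
  if (any(bl$size < 1)) stop("chain record ", rec$id, ": block size < 1")
  if (any(bl$dt < 0) || any(bl$dq < 0)) stop("chain record ", rec$id, ": negative gap")
  if (sum(bl$size) + sum(bl$dt) != rec$tend - rec$tstart) {
    stop("chain record ", rec$id, ": target sum invariant violated (",
         sum(bl$size) + sum(bl$dt), " != ", rec$tend - rec$tstart, ")")
  }
  if (sum(bl$size) + sum(bl$dq) != rec$qend - rec$qstart) {
    stop("chain record ", rec$id, ": query sum invariant violated (",
         sum(bl$size) + sum(bl$dq), " != ", rec$qend - rec$qstart, ")")
  }
  invisible(rec)
}

# reverse the alignment walk so the target is on '+'
chain_flip_target <- function(rec) {
  nb <- nrow(rec$blocks)
  bl <- rec$blocks
  new <- data.frame(size = rev(bl$size),
                    dt = c(rev(bl$dt[-nb]), 0),
                    dq = c(rev(bl$dq[-nb]), 0))
  flip <- function(strand) if (strand == "+") "-" else "+"
  rec2 <- rec
  rec2$tstrand <- "+"
  rec2$tstart <- rec$tsize - rec$tend
  rec2$tend <- rec$tsize - rec$tstart
  rec2$qstrand <- flip(rec$qstrand)
  rec2$qstart <- rec$qsize - rec$qend
  rec2$qend <- rec$qsize - rec$qstart
  rec2$blocks <- new
  rec2
}

#' Write chain records
#'
#' Reproduces the UCSC layout: single-space-separated header, then one
#' tab-separated `size dt dq` line per block with a final size-only
#' line, then a blank line.
#'
#' @param chain a `chain` object or list of `chain_record`s.
#' @param path output file, or `""` for stdout.
#' @export
write_chain <- function(chain, path = "") {
  out <- unlist(lapply(unclass(chain), function(rec) {
    validate_chain_record(rec)
    bl <- rec$blocks
    nb <- nrow(bl)
    body <- if (nb > 1L) {
      c(paste(fmt_num(bl$size[-nb]), fmt_num(bl$dt[-nb]), fmt_num(bl$dq[-nb]),
              sep = "\t"),
        fmt_num(bl$size[nb]))
    } else {
      fmt_num(bl$size)
    }
    c(paste("chain", fmt_num(rec$score), rec$tname, fmt_num(rec$tsize), "+",
            fmt_num(rec$tstart), fmt_num(rec$tend), rec$qname,
            fmt_num(rec$qsize), rec$qstrand, fmt_num(rec$qstart),
            fmt_num(rec$qend), rec$id),
      body, "")
  }))
  write_text_lines(out, path)
}

#' Convert a chain record to the canonical pairwise model
#'
#' Blocks become `M` runs (a chain carries no base-level detail), `dt`
#' becomes `D` and `dq` becomes `I` (`D` emitted before `I` inside a
#' mixed gap). Strand-relative query coordinates are mapped to the
#' forward strand.
#'
#' @param rec a `chain_record`.
#' @return A [pairwise_block()] with an `M`/`I`/`D` cigar.
#' @export
chain_record_to_block <- function(rec) {
  bl <- rec$blocks
  op <- character(0)
  len <- numeric(0)
  for (j in seq_len(nrow(bl))) {
    op <- c(op, "M", "D", "I")
    len <- c(len, bl$size[j], bl$dt[j], bl$dq[j])
  }
  cig <- cigar(op, len, drop_zero = TRUE)
  qstart_fwd <- if (rec$qstrand == "+") rec$qstart else rec$qsize - rec$qend
  qend_fwd <- if (rec$qstrand == "+") rec$qend else rec$qsize - rec$qstart
  pairwise_block(rec$tname, rec$tsize, rec$tstart, rec$tend,
                 rec$qname, rec$qsize, rec$qstrand, qstart_fwd, qend_fwd,
                 cig = cig, score = rec$score)
}

#' Convert a pairwise block to a chain record
#'
#' Maximal runs of `=`/`X`/`M` become ungapped block sizes; `I`
#' contributes `dq` and `D` contributes `dt`, with adjacent `I` and `D`
#' runs merged into one triple. A cigar beginning or ending with an
#' indel is trimmed into the coordinates with a warning, since a chain
#' must start and end with a block. The score is the carried block
#' score when present, else the match count when `=`/`X` resolution is
#' available, else the summed block sizes.
#'
#' @param b a [pairwise_block()].
#' @param id chain id (assigned 1, 2, 3, ... in input order by
#'   [blocks_to_chain()]).
#' @return A `chain_record`.
#' @export
block_to_chain_record <- function(b, id = 1L) {
  b <- block_ensure_cigar(b)
  op <- b$cigar$op
  len <- b$cigar$len
  tstart <- b$tstart; tend <- b$tend
  qstart <- b$qstart; qend <- b$qend
  trimmed <- FALSE
  while (length(op) && op[1L] %in% c("I", "D")) {
    if (op[1L] == "D") tstart <- tstart + len[1L]
    else if (b$qstrand == "+") qstart <- qstart + len[1L]
    else qend <- qend - len[1L]
    op <- op[-1L]; len <- len[-1L]; trimmed <- TRUE
  }
  while (length(op) && op[length(op)] %in% c("I", "D")) {
    k <- length(op)
    if (op[k] == "D") tend <- tend - len[k]
    else if (b$qstrand == "+") qend <- qend - len[k]
    else qstart <- qstart + len[k]
    op <- op[-k]; len <- len[-k]; trimmed <- TRUE
  }
  if (trimmed) {
    warning("boundary indel(s) trimmed into the coordinates of chain ", id,
            " (a chain must start and end with an ungapped block)")
  }
  if (!length(op)) stop("cigar has no aligned block; cannot form a chain")
  is_match <- op %in% c("=", "X", "M")
  grp <- cumsum(c(TRUE, is_match[-1L] != is_match[-length(is_match)]))
  sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
  for (g in unique(grp)) {
    sel <- grp == g
    if (is_match[sel][1L]) {
      sizes <- c(sizes, sum(len[sel]))
      dts <- c(dts, 0); dqs <- c(dqs, 0)
    } else {
      k <- length(sizes)
      dts[k] <- sum(len[sel & op == "D"])
      dqs[k] <- sum(len[sel & op == "I"])
    }
  }
  score <- if (!is.na(b$score)) {
    b$score
  } else if (!any(op == "M") || !is.null(b$taln)) {
    block_matches(b)
  } else {
    sum(sizes)
  }
  qstart_rel <- if (b$qstrand == "+") qstart else b$qsize - qend
  qend_rel <- if (b$qstrand == "+") qend else b$qsize - qstart
  rec <- structure(list(
    score = score, tname = b$tname, tsize = b$tsize, tstrand = "+",
    tstart = tstart, tend = tend, qname = b$qname, qsize = b$qsize,
    qstrand = b$qstrand, qstart = qstart_rel, qend = qend_rel,
    id = as.character(id),
    blocks = data.frame(size = sizes, dt = dts, dq = dqs)),
    class = "chain_record")
  validate_chain_record(rec)
}

#' Convert a list of pairwise blocks to a chain, ids in input order
#' @param blocks list of [pairwise_block()]s.
#' @return A `chain` object.
#' @export
blocks_to_chain <- function(blocks) {
  if (inherits(blocks, "pairwise_block")) blocks <- list(blocks)
  structure(mapply(block_to_chain_record, blocks, seq_along(blocks),
                   SIMPLIFY = FALSE),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat("<chain> ", length(x), " record(s)\n", sep = "")
  invisible(x)
}
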