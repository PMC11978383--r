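#' Read a PAF file
#'
#' Parses the 12 mandatory tab-separated columns plus typed
#' `TAG:TYPE:VALUE` optional fields. The `cg:Z:` CIGAR tag is kept as
#' text in the `cg` column (parse it on demand with [cigar_parse()]);
#' all other tags are preserved verbatim in `tags`. Query coordinates
#' are 0-based half-open on the query forward strand; target
#' coordinates on the target forward strand.
#'
#' @param path PAF file (plain or gzip-compressed), `"-"` for stdin, or
#'   a connection.
#' @return A data frame of class `paf` with columns `qname, qlen,
#'   qstart, qend, strand, tname, tlen, tstart, tend, nmatch,
#'   block_len, mapq, cg, tags`.
#' @export
read_paf <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_paf())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 12L)) {
    stop("PAF line ", which(ncols < 12L)[1L], " has ", ncols[ncols < 12L][1L],
         " columns; 12 required")
  }
  col <- function(i) vapply(parts, `[[`, character(1L), i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) stop("non-integer ", what, " in PAF line ", which(is.na(v))[1L])
    v
  }
  strand <- col(5L)
  if (!all(strand %in% c("+", "-"))) stop("bad strand in PAF")
  tagf <- lapply(parts, function(p) if (length(p) > 12L) p[-(1:12)] else character())
  badtag <- vapply(tagf, function(tg) any(!grepl("^[A-Za-z][A-Za-z0-9]:[AifZHB]:", tg)),
                   logical(1L))
  if (any(badtag)) stop("malformed tag in PAF line ", which(badtag)[1L])
  cg <- vapply(tagf, function(tg) {
    hit <- grep("^cg:Z:", tg, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1L]) else NA_character_
  }, character(1L))
  tags <- vapply(tagf, function(tg) {
    rest <- tg[!grepl("^cg:Z:", tg)]
    if (length(rest)) paste(rest, collapse = "\t") else NA_character_
  }, character(1L))
  x <- data.frame(
    qname = col(1L), qlen = num(2L, "qlen"), qstart = num(3L, "qstart"),
    qend = num(4L, "qend"), strand = strand, tname = col(6L),
    tlen = num(7L, "tlen"), tstart = num(8L, "tstart"), tend = num(9L, "tend"),
    nmatch = num(10L, "nmatch"), block_len = num(11L, "block_len"),
    mapq = num(12L, "mapq"), cg = cg, tags = tags, stringsAsFactors = FALSE)
  bad <- !(x$qstart < x$qend & x$qend <= x$qlen &
             x$tstart < x$tend & x$tend <= x$tlen & x$nmatch <= x$block_len)
  if (any(bad)) stop("PAF coordinate invariant violated on line ", which(bad)[1L])
  class(x) <- c("paf", "data.frame")
  x
}

empty_paf <- function() {
  x <- data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
                  qend = numeric(), strand = character(), tname = character(),
                  tlen = numeric(), tstart = numeric(), tend = numeric(),
                  nmatch = numeric(), block_len = numeric(), mapq = numeric(),
                  cg = character(), tags = character(), stringsAsFactors = FALSE)
  class(x) <- c("paf", "data.frame")
  x
}

#' Write PAF records
#'
#' Emits exactly 12 mandatory columns, then the `cg:Z:` tag when
#' present, then any other preserved tags — tab-separated,
#' newline-terminated.
#'
#' @param paf a `paf` data frame ([read_paf()]).
#' @param path output file, or `""` for stdout.
#' @export
write_paf <- function(paf, path = "") {
  if (nrow(paf) == 0L) return(write_text_lines(character(), path))
  lines <- paste(paf$qname, fmt_num(paf$qlen), fmt_num(paf$qstart),
                 fmt_num(paf$qend), paf$strand, paf$tname, fmt_num(paf$tlen),
                 fmt_num(paf$tstart), fmt_num(paf$tend), fmt_num(paf$nmatch),
                 fmt_num(paf$block_len), fmt_num(paf$mapq), sep = "\t")
  has_cg <- !is.na(paf$cg)
  lines[has_cg] <- paste(lines[has_cg], paste0("cg:Z:", paf$cg[has_cg]), sep = "\t")
  has_tags <- !is.na(paf$tags)
  lines[has_tags] <- paste(lines[has_tags], paf$tags[has_tags], sep = "\t")
  write_text_lines(lines, path)
}

#' Convert one PAF record to the canonical pairwise model
#'
#' Requires the `cg` tag; its spans are checked against the coordinate
#' intervals. The resulting block has no aligned strings (reconstruct
#' with [block_ensure_aligned()] when bases are needed).
#'
#' @param paf a `paf` data frame.
#' @param i row index.
#' @return A [pairwise_block()].
#' @export
paf_row_to_block <- function(paf, i = 1L) {
  r <- paf[i, ]
  if (is.na(r$cg)) stop("CIGAR required: PAF record ", i, " has no cg:Z: tag")
  cig <- cigar_parse(r$cg)
  if (cigar_target_span(cig) != r$tend - r$tstart ||
      cigar_query_span(cig) != r$qend - r$qstart) {
    stop("cg spans disagree with PAF coordinates on record ", i)
  }
  pairwise_block(r$tname, r$tlen, r$tstart, r$tend,
                 r$qname, r$qlen, r$strand, r$qstart, r$qend,
                 cig = cig, validate = FALSE)
}

#' Convert PAF records to a list of pairwise blocks
#' @inheritParams paf_row_to_block
#' @return List of [pairwise_block()]s.
#' @export
paf_to_blocks <- function(paf) {
  lapply(seq_len(nrow(paf)), function(i) paf_row_to_block(paf, i))
}

#' Convert pairwise blocks to PAF records
#'
#' `nmatch` is the `=` column count when it can be resolved (from the
#' cigar or the aligned strings); for an opaque all-`M` cigar it falls
#' back to the `M` column count, mirroring how chains are promoted.
#' `mapq` is written as 60 (unknown); `block_len` is the total column
#' count.
#'
#' @param blocks a list of [pairwise_block()]s (or a single block).
#' @return A `paf` data frame, one row per block in input order.
#' @export
blocks_to_paf <- function(blocks) {
  if (inherits(blocks, "pairwise_block")) blocks <- list(blocks)
  if (length(blocks) == 0L) return(empty_paf())
  rows <- lapply(blocks, function(b) {
    b <- block_ensure_cigar(b)
    nmatch <- if (any(b$cigar$op == "M") && is.null(b$taln)) {
      sum(b$cigar$len[b$cigar$op %in% c("=", "M")])
    } else {
      block_matches(b)
    }
    cg <- if (!is.null(b$taln)) cigar_resolve_m(b$cigar, b$taln, b$qaln) else b$cigar
    data.frame(qname = b$qname, qlen = b$qsize, qstart = b$qstart, qend = b$qend,
               strand = b$qstrand, tname = b$tname, tlen = b$tsize,
               tstart = b$tstart, tend = b$tend, nmatch = nmatch,
               block_len = cigar_columns(b$cigar), mapq = 60,
               cg = cigar_render(cg), tags = NA_character_,
               stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, rows)
  class(x) <- c("paf", "data.frame")
  x
}
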