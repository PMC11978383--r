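#' Index a MAF file for region extraction
#'
#' Writes a sidecar TSV `<maf>.idx` with one line per block:
#' `name  start  end  byte_offset`, keyed by the target (first) row in
#' forward coordinates, with `byte_offset` pointing at the block's `a`
#' line. Granularity is per block; sub-block slicing is computed on
#' demand by [maf_extract()]. The sidecar is written atomically
#' (temp file + rename). Compressed MAF cannot be indexed (offsets
#' would not be seekable).
#'
#' @param path a plain-text MAF file.
#' @param idx_path sidecar path, default `<maf>.idx`.
#' @return The index as a data frame (`name,start,end,offset`),
#'   invisibly; side effect is the sidecar file.
#' @export
maf_index <- function(path, idx_path = paste0(path, ".idx")) {
  if (is_gzip_file(path)) {
    stop("cannot index compressed MAF (byte offsets are not seekable): ", path)
  }
  idx <- maf_scan_index(path)
  tmp <- paste0(idx_path, ".tmp")
  writeLines(paste(idx$name, fmt_num(idx$start), fmt_num(idx$end),
                   fmt_num(idx$offset), sep = "\t"), tmp)
  file.rename(tmp, idx_path)
  invisible(idx)
}

# build the per-block index in memory (assumes \n line endings)
maf_scan_index <- function(path) {
  lines <- readLines(path, warn = FALSE)
  offsets <- c(0, cumsum(nchar(lines, type = "bytes") + 1L))
  is_a <- startsWith(lines, "a")
  name <- character(0); start <- numeric(0); end <- numeric(0); off <- numeric(0)
  for (i in which(is_a)) {
    j <- i + 1L
    while (j <= length(lines) && !startsWith(lines[j], "s")) j <- j + 1L
    if (j > length(lines)) stop("truncated MAF block at byte offset ", offsets[i])
    f <- strsplit(trimws(lines[j]), "\\s+")[[1L]]
    s <- as.numeric(f[3L]); w <- as.numeric(f[4L]); ssize <- as.numeric(f[6L])
    fstart <- if (f[5L] == "+") s else ssize - s - w
    name <- c(name, f[2L]); start <- c(start, fstart)
    end <- c(end, fstart + w); off <- c(off, offsets[i])
  }
  data.frame(name = name, start = start, end = end, offset = off,
             stringsAsFactors = FALSE)
}

#' Read a MAF index sidecar
#' @param idx_path the `.idx` file written by [maf_index()].
#' @return A data frame `name,start,end,offset`.
#' @export
read_maf_index <- function(idx_path) {
  x <- utils::read.table(idx_path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("name", "start", "end", "offset"),
                         colClasses = c("character", "numeric", "numeric", "numeric"))
  x
}

#' Parse region strings of the form `name:start-end`
#'
#' CLI regions follow the samtools convention: 1-based, inclusive.
#' They are converted to the internal 0-based half-open frame. A bare
#' `name` selects the whole sequence.
#'
#' @param x character vector of region strings.
#' @return Data frame `name,start,end` (0-based half-open; `end = Inf`
#'   for whole-sequence regions).
#' @export
parse_region <- function(x) {
  out <- lapply(x, function(r) {
    m <- regexec("^(.+):([0-9,]+)-([0-9,]+)$", r)[[1L]]
    if (m[1L] == -1L) {
      if (grepl(":", r)) stop("malformed region string: ", sQuote(r))
      return(data.frame(name = r, start = 0, end = Inf, stringsAsFactors = FALSE))
    }
    g <- regmatches(r, regexec("^(.+):([0-9,]+)-([0-9,]+)$", r))[[1L]]
    s1 <- as.numeric(gsub(",", "", g[3L]))
    e1 <- as.numeric(gsub(",", "", g[4L]))
    if (s1 < 1 || e1 < s1) stop("malformed region string: ", sQuote(r))
    data.frame(name = g[2L], start = s1 - 1, end = e1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read regions from a BED file (0-based half-open)
#' @param path BED3+ file.
#' @return Data frame `name,start,end`.
#' @export
read_bed_regions <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(name = vapply(f, `[[`, character(1L), 1L),
             start = as.numeric(vapply(f, `[[`, character(1L), 2L)),
             end = as.numeric(vapply(f, `[[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

#' Extract MAF blocks overlapping regions
#'
#' Looks up overlapping blocks through the index (built on the fly when
#' no sidecar exists), seeks to each block's byte offset and parses just
#' that block. With `slice = TRUE` blocks are cut to the region by
#' column projection: target-consuming columns inside the region are
#' kept, plus insertion columns anchored at the last in-region target
#' base; every row's strand-relative start and size are recomputed.
#'
#' @param path plain-text MAF file.
#' @param regions a data frame `name,start,end` in 0-based half-open
#'   coordinates ([parse_region()], [read_bed_regions()]), or a
#'   character vector of `name:start-end` strings (1-based inclusive).
#' @param slice cut blocks to the region instead of returning whole
#'   overlapping blocks.
#' @param index optional pre-loaded index data frame.
#' @return A `maf` object. Regions naming absent sequences yield no
#'   blocks, with a warning.
#' @export
maf_extract <- function(path, regions, slice = FALSE, index = NULL) {
  if (is.character(regions)) regions <- parse_region(regions)
  if (is.null(index)) {
    index <- if (file.exists(paste0(path, ".idx"))) {
      read_maf_index(paste0(path, ".idx"))
    } else {
      maf_scan_index(path)
    }
  }
  absent <- setdiff(unique(regions$name), unique(index$name))
  if (length(absent)) {
    warning("region sequence(s) not in MAF: ", paste(absent, collapse = ", "))
  }
  out <- list()
  con <- file(path, open = "rb")
  on.exit(close(con))
  seen <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(regions))) {
    ov <- which(index$name == regions$name[r] &
                  index$start < regions$end[r] &
                  index$end > regions$start[r])
    for (k in ov) {
      key <- as.character(index$offset[k])
      blk <- if (!is.null(seen[[key]])) seen[[key]] else {
        b <- read_maf_block_at(con, index$offset[k])
        seen[[key]] <- b
        b
      }
      out[[length(out) + 1L]] <- if (slice) {
        slice_maf_block(blk, max(regions$start[r], index$start[k]),
                        min(regions$end[r], index$end[k]))
      } else {
        blk
      }
    }
  }
  # de-duplicate whole blocks found by several regions
  if (!slice && length(out) > 1L) out <- unique(out)
  structure(out, class = "maf")
}

# seek to a block's 'a' line and parse until the next blank line / EOF
read_maf_block_at <- function(con, offset) {
  seek(con, where = offset, origin = "start")
  lines <- character(0)
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L || !nzchar(trimws(ln))) break
    lines <- c(lines, ln)
  }
  blocks <- parse_maf_lines(lines)
  if (length(blocks) != 1L) stop("failed to parse MAF block at offset ", offset)
  blocks[[1L]]
}

#' Slice a MAF block to a target interval
#'
#' Keeps the alignment columns whose projected target position lies in
#' `[start, end)` plus insertion columns anchored at the last in-region
#' target base, and recomputes each row's strand-relative start and
#' size. A row left with no bases (e.g. the query fully deleted in the
#' window) is kept with size 0 for coordinate continuity.
#'
#' @param b a `maf_block` (pairwise: 2 rows).
#' @param start,end 0-based half-open target interval.
#' @return A sliced `maf_block`.
#' @export
slice_maf_block <- function(b, start, end) {
  pb <- maf_block_to_pairwise(b)
  m <- cigar_column_targets(pb$cigar, pb$tstart)
  # consuming columns: their own coordinate; I columns: their anchor
  keep <- m$pos >= start & m$pos < end
  if (!any(keep)) stop("region [", start, ",", end, ") selects no columns")
  c0 <- which(keep)[1L]
  c1 <- which(keep)[sum(keep)]
  maf_block_columns(b, c0, c1)
}

# cut a maf_block to 1-based column range [c0, c1], recomputing starts/sizes;
# starts are strand-relative and texts run in the same direction, so the new
# start is the old start plus the bases consumed before the cut
maf_block_columns <- function(b, c0, c1) {
  rows <- b$rows
  nongap <- function(s) nchar(s) - nchar(gsub("[^-]", "", s))
  pre <- substr(rows$text, 1L, c0 - 1L)
  mid <- substr(rows$text, c0, c1)
  newrows <- rows
  newrows$start <- rows$start + nongap(pre)
  newrows$size <- nongap(mid)
  newrows$text <- mid
  structure(list(score = b$score, rows = newrows), class = "maf_block")
}

#' Split MAF blocks into bounded chunks
#'
#' Each block is split at column boundaries into consecutive blocks of
#' at most `max_columns` columns. Row starts and sizes are recomputed
#' (starts are strand-relative, so the update is simply the non-gap
#' count consumed by earlier chunks in text order). Concatenating the
#' chunk row texts reproduces the original texts exactly; a chunk row
#' whose bases are all gaps is kept with size 0.
#'
#' @param maf a `maf` object (any row count per block).
#' @param max_columns maximum columns per chunk, >= 1.
#' @return A `maf` object of chunks in order.
#' @export
maf_chunk <- function(maf, max_columns) {
  stopifnot(max_columns >= 1)
  out <- list()
  for (b in maf) {
    width <- nchar(b$rows$text[1L])
    starts <- seq(1L, width, by = max_columns)
    for (s in starts) {
      out[[length(out) + 1L]] <-
        maf_block_columns(b, s, min(s + max_columns - 1L, width))
    }
  }
  structure(out, class = "maf")
}
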