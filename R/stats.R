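#' Per-block alignment statistics
#'
#' For each block counts alignment columns, matches (`=`), mismatches
#' (`X`), insertion events/bases (`I` runs) and deletion events/bases
#' (`D` runs), and derives two identities:
#' *gap-compressed* `matches / (matches + mismatches)` and *overall*
#' `matches / columns`. The partition identity
#' `matches + mismatches + ins_bases + del_bases == columns` holds on
#' every input. An opaque `M` cigar without bases is an error (the
#' match/mismatch split cannot be known).
#'
#' @param blocks a list of [pairwise_block()]s, a `maf`, `paf` or
#'   `chain` object.
#' @param aggregate append a final `total` row with summed counts and
#'   length-weighted identities.
#' @return A data frame, one row per block: `tname, tstart, tend,
#'   qname, qstrand, qstart, qend, columns, matches, mismatches,
#'   ins_events, ins_bases, del_events, del_bases,
#'   identity_gap_compressed, identity_overall`.
#' @export
block_stats <- function(blocks, aggregate = FALSE) {
  blocks <- as_block_list(blocks)
  rows <- lapply(blocks, function(b) {
    b <- block_ensure_cigar(b)
    if (any(b$cigar$op == "M")) {
      if (is.null(b$taln)) {
        stop("cigar has M runs and no bases; cannot split match/mismatch")
      }
      b$cigar <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
    }
    op <- b$cigar$op; len <- b$cigar$len
    matches <- sum(len[op == "="])
    mism <- sum(len[op == "X"])
    insb <- sum(len[op == "I"])
    delb <- sum(len[op == "D"])
    cols <- sum(len)
    data.frame(tname = b$tname, tstart = b$tstart, tend = b$tend,
               qname = b$qname, qstrand = b$qstrand,
               qstart = b$qstart, qend = b$qend,
               columns = cols, matches = matches, mismatches = mism,
               ins_events = sum(op == "I"), ins_bases = insb,
               del_events = sum(op == "D"), del_bases = delb,
               identity_gap_compressed = matches / (matches + mism),
               identity_overall = matches / cols,
               stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, rows)
  if (aggregate && nrow(x) > 0L) {
    tot <- data.frame(tname = "total", tstart = NA_real_, tend = NA_real_,
                      qname = "total", qstrand = "+",
                      qstart = NA_real_, qend = NA_real_,
                      columns = sum(x$columns), matches = sum(x$matches),
                      mismatches = sum(x$mismatches),
                      ins_events = sum(x$ins_events), ins_bases = sum(x$ins_bases),
                      del_events = sum(x$del_events), del_bases = sum(x$del_bases),
                      identity_gap_compressed =
                        sum(x$matches) / (sum(x$matches) + sum(x$mismatches)),
                      identity_overall = sum(x$matches) / sum(x$columns),
                      stringsAsFactors = FALSE)
    x <- rbind(x, tot)
  }
  x
}

# coerce any of the package's alignment containers to a block list
as_block_list <- function(x) {
  if (inherits(x, "pairwise_block")) return(list(x))
  if (inherits(x, "maf")) return(lapply(x, maf_block_to_pairwise))
  if (inherits(x, "paf")) return(paf_to_blocks(x))
  if (inherits(x, "chain")) return(lapply(x, chain_record_to_block))
  if (is.list(x)) {
    return(lapply(x, function(e) {
      if (inherits(e, "pairwise_block")) e
      else if (inherits(e, "maf_block")) maf_block_to_pairwise(e)
      else if (inherits(e, "chain_record")) chain_record_to_block(e)
      else stop("cannot interpret element as an alignment block")
    }))
  }
  stop("cannot interpret input as alignment blocks")
}

#' Aligned coverage per sequence
#'
#' Merges the aligned intervals on the chosen side (union semantics:
#' duplicated or overlapping blocks never double-count) and reports
#' covered bases and the covered fraction per sequence, plus a
#' genome-wide aggregate row.
#'
#' @param blocks see [block_stats()].
#' @param by `"target"` or `"query"` (query intervals are
#'   forward-strand).
#' @return Data frame `name, size, covered, fraction`, last row
#'   `genome`.
#' @export
coverage <- function(blocks, by = c("target", "query")) {
  by <- match.arg(by)
  blocks <- as_block_list(blocks)
  name <- vapply(blocks, function(b) if (by == "target") b$tname else b$qname,
                 character(1L))
  size <- vapply(blocks, function(b) if (by == "target") b$tsize else b$qsize,
                 numeric(1L))
  start <- vapply(blocks, function(b) if (by == "target") b$tstart else b$qstart,
                  numeric(1L))
  end <- vapply(blocks, function(b) if (by == "target") b$tend else b$qend,
                numeric(1L))
  out <- lapply(unique(name), function(nm) {
    sel <- name == nm
    ir <- IRanges::reduce(IRanges::IRanges(start = start[sel] + 1L, end = end[sel]))
    cov <- sum(IRanges::width(ir))
    data.frame(name = nm, size = size[sel][1L], covered = cov,
               fraction = cov / size[sel][1L], stringsAsFactors = FALSE)
  })
  x <- do.call(rbind, out)
  rbind(x, data.frame(name = "genome", size = sum(x$size),
                      covered = sum(x$covered),
                      fraction = sum(x$covered) / sum(x$size),
                      stringsAsFactors = FALSE))
}

#' Windowed gap divergence along the target
#'
#' Every alignment column is assigned to the target window containing
#' its projected target position (insertion columns anchor at the
#' preceding consumed base; a leading insertion anchors at the block
#' start). Per window the function reports `aligned_cols` (all columns
#' assigned), `mismatch_cols` (`X`) and `gap_cols` (`I` + `D`), and
#' `gap_divergence = (mismatch_cols + gap_cols) / aligned_cols` —
#' `NA` for windows with no aligned columns. With
#' `include_gaps = FALSE` the divergence is mismatch-only,
#' `mismatch_cols / aligned_cols`.
#'
#' @param blocks see [block_stats()]; `M` runs require bases.
#' @param window window size in bp (default 1 Mb).
#' @param include_gaps count indel columns in the divergence numerator.
#' @return Data frame `tname, start, end, aligned_cols, mismatch_cols,
#'   gap_cols, gap_divergence`, windows tiling `[0, tsize)` for every
#'   target sequence seen.
#' @export
gap_divergence <- function(blocks, window = 1e6, include_gaps = TRUE) {
  stopifnot(window >= 1)
  blocks <- as_block_list(blocks)
  acc <- list()
  tsizes <- list()
  for (b in blocks) {
    b <- block_ensure_cigar(b)
    if (any(b$cigar$op == "M")) {
      if (is.null(b$taln)) stop("cigar has M runs and no bases")
      b$cigar <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
    }
    m <- cigar_column_targets(b$cigar, b$tstart)
    pos <- pmax(m$pos, b$tstart)  # leading insertions anchor at block start
    opv <- cigar_expand(b$cigar)
    win <- floor(pos / window)
    key <- paste0(b$tname, "\r", win)
    df <- rowsum(cbind(aligned = rep(1, length(opv)),
                       mism = as.numeric(opv == "X"),
                       gap = as.numeric(opv %in% c("I", "D"))), key)
    acc[[length(acc) + 1L]] <- data.frame(key = rownames(df),
                                          aligned = df[, "aligned"],
                                          mism = df[, "mism"], gap = df[, "gap"],
                                          stringsAsFactors = FALSE)
    tsizes[[b$tname]] <- b$tsize
  }
  agg <- if (length(acc)) {
    a <- do.call(rbind, acc)
    s <- rowsum(cbind(a$aligned, a$mism, a$gap), a$key)
    data.frame(key = rownames(s), aligned = s[, 1L], mism = s[, 2L], gap = s[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(), aligned = numeric(), mism = numeric(),
               gap = numeric(), stringsAsFactors = FALSE)
  }
  out <- list()
  for (nm in names(tsizes)) {
    nwin <- max(1, ceiling(tsizes[[nm]] / window))
    wins <- data.frame(tname = nm, start = (seq_len(nwin) - 1) * window,
                       stringsAsFactors = FALSE)
    wins$end <- pmin(wins$start + window, tsizes[[nm]])
    key <- paste0(nm, "\r", seq_len(nwin) - 1)
    i <- match(key, agg$key)
    wins$aligned_cols <- ifelse(is.na(i), 0, agg$aligned[i])
    wins$mismatch_cols <- ifelse(is.na(i), 0, agg$mism[i])
    wins$gap_cols <- ifelse(is.na(i), 0, agg$gap[i])
    num <- if (include_gaps) wins$mismatch_cols + wins$gap_cols else wins$mismatch_cols
    wins$gap_divergence <- ifelse(wins$aligned_cols > 0,
                                  num / wins$aligned_cols, NA_real_)
    out[[length(out) + 1L]] <- wins
  }
  do.call(rbind, out)
}

#' Filter alignment records by simple predicates
#'
#' A record passes iff it satisfies all supplied predicates; input
#' order is preserved and the kept/dropped counts are reported as a
#' message. Contradictory thresholds are not detected.
#'
#' @param blocks see [block_stats()]; the return keeps the input
#'   container type for `maf`, `paf` and `chain` inputs.
#' @param min_block_columns minimum total alignment columns.
#' @param min_target_span,min_query_span minimum consumed bases.
#' @param min_identity_gap_compressed minimum `matches/(matches+mismatches)`
#'   (requires `=`/`X` resolution when > 0).
#' @param allow,deny sequence-name allow/deny lists applied to both
#'   target and query names.
#' @param quiet suppress the kept/dropped message.
#' @return The surviving records, same container type as the input.
#' @export
filter_records <- function(blocks, min_block_columns = 0,
                           min_target_span = 0, min_query_span = 0,
                           min_identity_gap_compressed = 0,
                           allow = NULL, deny = NULL, quiet = FALSE) {
  stopifnot(min_block_columns >= 0, min_target_span >= 0, min_query_span >= 0,
            min_identity_gap_compressed >= 0, min_identity_gap_compressed <= 1)
  bl <- as_block_list(blocks)
  keep <- vapply(bl, function(b) {
    b <- block_ensure_cigar(b)
    if (cigar_columns(b$cigar) < min_block_columns) return(FALSE)
    if (b$tend - b$tstart < min_target_span) return(FALSE)
    if (b$qend - b$qstart < min_query_span) return(FALSE)
    if (min_identity_gap_compressed > 0) {
      mm <- block_matches(b)
      xx <- sum(b$cigar$len[b$cigar$op == "X"])
      if (!is.null(b$taln)) {
        cg <- cigar_resolve_m(b$cigar, b$taln, b$qaln)
        xx <- sum(cg$len[cg$op == "X"])
      }
      if (mm / (mm + xx) < min_identity_gap_compressed) return(FALSE)
    }
    if (!is.null(allow) && !(b$tname %in% allow && b$qname %in% allow)) return(FALSE)
    if (!is.null(deny) && (b$tname %in% deny || b$qname %in% deny)) return(FALSE)
    TRUE
  }, logical(1L))
  if (!quiet) {
    message("filter: kept ", sum(keep), " of ", length(keep), " record(s)")
  }
  if (inherits(blocks, "paf")) {
    x <- blocks[keep, , drop = FALSE]
    class(x) <- c("paf", "data.frame")
    return(x)
  }
  if (inherits(blocks, "maf") || inherits(blocks, "chain")) {
    return(structure(unclass(blocks)[keep], class = class(blocks)[1L]))
  }
  bl[keep]
}
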