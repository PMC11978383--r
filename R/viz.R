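#' Decompose alignments into dotplot segments
#'
#' Each maximal run of aligned columns (`=`, `X`, `M`) uninterrupted by
#' an indel of at least `break_at_indel_ge` bases becomes one segment;
#' smaller indels are absorbed into the segment (so its target and
#' query widths may differ). Segment identity is the fraction of
#' aligned columns that match, counting opaque `M` columns as matches.
#' Coordinates are forward-strand on both axes; minus-strand segments
#' carry `strand == "-"` and are drawn with descending query geometry
#' by [render_svg()].
#'
#' @param blocks see [block_stats()].
#' @param break_at_indel_ge indel length (bp) that breaks a segment;
#'   default 1 (every indel breaks).
#' @return Data frame `tname, tstart, tend, qname, qstart, qend,
#'   strand, identity`.
#' @export
dot_segments <- function(blocks, break_at_indel_ge = 1) {
  stopifnot(break_at_indel_ge >= 1)
  blocks <- as_block_list(blocks)
  out <- lapply(blocks, function(b) {
    b <- block_ensure_cigar(b)
    op <- b$cigar$op
    len <- b$cigar$len
    segs <- list()
    t0 <- 0; q0 <- 0      # consumed offsets at segment start (alignment frame)
    t <- 0; q <- 0        # running consumed offsets
    matches <- 0; aln_cols <- 0
    open <- FALSE
    close_seg <- function() {
      if (!open) return()
      segs[[length(segs) + 1L]] <<- data.frame(
        t0 = t0, t1 = t, q0 = q0, q1 = q,
        identity = if (aln_cols > 0) matches / aln_cols else NA_real_)
      open <<- FALSE
    }
    for (i in seq_along(op)) {
      o <- op[i]; l <- len[i]
      if (o %in% c("=", "X", "M")) {
        if (!open) { t0 <- t; q0 <- q; matches <- 0; aln_cols <- 0; open <- TRUE }
        t <- t + l; q <- q + l
        aln_cols <- aln_cols + l
        if (o != "X") matches <- matches + l
      } else {
        if (l >= break_at_indel_ge) close_seg()
        if (o == "D") t <- t + l else q <- q + l
      }
    }
    close_seg()
    if (!length(segs)) return(NULL)
    s <- do.call(rbind, segs)
    qstart_fwd <- if (b$qstrand == "+") b$qstart + s$q0 else b$qend - s$q1
    qend_fwd <- if (b$qstrand == "+") b$qstart + s$q1 else b$qend - s$q0
    data.frame(tname = b$tname, tstart = b$tstart + s$t0, tend = b$tstart + s$t1,
               qname = b$qname, qstart = qstart_fwd, qend = qend_fwd,
               strand = b$qstrand, identity = s$identity,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    return(data.frame(tname = character(), tstart = numeric(), tend = numeric(),
                      qname = character(), qstart = numeric(), qend = numeric(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Render dotplot segments to a static SVG document
#'
#' Deterministic output: the same segments and options always produce
#' byte-identical SVG. Target sequences are laid out left to right on
#' the x axis and query sequences bottom to top on the y axis, each
#' scaled to its length; one `<line>` element is emitted per segment,
#' with minus-strand segments in a second colour and descending query
#' geometry. An empty segment table yields an empty plot with axes.
#'
#' @param segments a data frame from [dot_segments()].
#' @param width,height canvas size in px.
#' @param t_sizes,q_sizes optional named vectors of sequence lengths;
#'   defaults to the maximum end seen per name.
#' @param path optional output file.
#' @return The SVG document as a character scalar (invisibly when
#'   `path` is given).
#' @export
render_svg <- function(segments, width = 800, height = 600,
                       t_sizes = NULL, q_sizes = NULL, path = NULL) {
  margin <- 60
  axis_sizes <- function(given, names_seen, ends) {
    if (is.null(given)) {
      given <- vapply(split(ends, names_seen), max, numeric(1L))
    }
    given[order(names(given))]
  }
  tsz <- if (nrow(segments)) {
    axis_sizes(t_sizes, segments$tname, segments$tend)
  } else if (!is.null(t_sizes)) t_sizes[order(names(t_sizes))] else numeric(0)
  qsz <- if (nrow(segments)) {
    axis_sizes(q_sizes, segments$qname, segments$qend)
  } else if (!is.null(q_sizes)) q_sizes[order(names(q_sizes))] else numeric(0)
  toff <- c(0, cumsum(tsz))[seq_along(tsz)]
  names(toff) <- names(tsz)
  qoff <- c(0, cumsum(qsz))[seq_along(qsz)]
  names(qoff) <- names(qsz)
  tw <- max(sum(tsz), 1)
  qw <- max(sum(qsz), 1)
  px <- function(v) sprintf("%.2f", margin + v / tw * (width - 2 * margin))
  py <- function(v) sprintf("%.2f", height - margin - v / qw * (height - 2 * margin))
  doc <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<rect x="%s" y="%s" width="%.2f" height="%.2f" fill="none" stroke="#333333" stroke-width="1"/>',
            px(0), py(qw), width - 2 * margin, height - 2 * margin),
    # sequence boundary rules and axis labels
    if (length(tsz) > 1L) sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="0.5"/>',
                                  px(cumsum(tsz)[-length(tsz)]), py(0),
                                  px(cumsum(tsz)[-length(tsz)]), py(qw)),
    if (length(qsz) > 1L) sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-width="0.5"/>',
                                  px(0), py(cumsum(qsz)[-length(qsz)]),
                                  px(tw), py(cumsum(qsz)[-length(qsz)])),
    if (length(tsz)) sprintf('<text x="%s" y="%.2f" font-size="10" text-anchor="middle">%s</text>',
                             px(unname(toff + tsz / 2)), height - margin + 15, names(tsz)),
    if (length(qsz)) sprintf('<text x="%.2f" y="%s" font-size="10" text-anchor="end">%s</text>',
                             margin - 5, py(unname(qoff + qsz / 2)), names(qsz)))
  if (nrow(segments)) {
    x1 <- segments$tstart + toff[segments$tname]
    x2 <- segments$tend + toff[segments$tname]
    fwd <- segments$strand == "+"
    y1 <- ifelse(fwd, segments$qstart, segments$qend) + qoff[segments$qname]
    y2 <- ifelse(fwd, segments$qend, segments$qstart) + qoff[segments$qname]
    col <- ifelse(fwd, "#1f77b4", "#d62728")
    doc <- c(doc, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
                          px(x1), py(y1), px(x2), py(y2), col))
  }
  doc <- c(doc, "</svg>")
  svg <- paste(doc, collapse = "\n")
  if (!is.null(path)) {
    write_text_lines(svg, path)
    return(invisible(svg))
  }
  svg
}
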