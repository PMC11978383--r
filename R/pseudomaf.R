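#' Build a reference-projected pseudo-MAF matrix
#'
#' Projects one pairwise alignment set per sample onto a shared
#' reference interval: one matrix column per reference base, insertion
#' columns relative to the reference dropped. Each cell holds the
#' aligned query base, `-` when the reference base is deleted in that
#' sample, or `*` when the position is unaligned. Overlapping blocks of
#' a sample are resolved most-matches-wins, ties broken by input order
#' (the earlier block wins).
#'
#' @param samples named list; each element is a set of alignments for
#'   one sample (a `maf` object, a list of [pairwise_block()]s with
#'   aligned strings, ...), all with the reference as target.
#' @param ref_name reference sequence name; every block's `tname` must
#'   equal it.
#' @param start,end reference interval, 0-based half-open.
#' @param ref_fasta the reference genome (path, named character vector
#'   or `DNAStringSet`).
#' @return An object of class `pseudo_maf`: list with `ref_name`,
#'   `start`, `end`, `ref_seq` and `rows`, a named character vector of
#'   per-sample strings of length `end - start`.
#' @export
pseudo_maf <- function(samples, ref_name, start, end, ref_fasta) {
  stopifnot(is.list(samples), length(names(samples)) == length(samples))
  ref_fasta <- as_fasta(ref_fasta)
  ref_seq <- fasta_fetch(ref_fasta, ref_name, start, end, "+")
  width <- end - start
  rows <- vapply(samples, function(aln) {
    blocks <- lapply(as_block_list(aln), function(b) {
      if (b$tname != ref_name) {
        stop("target name mismatch: block targets ", sQuote(b$tname),
             ", expected ", sQuote(ref_name))
      }
      if (is.null(b$qaln)) {
        stop("pseudo-MAF needs query bases; blocks must carry aligned strings")
      }
      b
    })
    nmatch <- vapply(blocks, block_matches, numeric(1L))
    ord <- order(-nmatch)  # stable: ties keep input order
    cells <- rep("*", width)
    for (b in blocks[ord]) {
      m <- cigar_column_targets(block_ensure_cigar(b)$cigar, b$tstart)
      qc <- strsplit(b$qaln, "", fixed = TRUE)[[1L]]
      sel <- m$consumes & m$pos >= start & m$pos < end
      at <- m$pos[sel] - start + 1L
      unset <- cells[at] == "*"
      cells[at[unset]] <- qc[sel][unset]
    }
    paste(cells, collapse = "")
  }, character(1L))
  structure(list(ref_name = ref_name, start = start, end = end,
                 ref_seq = ref_seq, rows = rows),
            class = "pseudo_maf")
}

#' @export
print.pseudo_maf <- function(x, ...) {
  cat(sprintf("<pseudo_maf> %s:[%s,%s) %d sample(s)\n", x$ref_name,
              fmt_num(x$start), fmt_num(x$end), length(x$rows)))
  invisible(x)
}

#' Write a pseudo-MAF matrix as a degenerate MAF
#'
#' One block: the reference row followed by one row per sample, all on
#' `+` with start = the interval start. Sample rows may contain the
#' non-standard `*` (unaligned) character — hence "pseudo"-MAF.
#'
#' @param pm a [pseudo_maf()].
#' @param path output file, or `""` for stdout.
#' @export
write_pseudo_maf <- function(pm, path = "") {
  width <- pm$end - pm$start
  nongap <- function(s) nchar(s) - nchar(gsub("[^-]", "", s))
  rows <- data.frame(
    src = c(pm$ref_name, names(pm$rows)),
    start = pm$start,
    size = c(width, nongap(pm$rows)),
    strand = "+",
    src_size = width + pm$start,  # lower bound; true sizes are not tracked
    text = c(pm$ref_seq, unname(pm$rows)),
    stringsAsFactors = FALSE)
  out <- c("##maf version=1 program=pseudo_maf",
           paste0("a score=0"),
           sprintf("s %s %s %s %s %s %s", rows$src, fmt_num(rows$start),
                   fmt_num(rows$size), rows$strand, fmt_num(rows$src_size),
                   rows$text),
           "")
  write_text_lines(out, path)
}

#' Per-base conservation scores from a pseudo-MAF matrix
#'
#' For every reference position counts the samples whose base equals
#' the reference base (case-insensitive). `-` (deleted) and `*`
#' (unaligned) count as non-matching; `*` is additionally tallied as
#' unaligned, so `n_aligned` is the number of samples covering the
#' position (aligned base or deletion). The score denominator is the
#' total number of samples by default, or `n_aligned` with
#' `aligned_only = TRUE` (`NA` where no sample aligns).
#'
#' @param pm a [pseudo_maf()] with at least one sample.
#' @param aligned_only divide by `n_aligned` instead of the sample
#'   count.
#' @return Data frame `pos` (0-based reference coordinate), `ref`,
#'   `n_aligned`, `n_match`, `score`.
#' @export
conservation <- function(pm, aligned_only = FALSE) {
  nsamp <- length(pm$rows)
  if (nsamp == 0L) stop("no samples in pseudo-MAF matrix")
  width <- pm$end - pm$start
  refc <- toupper(strsplit(pm$ref_seq, "", fixed = TRUE)[[1L]])
  n_match <- integer(width)
  n_aligned <- integer(width)
  for (s in pm$rows) {
    sc <- toupper(strsplit(s, "", fixed = TRUE)[[1L]])
    n_aligned <- n_aligned + (sc != "*")
    n_match <- n_match + (sc == refc & sc != "*" & sc != "-")
  }
  score <- if (aligned_only) {
    ifelse(n_aligned > 0L, n_match / n_aligned, NA_real_)
  } else {
    n_match / nsamp
  }
  data.frame(pos = seq_len(width) - 1L + pm$start, ref = refc,
             n_aligned = n_aligned, n_match = n_match, score = score,
             stringsAsFactors = FALSE)
}
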