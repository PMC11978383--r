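# Worked fixture used throughout: a 10-column alignment with one
# mismatch and one insertion, every derived value computed by an
# independent hand column-walk before implementation.
#
#   target ACGTTGCA-T   [0,9) of t.chr1 (9 bp)
#   query  ACGATGCAGT   [0,10) of q.chr1 (10 bp), '+'
#   cigar 3=1X4=1I1= ; matches 8, mismatch 1 (t pos 3), insertion G after t pos 7

fx_taln <- "ACGTTGCA-T"
fx_qaln <- "ACGATGCAGT"
fx_tseq <- "ACGTTGCAT"
fx_qseq <- "ACGATGCAGT"
fx_tfa <- c(t.chr1 = fx_tseq)
fx_qfa <- c(q.chr1 = fx_qseq)

fixture_block <- function() {
  pairwise_block("t.chr1", 9, 0, 9, "q.chr1", 10, "+", 0, 10,
                 cig = cigar_from_aligned(fx_taln, fx_qaln),
                 taln = fx_taln, qaln = fx_qaln)
}

fixture_maf_text <- c(
  "##maf version=1",
  "a score=0",
  "s t.chr1 0 9 + 9 ACGTTGCA-T",
  "s q.chr1 0 10 + 10 ACGATGCAGT",
  "")

fixture_paf_line <- "q.chr1\t10\t0\t10\t+\tt.chr1\t9\t0\t9\t8\t10\t60\tcg:Z:3=1X4=1I1="

fixture_chain_text <- c(
  "chain 8 t.chr1 9 + 0 9 q.chr1 10 + 0 10 1",
  "8\t0\t1",
  "1",
  "")

write_fixture_maf <- function(path = tempfile(fileext = ".maf")) {
  writeLines(fixture_maf_text, path)
  path
}

write_fixture_paf <- function(path = tempfile(fileext = ".paf")) {
  writeLines(fixture_paf_line, path)
  path
}

write_fixture_chain <- function(path = tempfile(fileext = ".chain")) {
  writeLines(fixture_chain_text, path)
  path
}

revcomp_str <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Random pairwise block with genomes, for round-trip properties.
# The cigar starts and ends with '=' (chain-compatible boundaries) and
# never repeats an op kind, so it is normalized by construction.
random_block <- function(seed, tname = "t1", qname = "q1") {
  set.seed(seed)
  DNA <- c("A", "C", "G", "T")
  nops <- sample(3:12, 1L)
  ops <- character(0)
  lens <- integer(0)
  last <- ""
  for (i in seq_len(nops)) {
    choices <- if (i == 1L || i == nops) "=" else setdiff(c("=", "X", "I", "D"), last)
    o <- if (length(choices) == 1L) choices else sample(choices, 1L)
    ops <- c(ops, o)
    lens <- c(lens, sample(1:6, 1L))
    last <- o
  }
  cig <- cigar(ops, lens)
  opv <- cigar_expand(cig)
  tcol <- rep("-", length(opv))
  qcol <- rep("-", length(opv))
  tcol[opv != "I"] <- sample(DNA, sum(opv != "I"), replace = TRUE)
  qcol[opv == "="] <- tcol[opv == "="]
  qcol[opv == "X"] <- vapply(tcol[opv == "X"],
                             function(x) sample(setdiff(DNA, x), 1L),
                             character(1L), USE.NAMES = FALSE)
  qcol[opv == "I"] <- sample(DNA, sum(opv == "I"), replace = TRUE)
  taln <- paste(tcol, collapse = "")
  qaln <- paste(qcol, collapse = "")
  tspan <- cigar_target_span(cig)
  qspan <- cigar_query_span(cig)
  tstart <- sample(0:10, 1L)
  tpad <- sample(0:10, 1L)
  qstart <- sample(0:10, 1L)
  qpad <- sample(0:10, 1L)
  qstrand <- sample(c("+", "-"), 1L)
  tsize <- tstart + tspan + tpad
  qsize <- qstart + qspan + qpad
  b <- pairwise_block(tname, tsize, tstart, tstart + tspan,
                      qname, qsize, qstrand, qstart, qstart + qspan,
                      cig = cig, taln = taln, qaln = qaln)
  tgenome <- paste(sample(DNA, tsize, replace = TRUE), collapse = "")
  substr(tgenome, tstart + 1L, tstart + tspan) <- ungap(taln)
  qseg_fwd <- if (qstrand == "+") ungap(qaln) else revcomp_str(ungap(qaln))
  qgenome <- paste(sample(DNA, qsize, replace = TRUE), collapse = "")
  substr(qgenome, qstart + 1L, qstart + qspan) <- qseg_fwd
  list(block = b,
       tfa = stats::setNames(tgenome, tname),
       qfa = stats::setNames(qgenome, qname))
}

expect_blocks_equal <- function(a, b) {
  expect_equal(a$tname, b$tname)
  expect_equal(a$tsize, b$tsize)
  expect_equal(a$tstart, b$tstart)
  expect_equal(a$tend, b$tend)
  expect_equal(a$qname, b$qname)
  expect_equal(a$qsize, b$qsize)
  expect_equal(a$qstrand, b$qstrand)
  expect_equal(a$qstart, b$qstart)
  expect_equal(a$qend, b$qend)
  expect_equal(cigar_render(a$cigar), cigar_render(b$cigar))
  expect_equal(a$taln, b$taln)
  expect_equal(a$qaln, b$qaln)
}

variant_key <- function(v) {
  if (nrow(v) == 0L) return(character(0))
  sort(paste(v$chrom, v$pos, v$ref, v$alt, v$kind, sep = "|"))
}

parse_maf_text <- function(lines) {
  suppressWarnings(wgakit:::parse_maf_lines(lines))
}

# Rewrite every maximal indel run as D-total then I-total: the canonical
# form a chain triple can represent. The chain edge preserves cigars only
# up to this reordering (plus the =/X -> M coarsening).
canonical_gaps <- function(cg) {
  cig <- cigar_parse(cg)
  op <- cig$op
  len <- cig$len
  isgap <- op %in% c("I", "D")
  r <- rle(isgap)
  newop <- character(0)
  newlen <- numeric(0)
  idx <- 1L
  for (k in seq_along(r$lengths)) {
    sel <- idx:(idx + r$lengths[k] - 1L)
    idx <- idx + r$lengths[k]
    if (!r$values[k]) {
      newop <- c(newop, op[sel])
      newlen <- c(newlen, len[sel])
    } else {
      d <- sum(len[sel][op[sel] == "D"])
      i <- sum(len[sel][op[sel] == "I"])
      if (d > 0) { newop <- c(newop, "D"); newlen <- c(newlen, d) }
      if (i > 0) { newop <- c(newop, "I"); newlen <- c(newlen, i) }
    }
  }
  cigar_render(cigar(newop, newlen))
}
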