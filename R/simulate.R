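#' Configuration for the genome-pair simulator
#'
#' @param length target genome length (bp).
#' @param snp_rate,ins_rate,del_rate per-base event probabilities; their
#'   sum must be below 1.
#' @param indel_len_p geometric length parameter in (0, 1]; indel run
#'   lengths are `rgeom(indel_len_p) + 1` (memoryless, the standard
#'   simulator choice), so `indel_len_p = 1` gives 1 bp indels.
#' @param sv_count,sv_len optional planted long indels: `sv_count`
#'   events of exactly `sv_len` bp, alternating insertion/deletion,
#'   evenly spaced along the genome (they override nearby random
#'   events).
#' @param seed integer RNG seed; the same configuration always yields
#'   byte-identical output.
#' @param tname,qname sequence names for the pair.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(length, snp_rate = 0, ins_rate = 0, del_rate = 0,
                       indel_len_p = 0.5, sv_count = 0, sv_len = 0,
                       seed = 1, tname = "target", qname = "query") {
  stopifnot(length >= 1,
            snp_rate >= 0, snp_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1,
            snp_rate + ins_rate + del_rate < 1,
            indel_len_p > 0, indel_len_p <= 1,
            sv_count >= 0, sv_count == 0 || sv_len >= 1)
  structure(list(length = length, snp_rate = snp_rate, ins_rate = ins_rate,
                 del_rate = del_rate, indel_len_p = indel_len_p,
                 sv_count = sv_count, sv_len = sv_len, seed = as.integer(seed),
                 tname = tname, qname = qname),
            class = "sim_config")
}

#' Simulate a genome pair with planted variants and an exact truth set
#'
#' The target is drawn uniformly over A/C/G/T from the seeded
#' generator. Each base may host a substitution, an insertion (after
#' the base) or a deletion (starting at the base) with the configured
#' probabilities; indel lengths are geometric. Planted events are
#' forced non-adjacent (at least 2 bp of untouched sequence between
#' events, by rejection), so truth comparison after left-normalization
#' needs no haplotype realignment. The editing trace *is* the
#' alignment: the returned [pairwise_block()] and truth variant table
#' are exact by construction, which makes the simulator the ground
#' truth generator for every other module.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_pair`: `config`, `target` and `query`
#'   (plain strings), `block` (a [pairwise_block()] with aligned
#'   strings and an `=`/`X`/`I`/`D` cigar) and `truth` (a `variants`
#'   data frame as produced by [call_variants()], already
#'   left-normalized anchors at the planting site).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  DNA <- c("A", "C", "G", "T")
  L <- cfg$length
  tchars <- sample(DNA, L, replace = TRUE)
  u <- stats::runif(L)
  ps <- cfg$snp_rate; pi_ <- cfg$ins_rate; pd <- cfg$del_rate
  kind <- character(L)
  kind[u < ps] <- "SNP"
  kind[u >= ps & u < ps + pi_] <- "INS"
  kind[u >= ps + pi_ & u < ps + pi_ + pd] <- "DEL"
  pos <- which(nzchar(kind))
  pos <- pos[pos >= 2L & pos <= L - 2L]
  ev <- data.frame(pos = pos, kind = kind[pos], len = rep(1, length(pos)),
                   stringsAsFactors = FALSE)
  is_indel <- ev$kind != "SNP"
  if (any(is_indel)) {
    ev$len[is_indel] <- stats::rgeom(sum(is_indel), cfg$indel_len_p) + 1
  }
  if (cfg$sv_count > 0) {
    svpos <- round(L * seq_len(cfg$sv_count) / (cfg$sv_count + 1))
    svpos <- pmin(pmax(svpos, 2L), L - cfg$sv_len - 1L)
    sv <- data.frame(pos = svpos,
                     kind = rep(c("INS", "DEL"), length.out = cfg$sv_count),
                     len = cfg$sv_len, stringsAsFactors = FALSE)
    # SVs override random events in their exclusion zone
    near_sv <- vapply(ev$pos, function(p) {
      any(abs(p - sv$pos) <= cfg$sv_len + 2L)
    }, logical(1L))
    ev <- rbind(ev[!near_sv, , drop = FALSE], sv)
    ev <- ev[order(ev$pos), , drop = FALSE]
  }
  # rejection pass: >= 2 bp untouched between consecutive kept events
  keep_pos <- numeric(0); keep_kind <- character(0); keep_len <- numeric(0)
  next_ok <- 2
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]; k <- ev$kind[i]; l <- ev$len[i]
    if (p < next_ok) next
    if (k == "DEL" && p + l - 1 > L - 1) next  # must leave a trailing match base
    if (k == "INS" && p > L - 1) next
    keep_pos <- c(keep_pos, p); keep_kind <- c(keep_kind, k)
    keep_len <- c(keep_len, l)
    next_ok <- if (k == "DEL") p + l + 2 else p + 2
  }
  # walk the edit trace, building cigar, query and truth simultaneously
  ops <- character(0); lens <- numeric(0)
  qp <- character(0)    # query pieces (ungapped)
  truth <- list()
  cur <- 1
  emit <- function(op, len) {
    ops <<- c(ops, op); lens <<- c(lens, len)
  }
  for (i in seq_along(keep_pos)) {
    p <- keep_pos[i]; k <- keep_kind[i]; l <- keep_len[i]
    if (k == "SNP") {
      if (p > cur) {
        emit("=", p - cur)
        qp <- c(qp, paste(tchars[cur:(p - 1)], collapse = ""))
      }
      alt <- sample(DNA[DNA != tchars[p]], 1L)
      emit("X", 1)
      qp <- c(qp, alt)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = cfg$tname, pos = p, ref = tchars[p], alt = alt, kind = "SNP",
        svlen = 0, end = p, stringsAsFactors = FALSE)
      cur <- p + 1
    } else if (k == "INS") {
      emit("=", p - cur + 1)
      qp <- c(qp, paste(tchars[cur:p], collapse = ""))
      ins <- paste(sample(DNA, l, replace = TRUE), collapse = "")
      emit("I", l)
      qp <- c(qp, ins)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = cfg$tname, pos = p, ref = tchars[p],
        alt = paste0(tchars[p], ins), kind = "INS",
        svlen = l, end = p, stringsAsFactors = FALSE)
      cur <- p + 1
    } else {
      if (p > cur) {
        emit("=", p - cur)
        qp <- c(qp, paste(tchars[cur:(p - 1)], collapse = ""))
      }
      emit("D", l)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = cfg$tname, pos = p - 1,
        ref = paste(tchars[(p - 1):(p + l - 1)], collapse = ""),
        alt = tchars[p - 1], kind = "DEL",
        svlen = -l, end = p - 1 + l, stringsAsFactors = FALSE)
      cur <- p + l
    }
  }
  emit("=", L - cur + 1)
  qp <- c(qp, paste(tchars[cur:L], collapse = ""))
  cig <- cigar(ops, lens)
  target <- paste(tchars, collapse = "")
  query <- paste(qp, collapse = "")
  # gapped rows from the same trace
  opv <- cigar_expand(cig)
  tcol <- rep("-", length(opv)); qcol <- rep("-", length(opv))
  tcol[opv != "I"] <- tchars
  qcol[opv != "D"] <- strsplit(query, "", fixed = TRUE)[[1L]]
  block <- pairwise_block(
    cfg$tname, L, 0, L, cfg$qname, nchar(query), "+", 0, nchar(query),
    cig = cig, taln = paste(tcol, collapse = ""),
    qaln = paste(qcol, collapse = ""), score = NA_real_, validate = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(chrom = character(), pos = numeric(), ref = character(),
               alt = character(), kind = character(), svlen = numeric(),
               end = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(config = cfg, target = target, query = query,
                 block = block, truth = truth),
            class = "sim_pair")
}

#' Write a simulated pair in every supported format
#'
#' Emits `<prefix>.t.fa`, `<prefix>.q.fa`, `<prefix>.maf`,
#' `<prefix>.paf`, `<prefix>.chain` and `<prefix>.truth.tsv`. The three
#' alignment files are mutually consistent by construction: converting
#' any one into another reproduces it.
#'
#' @param sim a `sim_pair` from [simulate_pair()].
#' @param prefix output path prefix.
#' @return Named character vector of the files written.
#' @export
emit_formats <- function(sim, prefix) {
  cfg <- sim$config
  paths <- c(t_fa = paste0(prefix, ".t.fa"), q_fa = paste0(prefix, ".q.fa"),
             maf = paste0(prefix, ".maf"), paf = paste0(prefix, ".paf"),
             chain = paste0(prefix, ".chain"), truth = paste0(prefix, ".truth.tsv"))
  write_fasta(stats::setNames(c(sim$target), cfg$tname), paths["t_fa"])
  write_fasta(stats::setNames(c(sim$query), cfg$qname), paths["q_fa"])
  write_maf(list(sim$block), paths["maf"])
  write_paf(blocks_to_paf(list(sim$block)), paths["paf"])
  write_chain(blocks_to_chain(list(sim$block)), paths["chain"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' @export
print.sim_pair <- function(x, ...) {
  cat(sprintf("<sim_pair> target %s bp, query %s bp, %d truth variant(s)\n",
              fmt_num(nchar(x$target)), fmt_num(nchar(x$query)), nrow(x$truth)))
  invisible(x)
}
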