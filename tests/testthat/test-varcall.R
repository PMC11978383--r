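test_that("alignment signatures yield the fixture SNP and insertion", {
  v <- call_variants(list(fixture_block()))
  expect_equal(nrow(v), 2L)
  expect_equal(v$kind, c("SNP", "INS"))
  expect_equal(v$pos, c(4, 8))
  expect_equal(v$ref, c("T", "A"))
  expect_equal(v$alt, c("A", "AG"))
  expect_equal(v$svlen, c(0, 1))
  expect_equal(v$qpos, c(4, 9))
  expect_false(any(v$is_sv))
})

test_that("deletion runs anchor on the preceding base", {
  b <- pairwise_block("t", 7, 0, 7, "q", 4, "+", 0, 4,
                      cig = cigar_parse("2=3D2="),
                      taln = "AAGGGTT", qaln = "AA---TT")
  v <- call_variants(list(b))
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 2)
  expect_equal(v$ref, "AGGG")
  expect_equal(v$alt, "A")
  expect_equal(v$svlen, -3)
  expect_equal(v$end, 5)
})

test_that("identity alignments produce no calls", {
  ident <- pairwise_block("t", 6, 0, 6, "q", 6, "+", 0, 6,
                          cig = cigar_parse("6="), taln = "AAAAAA", qaln = "AAAAAA")
  expect_equal(nrow(call_variants(list(ident))), 0L)
})

test_that("calls can be reconstructed from cigar plus FASTAs", {
  paf <- read_paf(write_fixture_paf())
  v <- call_variants(paf, target_fasta = fx_tfa, query_fasta = fx_qfa)
  expect_equal(variant_key(v), variant_key(call_variants(list(fixture_block()))))
  expect_error(call_variants(paf), "supply target_fasta")
})

test_that("every REF string matches the target genome at its position", {
  for (seed in 1:15) {
    rb <- random_block(seed)
    v <- call_variants(list(rb$block))
    if (nrow(v) == 0) next
    g <- rb$tfa[[1]]
    expect_equal(substring(g, v$pos, v$pos + nchar(v$ref) - 1L), v$ref)
    # kind-specific REF/ALT shape invariants
    snp <- v$kind == "SNP"
    expect_true(all(nchar(v$ref[snp]) == 1 & nchar(v$alt[snp]) == 1 &
                      v$ref[snp] != v$alt[snp]))
    ins <- v$kind == "INS"
    expect_true(all(nchar(v$alt[ins]) > 1 & nchar(v$ref[ins]) == 1 &
                      substr(v$alt[ins], 1, 1) == v$ref[ins]))
    del <- v$kind == "DEL"
    expect_true(all(nchar(v$ref[del]) > 1 & nchar(v$alt[del]) == 1 &
                      substr(v$ref[del], 1, 1) == v$alt[del]))
  }
})

test_that("minus-strand blocks are called in target coordinates", {
  # same alignment as the fixture, query presented on '-'
  rb <- random_block(101)
  b <- rb$block
  v1 <- call_variants(list(b))
  # reconstruct the block from cigar + genomes and re-call
  b2 <- pairwise_block(b$tname, b$tsize, b$tstart, b$tend, b$qname, b$qsize,
                       b$qstrand, b$qstart, b$qend, cig = b$cigar)
  v2 <- call_variants(list(b2), target_fasta = rb$tfa, query_fasta = rb$qfa)
  expect_equal(variant_key(v1), variant_key(v2))
})

test_that("indels at or above the length threshold are flagged structural", {
  sim <- simulate_pair(sim_config(5000, sv_count = 2, sv_len = 60, seed = 3))
  v <- call_variants(list(sim$block), sv_min_len = 50)
  expect_equal(sum(v$is_sv), 2L)
  expect_setequal(v$kind[v$is_sv], c("INS", "DEL"))
  expect_equal(abs(v$svlen[v$is_sv]), c(60, 60))
  v2 <- call_variants(list(sim$block), sv_min_len = 61)
  expect_equal(sum(v2$is_sv), 0L)
})

test_that("left-normalization matches brute-force enumeration and is idempotent", {
  # genome CAAAT: deleting any single A gives CAAT; the brute-force
  # leftmost VCF-anchored representation is pos 1 REF=CA ALT=C
  g <- "CAAAT"
  apply_del <- function(pos1) paste0(substr(g, 1, pos1 - 1), substr(g, pos1 + 1, 5))
  results <- vapply(2:4, apply_del, character(1))
  expect_true(all(results == "CAAT"))
  leftmost_deleted <- min(which(vapply(2:4, apply_del, character(1)) == "CAAT")) + 1
  expect_equal(leftmost_deleted, 2)  # so the VCF anchor is base 1

  called <- data.frame(chrom = "c", pos = 3, ref = "AA", alt = "A",
                       kind = "DEL", stringsAsFactors = FALSE)
  n1 <- normalize_variants(called, c(c = g))
  expect_equal(n1$pos, 1)
  expect_equal(n1$ref, "CA")
  expect_equal(n1$alt, "C")
  expect_equal(normalize_variants(n1, c(c = g)), n1)

  # non-repeat context is a fixed point
  fixed <- data.frame(chrom = "c", pos = 2, ref = "AG", alt = "A",
                      kind = "DEL", stringsAsFactors = FALSE)
  expect_equal(normalize_variants(fixed, c(c = "CAGT")), fixed)

  # SNPs pass through untouched
  snp <- data.frame(chrom = "c", pos = 3, ref = "A", alt = "G",
                    kind = "SNP", stringsAsFactors = FALSE)
  expect_equal(normalize_variants(snp, c(c = g)), snp)

  # insertions shift through a repeat run the same way
  insv <- data.frame(chrom = "c", pos = 3, ref = "A", alt = "AA",
                     kind = "INS", stringsAsFactors = FALSE)
  ni <- normalize_variants(insv, c(c = g))
  expect_equal(ni$pos, 1)
  expect_equal(ni$ref, "C")
  expect_equal(ni$alt, "CA")
})

test_that("calling is invariant under chunking away from variant boundaries", {
  sim <- simulate_pair(sim_config(3000, snp_rate = 0.01, seed = 21))
  whole <- call_variants(list(sim$block))
  maf <- structure(list(pairwise_to_maf_block(sim$block)), class = "maf")
  chunked <- call_variants(maf_chunk(maf, 97))
  # SNP-only simulation: no variant can span a chunk boundary
  expect_equal(variant_key(chunked), variant_key(whole))
})

test_that("emit filters select variant kinds", {
  v <- call_variants(list(fixture_block()), emit = "SNP")
  expect_equal(v$kind, "SNP")
  v2 <- call_variants(list(fixture_block()), emit = c("INS", "DEL"))
  expect_equal(v2$kind, "INS")
})
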