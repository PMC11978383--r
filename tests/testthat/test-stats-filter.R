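test_that("block_stats reproduces the fixture column walk", {
  s <- block_stats(list(fixture_block()))
  expect_equal(s$columns, 10)
  expect_equal(s$matches, 8)
  expect_equal(s$mismatches, 1)
  expect_equal(s$ins_events, 1)
  expect_equal(s$ins_bases, 1)
  expect_equal(s$del_events, 0)
  expect_equal(s$del_bases, 0)
  expect_equal(s$identity_gap_compressed, 8 / 9)
  expect_equal(s$identity_overall, 0.8)

  ident <- pairwise_block("t", 6, 0, 6, "q", 6, "+", 0, 6,
                          cig = cigar_parse("6="), taln = "AAAAAA", qaln = "AAAAAA")
  si <- block_stats(list(ident))
  expect_equal(si$identity_gap_compressed, 1)
  expect_equal(si$identity_overall, 1)

  d <- pairwise_block("t", 7, 0, 7, "q", 4, "+", 0, 4, cig = cigar_parse("2=3D2="))
  sd <- block_stats(list(d))
  expect_equal(sd$del_events, 1)
  expect_equal(sd$del_bases, 3)

  m <- pairwise_block("t", 5, 0, 5, "q", 5, "+", 0, 5, cig = cigar_parse("5M"))
  expect_error(block_stats(list(m)), "M runs")
})

test_that("stat counts always satisfy the partition identity", {
  for (seed in 1:25) {
    rb <- random_block(seed)
    s <- block_stats(list(rb$block))
    expect_equal(s$matches + s$mismatches + s$ins_bases + s$del_bases, s$columns)
  }
  agg <- block_stats(lapply(1:10, function(s) random_block(s)$block),
                     aggregate = TRUE)
  tot <- agg[agg$tname == "total", ]
  expect_equal(tot$columns, sum(agg$columns[agg$tname != "total"]))
  expect_equal(tot$matches + tot$mismatches + tot$ins_bases + tot$del_bases,
               tot$columns)
})

test_that("coverage merges intervals with union semantics", {
  fx <- fixture_block()
  cv <- coverage(list(fx))
  expect_equal(cv$covered[cv$name == "t.chr1"], 9)
  expect_equal(cv$fraction[cv$name == "t.chr1"], 1)

  b1 <- pairwise_block("t", 9, 0, 5, "q", 20, "+", 0, 5, cig = cigar_parse("5="))
  b2 <- pairwise_block("t", 9, 3, 9, "q", 20, "+", 10, 16, cig = cigar_parse("6="))
  cv2 <- coverage(list(b1, b2))
  expect_equal(cv2$covered[cv2$name == "t"], 9)  # union of [0,5) and [3,9)
  # invariance under reordering and duplication
  cv3 <- coverage(list(b2, b1, b1))
  expect_equal(cv3[cv3$name == "t", ], cv2[cv2$name == "t", ], ignore_attr = TRUE)
  # query side
  cvq <- coverage(list(b1, b2), by = "query")
  expect_equal(cvq$covered[cvq$name == "q"], 11)
  expect_equal(cvq$fraction[cvq$name == "q"], 11 / 20)
})

test_that("gap divergence assigns columns to target windows", {
  g <- gap_divergence(list(fixture_block()), window = 10)
  expect_equal(nrow(g), 1L)
  expect_equal(g$aligned_cols, 10)
  expect_equal(g$mismatch_cols, 1)
  expect_equal(g$gap_cols, 1)
  expect_equal(g$gap_divergence, 0.2)

  gm <- gap_divergence(list(fixture_block()), window = 10, include_gaps = FALSE)
  expect_equal(gm$gap_divergence, 0.1)

  ident <- pairwise_block("t", 6, 0, 6, "q", 6, "+", 0, 6, cig = cigar_parse("6="),
                          taln = "AAAAAA", qaln = "AAAAAA")
  expect_equal(gap_divergence(list(ident), window = 10)$gap_divergence, 0)

  # window with no aligned columns reports NA
  far <- pairwise_block("t", 30, 25, 30, "q", 5, "+", 0, 5, cig = cigar_parse("5="),
                        taln = "AAAAA", qaln = "AAAAA")
  g3 <- gap_divergence(list(far), window = 10)
  expect_equal(nrow(g3), 3L)
  expect_true(all(is.na(g3$gap_divergence[1:2])))
  expect_equal(g3$aligned_cols, c(0, 0, 5))
})

test_that("window sums conserve whole-alignment totals across bin sizes", {
  sim <- simulate_pair(sim_config(20000, snp_rate = 0.01, ins_rate = 0.002,
                                  del_rate = 0.002, seed = 5))
  s <- block_stats(list(sim$block))
  for (w in c(100, 1000, 1e6)) {
    g <- gap_divergence(list(sim$block), window = w)
    expect_equal(sum(g$aligned_cols), s$columns)
    expect_equal(sum(g$mismatch_cols), s$mismatches)
    expect_equal(sum(g$gap_cols), s$ins_bases + s$del_bases)
  }
})

test_that("pseudo-MAF projects samples onto the reference frame", {
  pm <- pseudo_maf(list(s1 = list(fixture_block())), "t.chr1", 0, 9, fx_tfa)
  expect_equal(pm$rows[["s1"]], "ACGATGCAT")  # insertion dropped, mismatch kept
  expect_equal(pm$ref_seq, "ACGTTGCAT")
  expect_equal(nchar(pm$rows[["s1"]]), 9L)

  # sample with no alignment in the region
  off <- pairwise_block("t.chr1", 9, 0, 2, "q2", 5, "+", 0, 2,
                        cig = cigar_parse("2="), taln = "AC", qaln = "AC")
  pm2 <- pseudo_maf(list(a = list(off)), "t.chr1", 4, 9, fx_tfa)
  expect_equal(pm2$rows[["a"]], "*****")

  # deletion shows as '-', uncovered as '*'
  d <- pairwise_block("t.chr1", 9, 0, 7, "q3", 4, "+", 0, 4,
                      cig = cigar_parse("2=3D2="), taln = "ACGTTGC", qaln = "AC---GC")
  pm3 <- pseudo_maf(list(a = list(d)), "t.chr1", 0, 9, fx_tfa)
  expect_equal(pm3$rows[["a"]], "AC---GC**")

  expect_error(pseudo_maf(list(a = list(fixture_block())), "other", 0, 5,
                          c(other = "ACGTA")), "target name mismatch")
})

test_that("overlap resolution is most-matches-wins with stable ties", {
  # two overlapping alignments; the one with more matches claims the overlap
  hi <- pairwise_block("t.chr1", 9, 0, 5, "qq", 10, "+", 0, 5,
                       cig = cigar_parse("5="), taln = "ACGTT", qaln = "ACGTT")
  lo <- pairwise_block("t.chr1", 9, 2, 7, "qq", 10, "+", 5, 10,
                       cig = cigar_parse("1X4="), taln = "GTTGC", qaln = "TTTGC")
  pm <- pseudo_maf(list(s = list(lo, hi)), "t.chr1", 0, 9, fx_tfa)
  expect_equal(pm$rows[["s"]], "ACGTTGC**")  # hi wins [2,5): G T T not T T T
})

test_that("conservation counts matches per reference position", {
  pm <- pseudo_maf(list(s1 = list(fixture_block())), "t.chr1", 0, 9, fx_tfa)
  cs <- conservation(pm)
  expect_equal(cs$n_aligned[1], 1)
  expect_equal(cs$n_match[1], 1)
  expect_equal(cs$score[1], 1)
  expect_equal(cs$n_match[4], 0)  # ref T vs sample A at pos 3
  expect_equal(cs$score[4], 0)
  expect_equal(nrow(cs), 9L)

  # two identical samples conserve everywhere
  pm2 <- pseudo_maf(list(a = list(fixture_block()), b = list(fixture_block())),
                    "t.chr1", 0, 9, fx_tfa)
  cs2 <- conservation(pm2)
  expect_equal(cs2$score, c(1, 1, 1, 0, 1, 1, 1, 1, 1))

  # unaligned counts against the default denominator but not aligned-only
  off <- pairwise_block("t.chr1", 9, 0, 2, "q2", 5, "+", 0, 2,
                        cig = cigar_parse("2="), taln = "AC", qaln = "AC")
  pm3 <- pseudo_maf(list(a = list(fixture_block()), b = list(off)),
                    "t.chr1", 0, 9, fx_tfa)
  cs3 <- conservation(pm3)
  expect_equal(cs3$score[5], 0.5)
  cs3a <- conservation(pm3, aligned_only = TRUE)
  expect_equal(cs3a$score[5], 1)
  expect_equal(cs3$n_aligned[5], 1)

  expect_error(conservation(structure(list(rows = list()), class = "pseudo_maf")),
               "no samples")
})

test_that("filters are conjunctive and preserve order", {
  fx <- fixture_block()
  expect_length(filter_records(list(fx), min_block_columns = 10, quiet = TRUE), 1L)
  expect_length(filter_records(list(fx), min_block_columns = 11, quiet = TRUE), 0L)
  expect_length(filter_records(list(fx), quiet = TRUE), 1L)
  expect_length(filter_records(list(fx), min_block_columns = 10,
                               min_identity_gap_compressed = 0.95, quiet = TRUE), 0L)
  expect_length(filter_records(list(fx), deny = "q.chr1", quiet = TRUE), 0L)
  expect_length(filter_records(list(fx), allow = c("t.chr1", "q.chr1"),
                               quiet = TRUE), 1L)
  paf <- read_paf(write_fixture_paf())
  kept <- filter_records(paf, min_target_span = 5, quiet = TRUE)
  expect_s3_class(kept, "paf")
  expect_equal(nrow(kept), 1L)
  expect_message(filter_records(list(fx), min_block_columns = 11), "kept 0 of 1")
})
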