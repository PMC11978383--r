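test_that("maf_index records per-block offsets keyed by the target row", {
  p <- write_fixture_maf()
  idx <- maf_index(p)
  expect_true(file.exists(paste0(p, ".idx")))
  expect_equal(idx$name, "t.chr1")
  expect_equal(idx$start, 0)
  expect_equal(idx$end, 9)
  # offset of the 'a' line = bytes of the "##maf version=1\n" header
  expect_equal(idx$offset, nchar("##maf version=1") + 1)
  expect_equal(read_maf_index(paste0(p, ".idx")), idx)

  # two-block file: second offset = header + block 1 bytes
  two <- c(fixture_maf_text[1:4], "",
           "a score=1", "s t.chr1 0 4 + 9 ACGT", "s q.chr1 0 4 + 10 ACGT", "")
  p2 <- tempfile(fileext = ".maf")
  writeLines(two, p2)
  idx2 <- maf_index(p2)
  expect_equal(nrow(idx2), 2L)
  expect_equal(idx2$offset[2], sum(nchar(two[1:5]) + 1))
  expect_true(all(diff(idx2$offset) > 0))

  empty <- tempfile(fileext = ".maf")
  writeLines("##maf version=1", empty)
  expect_equal(nrow(maf_index(empty)), 0L)

  gz <- tempfile(fileext = ".maf.gz")
  con <- gzfile(gz, "wt"); writeLines(fixture_maf_text, con); close(con)
  expect_error(maf_index(gz), "compressed")
})

test_that("region strings follow the samtools 1-based inclusive convention", {
  r <- parse_region("t.chr1:1-9")
  expect_equal(r$start, 0)
  expect_equal(r$end, 9)
  expect_equal(parse_region("chr1:1,000-2,000")$start, 999)
  expect_equal(parse_region("chr1")$end, Inf)
  expect_error(parse_region("chr1:5-2"), "malformed")
  expect_error(parse_region("chr1:x-2"), "malformed")
})

test_that("extraction returns whole blocks or slices cut by column projection", {
  p <- write_fixture_maf()
  whole <- maf_extract(p, "t.chr1:1-9")
  expect_length(whole, 1L)
  expect_equal(whole[[1]]$rows$text, c("ACGTTGCA-T", "ACGATGCAGT"))

  sl <- maf_extract(p, data.frame(name = "t.chr1", start = 0, end = 5),
                    slice = TRUE)
  expect_equal(sl[[1]]$rows$text, c("ACGTT", "ACGAT"))
  expect_equal(sl[[1]]$rows$start, c(0, 0))
  expect_equal(sl[[1]]$rows$size, c(5, 5))

  # insertion columns anchored at the last in-region base are retained
  sl2 <- maf_extract(p, data.frame(name = "t.chr1", start = 5, end = 8),
                     slice = TRUE)
  expect_equal(sl2[[1]]$rows$text, c("GCA-", "GCAG"))
  expect_equal(sl2[[1]]$rows$start, c(5, 5))
  expect_equal(sl2[[1]]$rows$size, c(3, 4))

  expect_warning(none <- maf_extract(p, "nope:1-5"), "not in MAF")
  expect_length(none, 0L)
})

test_that("indexed lookup equals a brute-force linear scan on random regions", {
  sim <- simulate_pair(sim_config(4000, snp_rate = 0.01, ins_rate = 0.003,
                                  del_rate = 0.003, seed = 11))
  maf <- maf_chunk(structure(list(pairwise_to_maf_block(sim$block)),
                             class = "maf"), 80)
  p <- tempfile(fileext = ".maf")
  write_maf(maf, p)
  idx <- maf_index(p)
  fwd_start <- vapply(maf, function(b) b$rows$start[1], numeric(1))
  fwd_end <- fwd_start + vapply(maf, function(b) b$rows$size[1], numeric(1))
  set.seed(42)
  for (i in 1:100) {
    s <- sample(0:3900, 1)
    e <- s + sample(1:300, 1)
    got <- maf_extract(p, data.frame(name = "target", start = s, end = e),
                       index = idx)
    brute <- which(fwd_start < e & fwd_end > s)
    expect_equal(length(got), length(brute))
    if (length(brute)) {
      expect_equal(vapply(got, function(b) b$rows$start[1], numeric(1)),
                   fwd_start[brute])
    }
  }
})

test_that("chunking is lossless at every width", {
  p <- write_fixture_maf()
  maf <- read_maf(p)
  ch5 <- maf_chunk(maf, 5)
  expect_length(ch5, 2L)
  expect_equal(ch5[[1]]$rows$text, c("ACGTT", "ACGAT"))
  expect_equal(ch5[[1]]$rows$start, c(0, 0))
  expect_equal(ch5[[1]]$rows$size, c(5, 5))
  expect_equal(ch5[[2]]$rows$text, c("GCA-T", "GCAGT"))
  expect_equal(ch5[[2]]$rows$start, c(5, 5))
  expect_equal(ch5[[2]]$rows$size, c(4, 5))

  for (width in c(1, 3, 5, 64, 10000)) {
    ch <- maf_chunk(maf, width)
    glued <- vapply(seq_len(2), function(r) {
      paste(vapply(ch, function(b) b$rows$text[r], character(1)), collapse = "")
    }, character(1))
    expect_equal(glued, maf[[1]]$rows$text)
    expect_equal(sum(vapply(ch, function(b) b$rows$size[1], numeric(1))),
                 maf[[1]]$rows$size[1])
    expect_equal(sum(vapply(ch, function(b) b$rows$size[2], numeric(1))),
                 maf[[1]]$rows$size[2])
  }
  expect_equal(maf_chunk(maf, 10)[[1]]$rows$text, maf[[1]]$rows$text)
})

test_that("a chunk window inside a long deletion keeps the size-0 query row", {
  m <- parse_maf_text(c("a score=0",
                        "s t 0 9 + 9 ACGTTGCAT",
                        "s q 0 4 + 4 AC-----AT"))
  ch <- maf_chunk(m, 3)
  expect_equal(ch[[2]]$rows$size[2], 0)
  expect_equal(ch[[2]]$rows$text[2], "---")
  expect_equal(ch[[3]]$rows$start[2], 2)
  glued <- paste(vapply(ch, function(b) b$rows$text[2], character(1)),
                 collapse = "")
  expect_equal(glued, "AC-----AT")
})

test_that("chunking minus-strand rows keeps strand-relative starts consistent", {
  for (seed in 1:10) {
    rb <- random_block(seed)
    maf <- structure(list(pairwise_to_maf_block(rb$block)), class = "maf")
    ch <- maf_chunk(maf, 4)
    # chunks tile the target interval (target rows are written forward)
    tstarts <- vapply(ch, function(b) b$rows$start[1], numeric(1))
    tends <- tstarts + vapply(ch, function(b) b$rows$size[1], numeric(1))
    keep <- vapply(ch, function(b) b$rows$size[1] > 0, logical(1))
    expect_equal(min(tstarts[keep]), rb$block$tstart)
    expect_equal(max(tends[keep]), rb$block$tend)
    # chunks with bases on both rows re-convert cleanly
    both <- vapply(ch, function(b) all(b$rows$size > 0), logical(1))
    pbs <- lapply(ch[both], maf_block_to_pairwise)
    expect_true(all(vapply(pbs, function(p) p$qstrand, character(1)) ==
                      rb$block$qstrand))
    qcov <- sum(vapply(ch, function(b) b$rows$size[2], numeric(1)))
    expect_equal(qcov, rb$block$qend - rb$block$qstart)
  }
})
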