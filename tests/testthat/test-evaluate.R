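# Helpers to construct consistent PSL pairs. Reads are conceptually 400 bp;
# a cleaner that over-trims by `o` bases at an end maps `o` genome bases
# short on that side; one that under-trims leaves `u` unaligned query bases.

make_pair <- function(id, t0 = 1000, t1 = 1400, over5 = 0, over3 = 0,
                      under5 = 0, under3 = 0, strand = "+", tname = "chr1") {
  qsize <- (t1 - t0) - over5 - over3 + under5 + under3
  if (strand == "+") {
    ts <- t0 + over5; te <- t1 - over3
    qs <- under5; qe <- qsize - under3
  } else {
    # read 5' end sits at the genome end side on the minus strand
    ts <- t0 + over3; te <- t1 - over5
    qs <- under3; qe <- qsize - under5
  }
  psl_record(id, qsize, qs, qe, tname, 100000, ts, te, strand = strand)
}

iv_for <- function(psl) {
  data.frame(id = psl$qName, start = 0L, end = psl$qSize,
             stringsAsFactors = FALSE)
}

test_that("identical full alignments are correct at all four ends", {
  a <- make_pair("r1"); b <- make_pair("r1")
  cmp <- compare_trimming(a, b, iv_for(a), iv_for(b))
  expect_equal(cmp$comparisons$class5_a, "correct")
  expect_equal(cmp$comparisons$class3_a, "correct")
  expect_equal(cmp$comparisons$class5_b, "correct")
  expect_equal(cmp$comparisons$class3_b, "correct")
})

test_that("the outermost genome boundary defines over-trimming", {
  # A maps from 1000, B from 990: A lost 10 genuine bases at the 5' end
  a <- make_pair("r1", t0 = 1000)
  b <- make_pair("r1", t0 = 990)
  cmp <- compare_trimming(a, b, iv_for(a), iv_for(b))
  expect_equal(cmp$comparisons$class5_a, "over")
  expect_equal(cmp$comparisons$delta5_a, 10L)
  expect_equal(cmp$comparisons$class5_b, "correct")
})

test_that("unaligned query bases mean under-trimming on that side", {
  a <- make_pair("r1")
  b <- make_pair("r1", under3 = 11)
  cmp <- compare_trimming(a, b, iv_for(a), iv_for(b))
  expect_equal(cmp$comparisons$class3_b, "under")
  expect_equal(cmp$comparisons$delta3_b, -11L)
  expect_equal(cmp$comparisons$class3_a, "correct")
})

test_that("pairs below the genomic overlap threshold are excluded", {
  a <- make_pair("r1", t0 = 1000, t1 = 1400)
  b <- make_pair("r1", t0 = 1361, t1 = 1800)  # overlap 39
  cmp <- compare_trimming(a, b, iv_for(a), iv_for(b), overlap_min = 40)
  expect_equal(nrow(cmp$comparisons), 0)
  expect_equal(cmp$excluded$reason, "insufficient_overlap")
  b2 <- make_pair("r1", t0 = 1360, t1 = 1800)  # overlap 40: kept
  cmp2 <- compare_trimming(a, b2, iv_for(a), iv_for(b2), overlap_min = 40)
  expect_equal(nrow(cmp2$comparisons), 1)
})

test_that("multi-mapped reads are excluded from the evaluation", {
  a <- rbind(make_pair("r1"), make_pair("r1", t0 = 5000, t1 = 5400))
  b <- make_pair("r1")
  cmp <- compare_trimming(a, b, iv_for(b), iv_for(b))
  expect_equal(nrow(cmp$comparisons), 0)
  expect_true("multi_mapped" %in% cmp$excluded$reason)
})

test_that("swapping the two cleaners swaps the labels", {
  a <- make_pair("r1", over5 = 3)
  b <- make_pair("r1", under3 = 5)
  c1 <- compare_trimming(a, b, iv_for(a), iv_for(b))
  c2 <- compare_trimming(b, a, iv_for(b), iv_for(a))
  expect_equal(c1$comparisons$class5_a, c2$comparisons$class5_b)
  expect_equal(c1$comparisons$class3_b, c2$comparisons$class3_a)
})

test_that("minus-strand query coordinates flip to read orientation", {
  # B leaves 7 unaligned query bases at the read 5' end on the minus strand
  a <- make_pair("r1", strand = "-")
  b <- make_pair("r1", under5 = 7, strand = "-")
  cmp <- compare_trimming(a, b, iv_for(a), iv_for(b))
  expect_equal(cmp$comparisons$class5_b, "under")
  expect_equal(cmp$comparisons$class3_b, "correct")
  # and an over-trim at the read 5' end sits at the genome *end* side
  a2 <- make_pair("r2", strand = "-", over5 = 4)
  b2 <- make_pair("r2", strand = "-")
  cmp2 <- compare_trimming(a2, b2, iv_for(a2), iv_for(b2))
  expect_equal(cmp2$comparisons$class5_a, "over")
  expect_equal(cmp2$comparisons$delta5_a, 4L)
})

test_that("a PSL read missing from the interval table is an error", {
  a <- make_pair("r1")
  b <- make_pair("r1")
  expect_error(
    compare_trimming(a, b, data.frame(id = "zz", start = 0, end = 10),
                     iv_for(b)),
    "missing")
})

test_that("over-trim junction k-mers come from the original read", {
  set.seed(97)
  # A-run at positions [45,51); cleaner A cut one A too many (end 50 vs 51)
  orig <- paste0(rand_seq(45), "AAAAAA", rand_seq(10))
  reads <- c(r1 = orig)
  iv_a <- data.frame(id = "r1", start = 10L, end = 50L, stringsAsFactors = FALSE)
  iv_b <- data.frame(id = "r1", start = 10L, end = 51L, stringsAsFactors = FALSE)
  a <- psl_record("r1", 40, 0, 40, "chr1", 1e5, 1000, 1040)
  b <- psl_record("r1", 41, 0, 41, "chr1", 1e5, 1000, 1041)
  cmp <- compare_trimming(a, b, iv_a, iv_b, overlap_min = 40)
  expect_equal(cmp$comparisons$class3_a, "over")
  expect_equal(cmp$comparisons$delta3_a, 1L)
  aud <- audit_overtrim_kmers(cmp, reads, iv_a, cleaner = "A", k = 6)
  expect_equal(nrow(aud), 1)
  expect_equal(aud$kmer, "AAAAAA")
  expect_false(aud$clipped)
  # no over-trims: empty table
  cmp0 <- compare_trimming(a, a, iv_a, iv_a)
  expect_equal(nrow(audit_overtrim_kmers(cmp0, reads, iv_a)), 0)
})

test_that("junction windows clipped by the read boundary are flagged", {
  orig <- c(r1 = "ACGT")
  iv_a <- data.frame(id = "r1", start = 3L, end = 4L, stringsAsFactors = FALSE)
  iv_b <- data.frame(id = "r1", start = 0L, end = 4L, stringsAsFactors = FALSE)
  a <- psl_record("r1", 1, 0, 1, "chr1", 1e5, 1003, 1004)
  b <- psl_record("r1", 4, 0, 4, "chr1", 1e5, 1000, 1004)
  cmp <- compare_trimming(a, b, iv_a, iv_b, overlap_min = 1)
  expect_equal(cmp$comparisons$class5_a, "over")
  aud <- audit_overtrim_kmers(cmp, orig, iv_a, cleaner = "A", k = 6)
  expect_true(aud$clipped)
  expect_equal(aud$kmer, "ACGT")
})
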