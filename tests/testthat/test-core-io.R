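test_that("FASTA reads come in with a full-span clean interval", {
  p <- write_tmp(c(">r1", "ACGT"))
  reads <- read_reads(p)
  expect_length(reads, 1)
  expect_equal(reads[[1]]$id, "r1")
  expect_equal(reads[[1]]$seq, "ACGT")
  expect_equal(reads[[1]]$clean, c(0L, 4L))
  expect_equal(reads[[1]]$status, "active")
  expect_null(reads[[1]]$qual)
})

test_that("FASTQ qualities decode as Phred+33", {
  p <- write_tmp(c("@r1", "AC", "+", "II"), ext = ".fastq")
  reads <- read_reads(p)
  expect_equal(reads[[1]]$qual, c(40L, 40L))
})

test_that("mismatched QUAL records and duplicate ids are errors", {
  fa <- write_tmp(c(">r1", "ACGT"))
  qa <- write_tmp(c(">r1", "30 30 30"), ext = ".qual")
  expect_error(read_reads(fa, qa), "r1")
  dup <- write_tmp(c(">r1", "ACGT", ">r1", "TTTT"))
  expect_error(read_reads(dup), "duplicate")
})

test_that("FASTA + QUAL pairing by id works regardless of order", {
  fa <- write_tmp(c(">a", "ACGT", ">b", "GGCC"))
  qa <- write_tmp(c(">b", "10 20 30 40", ">a", "1 2 3 4"), ext = ".qual")
  reads <- read_reads(fa, qa)
  expect_equal(reads[[1]]$qual, 1:4)
  expect_equal(reads[[2]]$qual, c(10L, 20L, 30L, 40L))
})

test_that("write_cleaned emits clean subsequences and routes discards", {
  r1 <- scrub_read("r1", "AAACGTAAA")
  r1 <- readscrub:::set_clean(r1, 3, 6, "test")
  r2 <- readscrub:::discard_read(scrub_read("r2", "ACGTACGT"), "no_barcode")
  out <- tempfile(fileext = ".fasta")
  disc <- tempfile(fileext = ".fasta")
  write_cleaned(list(r1, r2), out, discarded_fasta = disc)
  fa <- Biostrings::readDNAStringSet(out)
  expect_equal(as.character(fa[[1]]), "CGT")
  dd <- Biostrings::readDNAStringSet(disc)
  expect_match(names(dd), "no_barcode")
  expect_equal(as.character(dd[[1]]), "ACGTACGT")
})

test_that("an active read with an empty interval becomes empty_after_trim", {
  r <- scrub_read("r1", "ACGT")
  r <- readscrub:::set_clean(r, 2, 2, "test")
  out <- tempfile(fileext = ".fasta")
  disc <- tempfile(fileext = ".fasta")
  res <- write_cleaned(list(r), out, discarded_fasta = disc)
  expect_equal(res[[1]]$status, "discarded")
  expect_equal(res[[1]]$discard_reason, "empty_after_trim")
  expect_length(Biostrings::readDNAStringSet(out), 0)
  expect_length(Biostrings::readDNAStringSet(disc), 1)
})

test_that("zero active reads still produce a valid empty FASTA", {
  out <- tempfile(fileext = ".fasta")
  write_cleaned(list(), out)
  expect_true(file.exists(out))
  expect_length(Biostrings::readDNAStringSet(out), 0)
})

test_that("round trip through read/write preserves untouched sequences", {
  set.seed(42)
  seqs <- vapply(1:5, function(i) rand_seq(sample(30:80, 1)), "")
  p <- write_tmp(as.vector(rbind(paste0(">s", 1:5), seqs)))
  out <- tempfile(fileext = ".fasta")
  write_cleaned(read_reads(p), out)
  back <- Biostrings::readDNAStringSet(out)
  expect_equal(unname(as.character(back)), seqs)
})

test_that("protocol FASTA parses role-encoded headers and round-trips", {
  p <- write_tmp(c(">MID1|barcode", "ACGAGTGCGT",
                   ">P1|amp5", "AAGCAGTGGT",
                   ">V1|vector", "CCGGTTAACC"))
  pro <- read_protocol(p)
  expect_equal(pro$barcodes, c(MID1 = "ACGAGTGCGT"))
  expect_equal(pro$primers$name, "P1")
  expect_equal(pro$primers$role, "amp5")
  expect_equal(pro$vectors, c(V1 = "CCGGTTAACC"))
  out <- tempfile(fileext = ".fasta")
  write_protocol(pro, out)
  expect_equal(read_protocol(out), pro)
})

test_that("unknown roles and empty protocol sequences are rejected", {
  p <- write_tmp(c(">X|frobnicate", "ACGT"))
  expect_error(read_protocol(p), "unknown role")
  p2 <- write_tmp(c(">A|barcode", "", ">B|barcode", "ACGT"))
  expect_error(read_protocol(p2))
})

test_that("reverse complement is a self-inverse and maps N to N", {
  set.seed(7)
  seqs <- vapply(1:20, function(i) rand_seq(sample(1:50, 1)), "")
  expect_equal(revcomp(revcomp(seqs)), seqs)
  expect_equal(revcomp("ACGTN"), "NACGT")
})

test_that("PSL parsing accepts 21 columns and rejects short rows", {
  rec <- psl_record("q1", 100, 0, 100, "chr1", 1000, 200, 300)
  path <- tempfile(fileext = ".psl")
  write_psl(rec, path)
  back <- read_psl(path)
  expect_equal(back$qName, "q1")
  expect_equal(back$tStart, 200L)
  expect_equal(back$tEnd, 300L)
  bad <- write_tmp(c(paste(rep("1", 10), collapse = "\t")), ext = ".psl")
  expect_error(read_psl(bad), "21")
})

test_that("PSL rows with out-of-bounds intervals are rejected", {
  rec <- psl_record("q1", 100, 0, 100, "chr1", 1000, 200, 300)
  rec$qEnd <- 150L
  path <- tempfile(fileext = ".psl")
  write_psl(rec, path)
  expect_error(read_psl(path), "bounds")
})

test_that("trim log narrows monotonically and refuses to widen", {
  r <- scrub_read("r1", rand_seq(50))
  r <- readscrub:::set_clean(r, 5, 45, "a")
  r <- readscrub:::set_clean(r, 10, 40, "b")
  expect_error(readscrub:::set_clean(r, 5, 40, "c"), "not nested")
  expect_equal(length(r$trim_log), 2)
  for (tl in r$trim_log) {
    expect_true(tl$after[1] >= tl$before[1])
    expect_true(tl$after[2] <= tl$before[2])
  }
})
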