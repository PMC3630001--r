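test_that("semi-global prefix alignment handles exact, mismatch, indel, reject", {
  r <- semiglobal_prefix_align("ACGT", "ACGTTTTT", 0)
  expect_equal(r$errors, 0L); expect_equal(r$read_end, 4L); expect_true(r$aligned)
  r <- semiglobal_prefix_align("ACGT", "ATGTTTTT", 1)
  expect_equal(r$errors, 1L); expect_equal(r$read_end, 4L); expect_true(r$aligned)
  # single deletion: shortest prefix attaining the minimum
  r <- semiglobal_prefix_align("ACGT", "AGTTTTTT", 1)
  expect_equal(r$errors, 1L); expect_equal(r$read_end, 3L); expect_true(r$aligned)
  # pattern buried mid-read: anchored search must reject
  r <- semiglobal_prefix_align("ACGT", "TTTTACGT", 2)
  expect_false(r$aligned)
  expect_false(semiglobal_prefix_align("ACGT", "", 3)$aligned)
})

test_that("semi-global alignment agrees with the prefix edit-distance oracle", {
  set.seed(11)
  for (i in 1:300) {
    pat <- rand_seq(sample(1:20, 1))
    rd <- rand_seq(sample(1:60, 1))
    orc <- oracle_semiglobal(pat, rd)
    for (me in 0:3) {
      got <- semiglobal_prefix_align(pat, rd, me)
      expect_equal(got$errors, orc$errors)
      expect_equal(got$aligned, orc$errors <= me)
      expect_equal(got$read_end, orc$read_end)
    }
  }
})

test_that("seed_hits reports shared words in both orientations", {
  s <- seed_hits("ACGTACGT", "TTACGTACGTTT", 8)
  fwd <- s[s$orientation == "forward", ]
  expect_true(any(fwd$read_pos == 2 & fwd$subj_pos == 0))
  s <- seed_hits("AAAA", "TTTT", 4)
  expect_equal(nrow(s), 1)
  expect_equal(s$orientation, "reverse")
  expect_equal(s$read_pos, 0L)
  expect_equal(nrow(seed_hits("ACGT", "GGCCGGCC", 4)), 0)
  # subject shorter than the word size yields nothing
  expect_equal(nrow(seed_hits("ACG", "ACGTACGT", 4)), 0)
})

test_that("seed_hits finds every exact occurrence of the subject", {
  set.seed(13)
  for (i in 1:50) {
    subj <- rand_seq(sample(11:25, 1))
    pos <- sample(0:30, 1)
    rd <- paste0(rand_seq(pos), subj, rand_seq(sample(0:30, 1)))
    s <- seed_hits(subj, rd, 11)
    expect_true(any(s$orientation == "forward" &
                      s$read_pos - s$subj_pos == pos))
  }
})

test_that("banded extension recovers identity, substitution and overhangs", {
  set.seed(17)
  a <- rand_seq(20)
  h <- banded_nw_extend(a, a, list(subj_start = 0, subj_end = 20,
                                   read_start = 0, read_end = 20), band = 5)
  expect_equal(h$pid, 100)
  expect_equal(h$aln_len, 20L)
  expect_equal(h$oh_subj_left + h$oh_subj_right + h$oh_read5 + h$oh_read3, 0L)

  b <- a
  substr(b, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(a, 11, 11))[1]
  h <- banded_nw_extend(a, b, list(subj_start = 0, subj_end = 20,
                                   read_start = 0, read_end = 20), band = 5)
  expect_equal(h$pid, 95)
  expect_equal(h$aln_len, 20L)

  # subject running 3 bases past the read's 3' end
  rd <- substr(a, 1, 17)
  h <- banded_nw_extend(a, rd, list(subj_start = 0, subj_end = 20,
                                    read_start = 0, read_end = 17), band = 5)
  expect_equal(h$oh_subj_right, 3L)
  expect_equal(h$pid, 100)
})

test_that("banded score with a full-width band equals unbanded NW", {
  set.seed(19)
  for (i in 1:100) {
    a <- rand_seq(sample(5:40, 1))
    b <- rand_seq(sample(5:40, 1))
    h <- banded_nw_extend(a, b,
                          list(subj_start = 0, subj_end = nchar(a),
                               read_start = 0, read_end = nchar(b)),
                          band = max(nchar(a), nchar(b)))
    expect_equal(h$score, oracle_nw_score(a, b))
  }
})

test_that("hits are invariant under flanking sequence beyond the band", {
  set.seed(23)
  for (i in 1:20) {
    subj <- rand_seq(20)
    left <- sample(10:60, 1)
    rd <- paste0(rand_seq(left), subj, rand_seq(sample(10:60, 1)))
    anchor <- list(subj_start = 0, subj_end = 20,
                   read_start = left, read_end = left + 20)
    h1 <- banded_nw_extend(subj, rd, anchor, band = 5)
    rd2 <- paste0(rand_seq(30), rd, rand_seq(30))
    anchor2 <- list(subj_start = 0, subj_end = 20,
                    read_start = left + 30, read_end = left + 50)
    h2 <- banded_nw_extend(subj, rd2, anchor2, band = 5)
    expect_equal(h2$read_start - h1$read_start, 30L)
    expect_equal(h2$pid, h1$pid)
    expect_equal(h2$aln_len, h1$aln_len)
    expect_equal(h2$matches, h1$matches)
  }
})

test_that("reverse-orientation extension keeps read coordinates stable", {
  set.seed(29)
  subj <- rand_seq(20)
  rd <- paste0(rand_seq(15), revcomp(subj), rand_seq(15))
  se <- seed_hits(subj, rd, 11)
  expect_true(all(se$orientation == "reverse"))
  an <- readscrub:::merge_seeds(se, 20, 11, 5)
  h <- banded_nw_extend(subj, rd, an[1, ], band = 5, orientation = "reverse")
  expect_equal(h$read_start, 15L)
  expect_equal(h$read_end, 35L)
  expect_equal(h$pid, 100)
})
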