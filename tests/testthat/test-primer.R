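subjects_df <- function(name, seq, role = "amp5") {
  data.frame(name = name, seq = seq, role = role, stringsAsFactors = FALSE)
}

test_that("an exact internal primer is a middle hit at 100% identity", {
  set.seed(41)
  primer <- rand_seq(20)
  b <- build_read(left = rand_seq(100), p = primer, right = rand_seq(280))
  h <- locate_hits(b$read, subjects_df("P", primer),
                   match_criteria(middle_min_len = 16, middle_min_pid = 94))
  expect_equal(nrow(h), 1)
  expect_equal(h$read_start, 100L)
  expect_equal(h$read_end, 120L)
  expect_equal(h$pid, 100)
  expect_equal(h$kind, "middle")
})

test_that("partial terminal matches obey the end criteria thresholds", {
  set.seed(43)
  primer <- rand_seq(20)
  # last 12 primer bases match the first 12 read bases
  rd <- scrub_read("r", paste0(substr(primer, 9, 20), rand_seq(60)))
  h <- locate_hits(rd, subjects_df("P", primer),
                   match_criteria(end_max_unaligned_subj = 8,
                                  end_max_unaligned_read = 0))
  expect_equal(nrow(h), 1)
  expect_equal(h$oh_subj_left, 8L)
  expect_equal(h$pid, 100)
  expect_equal(h$kind, "end")
  # same geometry with a tighter subject-overhang budget: rejected
  h2 <- locate_hits(rd, subjects_df("P", primer),
                    match_criteria(end_max_unaligned_subj = 5,
                                   end_max_unaligned_read = 0))
  expect_equal(nrow(h2), 0)
})

test_that("a short internal exact hit fails a larger middle_min_len", {
  set.seed(47)
  primer <- rand_seq(20)
  b <- build_read(left = rand_seq(90), p = primer, right = rand_seq(90))
  h <- locate_hits(b$read, subjects_df("P", primer),
                   match_criteria(middle_min_len = 25))
  expect_equal(nrow(h), 0)
})

test_that("classification covers the whole erroneous-read taxonomy", {
  set.seed(53)
  p5 <- rand_seq(23); p3 <- rand_seq(23)
  subs <- rbind(subjects_df("P5", p5, "amp5"), subjects_df("P3", p3, "amp3"))
  crit <- match_criteria()
  classify <- function(...) {
    b <- build_read(...)
    h <- locate_hits(b$read, subs, crit)
    classify_read(h, b$read, crit)
  }
  ins <- rand_seq(150)
  # one forward hit flush at the 5' end
  expect_equal(classify(p = p5, i = ins), "OK")
  # forward flush 5' + reverse flush 3'
  expect_equal(classify(p = p5, i = ins, r = revcomp(p3)), "OK")
  # reverse at 5' + forward at 3'
  expect_equal(classify(a = revcomp(p3), i = ins, b = p5), "RF")
  # forward and reverse matches of the same primer
  expect_equal(classify(a = p5, i = ins, b = revcomp(p5)), "fr")
  # forward 5' hit preceded by 7 unmatched bases
  expect_equal(classify(j = rand_seq(7), p = p5, i = ins, r = revcomp(p3)), "SF")
  # reverse 3' hit followed by unmatched bases
  expect_equal(classify(p = p5, i = ins, r = revcomp(p3), j = rand_seq(7)), "RE")
  # multiple forward matches tiled along the read
  expect_equal(classify(a = p5, b = p5, i = ins, r = revcomp(p3)), "NF")
  expect_equal(classify(a = p5, i = ins, r = revcomp(p3), r2 = revcomp(p3)), "NR")
  # no hits at all
  expect_equal(classify(i = ins), "OK")
})

test_that("trimming follows classification and the per-type policy", {
  set.seed(59)
  p5 <- rand_seq(23); p3 <- rand_seq(23)
  subs <- rbind(subjects_df("P5", p5, "amp5"), subjects_df("P3", p3, "amp3"))
  crit <- match_criteria()

  # OK: advance past the 5' forward hit, retreat before the 3' reverse hit
  b <- build_read(p = p5, i = rand_seq(200), r = revcomp(p3))
  h <- locate_hits(b$read, subs, crit)
  out <- trim_by_hits(b$read, h, classify_read(h, b$read, crit))
  expect_equal(out$clean, c(b$ends[["p"]], b$starts[["r"]]))

  # NF with salvage keeps the longest hit-free stretch
  b <- build_read(a = p5, gap1 = rand_seq(30), b = p5, i = rand_seq(200))
  h <- locate_hits(b$read, subs, crit)
  expect_equal(classify_read(h, b$read, crit), "NF")
  out <- trim_by_hits(b$read, h, "NF")
  expect_equal(out$clean, c(b$ends[["b"]], b$ends[["i"]]))

  # RF with the default policy is discarded
  b <- build_read(a = revcomp(p3), i = rand_seq(200), b = p5)
  h <- locate_hits(b$read, subs, crit)
  out <- trim_by_hits(b$read, h, "RF")
  expect_equal(out$status, "discarded")
  expect_equal(out$discard_reason, "primer_RF")
})

test_that("salvage ties resolve to the leftmost interval", {
  set.seed(61)
  p5 <- rand_seq(23)
  # two equal hit-free gaps of 100 around a central primer
  b <- build_read(g1 = rand_seq(100), p = p5, g2 = rand_seq(100))
  h <- locate_hits(b$read, subjects_df("P5", p5, "amp5"))
  iv <- readscrub:::longest_free_interval(b$read$clean, h)
  expect_equal(iv, c(0L, 100L))
})

test_that("every accepted hit satisfies its own acceptance criterion", {
  set.seed(67)
  crit <- match_criteria()
  pro <- sim_protocol(seed = 77)
  sim <- simulate_reads(sim_config(pro, n_reads = 40, seed = 9,
                                   sub_rate = 0.01, indel_rate = 0.005))
  subs <- readscrub:::protocol_table(pro)
  subs <- subs[subs$role %in% c("amp5", "amp3"), ]
  for (r in sim$reads) {
    h <- locate_hits(r, subs, crit)
    if (nrow(h) == 0) next
    max_subj <- pmax(0L, h$subj_len - 8L)
    ok_end <- (h$gap_before <= crit$end_max_unaligned_read &
                 h$oh_subj_left <= max_subj & h$pid >= crit$end_min_pid) |
      (h$gap_after <= crit$end_max_unaligned_read &
         h$oh_subj_right <= max_subj & h$pid >= crit$end_min_pid)
    ok_mid <- h$aln_len >= crit$middle_min_len & h$pid >= crit$middle_min_pid
    expect_true(all(ok_end | ok_mid))
    expect_true(all(diff(h$read_start) >= 0))
    expect_true(all(h$read_start >= r$clean[1] & h$read_end <= r$clean[2]))
  }
})
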