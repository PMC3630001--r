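# Expected values below follow the window model exactly: the longest
# end-anchored window with base-fraction strictly above the cutoff wins, so a
# pure tail may legitimately absorb a base or two of adjacent sequence while
# the fraction stays above the cutoff. Deterministic G-bodies make the
# expectations computable by hand.

test_that("pure, noisy, and too-short tails behave per the window model", {
  p <- polya_params(min_len = 8, min_fraction = 0.8, max_end_offset = 0,
                    both_sides = FALSE)
  # 10-base tail after GGG...: windows of 10,11,12 A-fractions 1, .909, .833
  # all exceed 0.8; 13 gives .769 and stops. Longest window = 12.
  r <- scrub_read("r", paste0(strrep("G", 30), strrep("A", 10)))
  expect_equal(trim_polya(r, p)$clean[2], 28L)
  expect_equal(trim_polya(r, p)$clean,
               oracle_trim_polya(r$seq, c(0L, 40L), p))

  # 9 A's out of 10 (fraction .9); one more G gives .818, two .75 (stops)
  r <- scrub_read("r", paste0(strrep("G", 30), "AAAAAGAAAA"))
  expect_equal(trim_polya(r, p)$clean[2], 29L)

  # 7 A's cannot reach min_len 8 at fraction cutoff 0.9
  p9 <- polya_params(min_len = 8, min_fraction = 0.9, max_end_offset = 0,
                     both_sides = FALSE)
  r <- scrub_read("r", paste0(strrep("G", 30), strrep("A", 7)))
  expect_equal(trim_polya(r, p9)$clean[2], 37L)
})

test_that("poly-T heads are trimmed symmetrically when both_sides is on", {
  r <- scrub_read("r", paste0(strrep("T", 10), strrep("G", 40)))
  out <- trim_polya(r, polya_params(min_len = 8, min_fraction = 0.8,
                                    max_end_offset = 0))
  expect_equal(out$clean, c(12L, 50L))  # 10 T's + 2 absorbed G's at .833
})

test_that("the outer-edge offset bound gates tails set back from the end", {
  # 10 A's followed by 6 G's: within offset 3 no admissible window clears the
  # fraction cutoff; with offset 6 the window [28,40) (A10 + 2 G's, .833)
  # qualifies and the longest placement starts at 28.
  r <- scrub_read("r", paste0(strrep("G", 30), strrep("A", 10), strrep("G", 6)))
  p3 <- polya_params(min_len = 8, min_fraction = 0.8, max_end_offset = 3,
                     both_sides = FALSE)
  expect_equal(trim_polya(r, p3)$clean[2], 46L)
  p6 <- polya_params(min_len = 8, min_fraction = 0.8, max_end_offset = 6,
                     both_sides = FALSE)
  expect_equal(trim_polya(r, p6)$clean[2], 28L)
})

test_that("trim_polya matches the exhaustive window oracle on noisy tails", {
  set.seed(79)
  p <- polya_params()
  for (i in 1:400) {
    body <- rand_seq(sample(20:60, 1))
    tail_len <- sample(c(0, 0, 5:20), 1)
    tail <- paste(sample(c("A", "C", "G", "T"), tail_len, replace = TRUE,
                         prob = c(0.88, 0.04, 0.04, 0.04)), collapse = "")
    head_len <- sample(c(0, 0, 0, 5:15), 1)
    head <- paste(sample(c("A", "C", "G", "T"), head_len, replace = TRUE,
                         prob = c(0.04, 0.04, 0.04, 0.88)), collapse = "")
    off <- sample(0:3, 1)
    r <- scrub_read("r", paste0(head, body, tail, rand_seq(off)))
    out <- trim_polya(r, p)
    expect_equal(out$clean, oracle_trim_polya(r$seq, c(0L, nchar(r$seq)), p))
  }
})

test_that("poly-A trimming is idempotent and leaves no residual tail", {
  set.seed(83)
  p <- polya_params()
  for (i in 1:100) {
    r <- scrub_read("r", paste0(rand_seq(sample(30:60, 1)),
                                strrep("A", sample(8:25, 1)),
                                rand_seq(sample(0:3, 1))))
    once <- trim_polya(r, p)
    twice <- trim_polya(once, p)
    expect_equal(twice$clean, once$clean)
    # residual-tail freedom: no qualifying window remains at the 3' edge
    expect_null(readscrub:::polya_boundary3(once$seq, once$clean, p))
  }
})
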