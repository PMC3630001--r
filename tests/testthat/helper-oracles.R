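# Independent oracles used throughout the suite. Each one is deliberately
# implemented on a different code path than the function it checks.

# Semi-global prefix alignment: minimum Levenshtein distance of the pattern
# against every prefix of the read, via utils::adist.
oracle_semiglobal <- function(pattern, read) {
  n <- nchar(read)
  prefixes <- substring(read, 1, 0:n)
  d <- as.integer(utils::adist(pattern, prefixes))
  j <- which.min(d)  # first minimum = shortest prefix
  list(errors = d[j], read_end = j - 1L)
}

# Unbanded global Needleman-Wunsch score with linear gaps, via Biostrings.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = 0, gapExtension = -gap)
  Biostrings::score(pa)
}

# Exhaustive poly-A window oracle (3' side): enumerates every end-anchored
# window [i, e) with clean_end - e <= max_end_offset, keeps those with
# base-fraction strictly above min_fraction and length >= min_len, and picks
# the longest (outermost/most-trimming on ties). Returns the new clean end
# or NULL. Character-level counting, no cumulative sums.
oracle_polya3 <- function(seq, clean, p, base = "A") {
  s <- substr(seq, clean[1] + 1, clean[2])
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  best <- NULL
  for (e in seq_len(L)) {
    if ((L - e) > p$max_end_offset) next
    for (i in 0:(e - 1)) {
      len <- e - i
      if (len < p$min_len) next
      frac <- sum(ch[(i + 1):e] == base) / len
      if (frac > p$min_fraction) {
        if (is.null(best) || len > best$len ||
            (len == best$len && i < best$i)) best <- list(len = len, i = i)
      }
    }
  }
  if (is.null(best)) NULL else clean[1] + best$i
}

oracle_polya5 <- function(seq, clean, p, base = "T") {
  s <- substr(seq, clean[1] + 1, clean[2])
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  best <- NULL
  for (st in 0:min(p$max_end_offset, L - 1)) {
    for (j in (st + 1):L) {
      len <- j - st
      if (len < p$min_len) next
      frac <- sum(ch[(st + 1):j] == base) / len
      if (frac > p$min_fraction) {
        if (is.null(best) || len > best$len ||
            (len == best$len && j > best$j)) best <- list(len = len, j = j)
      }
    }
  }
  if (is.null(best)) NULL else clean[1] + best$j
}

# Full poly-A trim oracle mirroring trim_polya's order of operations
# (3' first, then 5' on the narrowed interval).
oracle_trim_polya <- function(seq, clean, p) {
  e <- oracle_polya3(seq, clean, p)
  if (!is.null(e)) clean[2] <- e
  if (p$both_sides) {
    s <- oracle_polya5(seq, clean, p)
    if (!is.null(s)) clean[1] <- s
  }
  clean
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")
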