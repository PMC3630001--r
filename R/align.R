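#' Semi-global alignment of a pattern against a read prefix
#'
#' Aligns `pattern` against a prefix of `read` with unit edit costs
#' (mismatch 1, insertion 1, deletion 1): the pattern must be consumed
#' entirely, the alignment is anchored at read position 0, and the read's
#' suffix is free. This is the barcode search primitive: the returned
#' `read_end` is where trimming resumes when the barcode is accepted.
#'
#' @param pattern Non-empty DNA string (e.g. a barcode).
#' @param read DNA string to search.
#' @param max_errors Maximum tolerated mismatches + indels.
#' @return A list with `errors` (the minimum edit distance over all read
#'   prefixes), `read_end` (0-based exclusive end of the pattern's alignment
#'   on the read; the shortest prefix attaining the minimum), and `aligned`
#'   (`FALSE` iff `errors > max_errors`).
#' @examples
#' semiglobal_prefix_align("ACGT", "ACGTTTTT", 0)
#' @export
semiglobal_prefix_align <- function(pattern, read, max_errors) {
  stopifnot(max_errors >= 0)
  res <- cpp_semiglobal_prefix(toupper(pattern), toupper(read),
                               as.integer(max_errors))
  res$read_end <- as.integer(res$read_end)
  res$errors <- as.integer(res$errors)
  res
}

#' Exact k-mer seeds between a subject and a read
#'
#' Reports every exact shared word of length `word_size` between the subject
#' (in both orientations) and the read. Reverse-orientation seeds are found by
#' reverse-complementing the *subject*, never the read, so read coordinates
#' stay stable; `subj_pos` of a reverse seed refers to the reverse-complemented
#' subject. Words containing `N` are skipped.
#'
#' @param subject,read DNA strings.
#' @param word_size Word length (4--31). Subjects shorter than `word_size`
#'   yield no seeds.
#' @return A data.frame with columns `subj_pos`, `read_pos` (0-based) and
#'   `orientation` (`"forward"`/`"reverse"`).
#' @export
seed_hits <- function(subject, read, word_size = 11L) {
  cpp_seed_hits(toupper(subject), toupper(read), as.integer(word_size))
}

# Merge diagonal-clustered seeds into candidate anchor regions. Seeds of the
# same orientation chain when their diagonals differ by at most `band` and
# their read positions are within one subject length of each other; each
# cluster yields one anchor spanning its seed extents.
merge_seeds <- function(seeds, subject_len, word_size, band = 5L) {
  mg <- merge_seeds0(seeds$subj_pos, seeds$read_pos, seeds$orientation,
                     subject_len, word_size, band)
  data.frame(orientation = mg$orient, subj_start = mg$ss, subj_end = mg$se,
             read_start = mg$rs, read_end = mg$re, stringsAsFactors = FALSE)
}

# Vector-level seed clustering used in the per-read inner loop.
merge_seeds0 <- function(subj_pos, read_pos, orientation, subject_len,
                         word_size, band = 5L) {
  out <- list(orient = character(0), ss = integer(0), se = integer(0),
              rs = integer(0), re = integer(0))
  if (length(subj_pos) == 0) return(out)
  for (ori in unique(orientation)) {
    pick <- orientation == ori
    sp <- subj_pos[pick]; rp <- read_pos[pick]
    o <- order(rp, sp)
    sp <- sp[o]; rp <- rp[o]
    diag <- rp - sp
    cluster <- integer(length(sp))
    cid <- 1L
    cluster[1] <- cid
    if (length(sp) > 1) {
      for (k in 2:length(sp)) {
        prev <- cluster == cid
        link <- abs(diag[k] - diag[prev]) <= band &
          (rp[k] - rp[prev]) <= subject_len
        if (!any(link)) cid <- cid + 1L
        cluster[k] <- cid
      }
    }
    for (g in split(seq_along(sp), cluster)) {
      out$orient <- c(out$orient, ori)
      out$ss <- c(out$ss, min(sp[g]))
      out$se <- c(out$se, max(sp[g]) + word_size)
      out$rs <- c(out$rs, min(rp[g]))
      out$re <- c(out$re, max(rp[g]) + word_size)
    }
  }
  out
}

# Reverse complements of the (few, short) protocol sequences recur for every
# read; cache them.
.rc_cache <- new.env(parent = emptyenv())
revcomp_cached <- function(x) {
  v <- .rc_cache[[x]]
  if (is.null(v)) {
    v <- revcomp(x)
    assign(x, v, envir = .rc_cache)
  }
  v
}

#' Banded Needleman-Wunsch extension of a seed anchor
#'
#' Extends a candidate region to a full alignment of the subject against the
#' read: a banded global alignment (linear gap penalties; diagonal band of
#' half-width `band` around the anchor, widened only as far as needed to
#' connect the matrix corners) is computed over the read window the band can
#' reach, and terminal gap runs are then trimmed off so that unaligned
#' terminal bases are reported as overhangs rather than penalised columns.
#'
#' For reverse-orientation anchors the subject is reverse-complemented (read
#' coordinates never flip); `subj_start`/`subj_end` and the subject overhangs
#' then refer to the oriented (reverse-complemented) subject, i.e. left/right
#' as seen from the read.
#'
#' @param subject Subject DNA string (adapter, primer, vector).
#' @param read Read DNA string.
#' @param anchor A list or one-row data.frame with `subj_start`, `subj_end`,
#'   `read_start`, `read_end` (0-based half-open; subject coordinates on the
#'   oriented subject), as produced by [seed_hits()] clustering.
#' @param band Band half-width (>= 1), default 5.
#' @param orientation `"forward"` or `"reverse"`.
#' @param match,mismatch,gap Alignment scores (linear gaps).
#' @return A one-row data.frame (an alignment hit) with columns
#'   `orientation`, `read_start`, `read_end`, `subj_start`, `subj_end`,
#'   `subj_len`, `pid` (percent identity over the aligned span), `aln_len`,
#'   `matches`, `score` (the banded global score, terminal gaps included),
#'   `oh_subj_left`, `oh_subj_right`, `oh_read5`, `oh_read3` (unaligned bases
#'   outside the hit), or `NULL` when nothing aligns.
#' @export
banded_nw_extend <- function(subject, read, anchor, band = 5L,
                             orientation = c("forward", "reverse"),
                             match = 1L, mismatch = -1L, gap = -2L) {
  orientation <- match.arg(orientation)
  subject <- toupper(subject); read <- toupper(read)
  oriented <- if (orientation == "reverse") revcomp(subject) else subject
  v <- nw_extend0(oriented, read,
                  anchor$subj_start, anchor$read_start,
                  band, match, mismatch, gap)
  if (is.null(v)) return(NULL)
  data.frame(orientation = orientation,
             read_start = v[["read_start"]], read_end = v[["read_end"]],
             subj_start = v[["subj_start"]], subj_end = v[["subj_end"]],
             subj_len = nchar(oriented),
             pid = v[["pid"]],
             aln_len = v[["aln_len"]], matches = v[["matches"]],
             score = v[["score"]],
             oh_subj_left = v[["oh_subj_left"]],
             oh_subj_right = v[["oh_subj_right"]],
             oh_read5 = v[["read_start"]],
             oh_read3 = nchar(read) - v[["read_end"]],
             stringsAsFactors = FALSE)
}

# Extension kernel on a pre-oriented subject; returns a named numeric vector
# or NULL. Kept free of data.frame construction: it sits in the per-read
# inner loop of locate_hits().
nw_extend0 <- function(oriented, read, subj_start, read_start,
                       band = 5L, match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(band >= 1)
  m <- nchar(oriented); n <- nchar(read)
  w0 <- read_start - subj_start
  w1 <- w0 + m
  # Subject bases the band cannot connect to any read base (they run past a
  # read end by more than the band) are recorded as overhang up front rather
  # than entering the DP as forced terminal gaps, whose penalty could favour
  # a spuriously shifted alignment over the true partial overlap.
  clip_l <- max(0L, as.integer(-w0 - band))
  clip_r <- max(0L, as.integer(w1 - n - band))
  if (clip_l + clip_r >= m) return(NULL)
  oriented_c <- substr(oriented, clip_l + 1L, m - clip_r)
  w0 <- w0 + clip_l
  w1 <- w0 + nchar(oriented_c)
  ws <- max(0L, as.integer(w0 - band))
  we <- min(n, as.integer(w1 + band))
  if (ws >= we) return(NULL)
  res <- cpp_banded_nw(oriented_c, substr(read, ws + 1L, we),
                       as.integer(band), as.integer(match),
                       as.integer(mismatch), as.integer(gap))
  if (res$aln_len == 0) return(NULL)
  c(read_start = res$b_start + ws, read_end = res$b_end + ws,
    subj_start = res$a_start + clip_l, subj_end = res$a_end + clip_l,
    pid = 100 * res$matches / res$aln_len,
    aln_len = res$aln_len, matches = res$matches, score = res$score,
    oh_subj_left = res$a_start + clip_l,
    oh_subj_right = m - (res$a_end + clip_l))
}
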