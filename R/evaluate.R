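#' Compare two cleaners' trimming against genome alignments
#'
#' Given genome alignments (PSL) of the reads cleaned by two tools, A and B,
#' classifies each tool's trimming at each read end. Reads mapped to multiple
#' genome locations by either tool are excluded, as are pairs whose genome
#' alignments lie on different targets/strands or overlap by fewer than
#' `overlap_min` bases. For each retained read and each read end:
#'
#' * a cleaner is **under**-trimmed when its cleaned read is not fully aligned
#'   on that side (more than `end_tolerance` unaligned query bases remain);
#' * otherwise it is **over**-trimmed when its aligned genome boundary is not
#'   the best of the pair (the minimum start / maximum end);
#' * otherwise it is **correct**.
#'
#' Minus-strand alignments have their query coordinates flipped to read
#' orientation before end assignment, and the genome start/end sides are
#' mapped to the read 5'/3' ends through the strand.
#'
#' Signed deltas accompany the classes: positive values are the excess genome
#' bases trimmed (over-trimming), negative values the unaligned query bases
#' left behind (under-trimming), zero is correct.
#'
#' @param psl_a,psl_b PSL data.frames ([read_psl()]) from mapping each
#'   cleaner's output.
#' @param intervals_a,intervals_b Data frames with columns `id`, `start`,
#'   `end`: each cleaner's clean intervals on the original reads
#'   ([trim_intervals()]). Every read in a PSL must be present (error
#'   otherwise).
#' @param overlap_min Minimum genomic overlap of the two alignments for a pair
#'   to be evaluated (default 40).
#' @param end_tolerance Unaligned query bases still counting as "fully
#'   aligned" (default 0, strict).
#' @return A list of class `trim_comparison` with `comparisons` (one row per
#'   evaluated read: classes and deltas per cleaner and end), `summary`
#'   (counts per cleaner, end and class) and `excluded` (read ids with the
#'   exclusion reason).
#' @export
compare_trimming <- function(psl_a, psl_b, intervals_a, intervals_b,
                             overlap_min = 40L, end_tolerance = 0L) {
  chk_intervals <- function(psl, iv, label) {
    missing <- setdiff(psl$qName, iv$id)
    if (length(missing))
      stop("read '", missing[1], "' present in PSL ", label,
           " but missing from its interval table")
  }
  chk_intervals(psl_a, intervals_a, "A")
  chk_intervals(psl_b, intervals_b, "B")
  excluded <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  excl <- function(ids, reason) {
    if (length(ids))
      rbind(excluded, data.frame(id = ids, reason = reason,
                                 stringsAsFactors = FALSE))
    else excluded
  }
  multi_a <- unique(psl_a$qName[duplicated(psl_a$qName)])
  multi_b <- unique(psl_b$qName[duplicated(psl_b$qName)])
  excluded <- excl(union(multi_a, multi_b), "multi_mapped")
  a <- psl_a[!psl_a$qName %in% multi_a, , drop = FALSE]
  b <- psl_b[!psl_b$qName %in% multi_b, , drop = FALSE]
  common <- intersect(a$qName, b$qName)
  common <- setdiff(common, union(multi_a, multi_b))
  rows <- vector("list", length(common))
  n_kept <- 0L
  for (id in common) {
    ra <- a[a$qName == id, ]
    rb <- b[b$qName == id, ]
    if (ra$tName != rb$tName || ra$strand != rb$strand) {
      excluded <- excl(id, "different_target_or_strand")
      next
    }
    overlap <- min(ra$tEnd, rb$tEnd) - max(ra$tStart, rb$tStart)
    if (overlap < overlap_min) {
      excluded <- excl(id, "insufficient_overlap")
      next
    }
    ca <- classify_ends(ra, rb, end_tolerance)
    cb <- classify_ends(rb, ra, end_tolerance)
    n_kept <- n_kept + 1L
    rows[[n_kept]] <- data.frame(
      id = id, strand = ra$strand, overlap = overlap,
      class5_a = ca$class5, class3_a = ca$class3,
      class5_b = cb$class5, class3_b = cb$class3,
      delta5_a = ca$delta5, delta3_a = ca$delta3,
      delta5_b = cb$delta5, delta3_b = cb$delta3,
      stringsAsFactors = FALSE)
  }
  comparisons <- if (n_kept) do.call(rbind, rows[seq_len(n_kept)]) else
    data.frame(id = character(0), strand = character(0), overlap = integer(0),
               class5_a = character(0), class3_a = character(0),
               class5_b = character(0), class3_b = character(0),
               delta5_a = integer(0), delta3_a = integer(0),
               delta5_b = integer(0), delta3_b = integer(0),
               stringsAsFactors = FALSE)
  summ <- expand.grid(cleaner = c("A", "B"), end = c("5'", "3'"),
                      class = c("correct", "over", "under"),
                      stringsAsFactors = FALSE)
  summ$n <- mapply(function(cl, e, cls) {
    col <- paste0("class", if (e == "5'") "5" else "3", "_", tolower(cl))
    sum(comparisons[[col]] == cls)
  }, summ$cleaner, summ$end, summ$class)
  structure(list(comparisons = comparisons, summary = summ,
                 excluded = excluded, overlap_min = overlap_min),
            class = "trim_comparison")
}

# Classify one cleaner (x) against the other (y) at both read ends.
# Both records are assumed same target and strand.
classify_ends <- function(x, y, tol) {
  # read-oriented query coordinates
  flip <- x$strand == "-"
  q0 <- if (flip) x$qSize - x$qEnd else x$qStart
  q1 <- if (flip) x$qSize - x$qStart else x$qEnd
  # genome boundaries corresponding to the read 5'/3' ends
  g5 <- if (flip) x$tEnd else x$tStart
  g3 <- if (flip) x$tStart else x$tEnd
  o5 <- if (flip) y$tEnd else y$tStart
  o3 <- if (flip) y$tStart else y$tEnd
  # best boundary of the pair: outermost genome position
  best5 <- if (flip) max(g5, o5) else min(g5, o5)
  best3 <- if (flip) min(g3, o3) else max(g3, o3)
  res5 <- if (q0 > tol) list("under", -q0)
    else if (g5 != best5) list("over", abs(g5 - best5))
    else list("correct", 0L)
  res3 <- if ((x$qSize - q1) > tol) list("under", -(x$qSize - q1))
    else if (g3 != best3) list("over", abs(g3 - best3))
    else list("correct", 0L)
  list(class5 = res5[[1]], delta5 = as.integer(res5[[2]]),
       class3 = res3[[1]], delta3 = as.integer(res3[[2]]))
}

#' @export
print.trim_comparison <- function(x, ...) {
  cat("<trim_comparison> ", nrow(x$comparisons), " reads evaluated, ",
      nrow(x$excluded), " excluded (overlap_min = ", x$overlap_min, ")\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Tally k-mers spanning over-trimmed junctions
#'
#' For every over-trimmed read end, extracts the `k` bases of the original
#' read anchored at the outer edge of the over-trimmed region (so the window
#' always includes the over-trimmed bases and, when the over-trim is shorter
#' than `k`, the adjacent retained bases) and tallies them. Windows clipped by
#' the read boundary are flagged. Used to ask whether apparent over-trimming
#' is in fact contaminant sequence (adapter fragments, poly-A) that happens to
#' continue in the genome.
#'
#' @param comparison A `trim_comparison` from [compare_trimming()].
#' @param reads Named character vector of the *original* read sequences.
#' @param intervals Data frame `id`, `start`, `end`: the evaluated cleaner's
#'   clean intervals on the original reads.
#' @param cleaner `"A"` or `"B"`: which cleaner's over-trims to audit.
#' @param k Window length (default 6).
#' @return A data.frame with columns `kmer`, `end` (`"5'"`/`"3'"`), `count`,
#'   `clipped`; empty when nothing was over-trimmed.
#' @export
audit_overtrim_kmers <- function(comparison, reads, intervals, cleaner = "A",
                                 k = 6L) {
  cmp <- comparison$comparisons
  suf <- tolower(cleaner)
  out <- list()
  iv <- setNames(split(intervals[, c("start", "end")], seq_len(nrow(intervals))),
                 intervals$id)
  grab <- function(id, lo, hi) {  # 0-based half-open, clipped
    s <- reads[[id]]
    clip <- lo < 0 || hi > nchar(s)
    lo <- max(0L, lo); hi <- min(nchar(s), hi)
    list(kmer = substr(s, lo + 1L, hi), clipped = clip)
  }
  for (r in seq_len(nrow(cmp))) {
    id <- cmp$id[r]
    if (is.null(iv[[id]])) next
    cs <- iv[[id]]$start; ce <- iv[[id]]$end
    d5 <- cmp[[paste0("delta5_", suf)]][r]
    if (cmp[[paste0("class5_", suf)]][r] == "over" && d5 > 0) {
      g <- grab(id, cs - d5, cs - d5 + k)
      out[[length(out) + 1L]] <- data.frame(kmer = g$kmer, end = "5'",
                                            clipped = g$clipped,
                                            stringsAsFactors = FALSE)
    }
    d3 <- cmp[[paste0("delta3_", suf)]][r]
    if (cmp[[paste0("class3_", suf)]][r] == "over" && d3 > 0) {
      g <- grab(id, ce + d3 - k, ce + d3)
      out[[length(out) + 1L]] <- data.frame(kmer = g$kmer, end = "3'",
                                            clipped = g$clipped,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(kmer = character(0), end = character(0),
                      count = integer(0), clipped = logical(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = list(kmer = df$kmer, end = df$end,
                                    clipped = df$clipped), FUN = sum)
  agg <- agg[order(-agg$count, agg$kmer), c("kmer", "end", "count", "clipped")]
  rownames(agg) <- NULL
  agg
}
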