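#' Acceptance criteria for adapter/primer matches
#'
#' A located contaminant match is judged by one of two criteria depending on
#' where it falls. A hit whose read interval starts within `end_zone` bases of
#' the clean start, or ends within `end_zone` bases of the clean end, is an
#' *end* match and may be partial: it is accepted when its percent identity is
#' at least `end_min_pid`, the subject bases hanging past the read end number
#' at most `end_max_unaligned_subj`, and the read bases left between the hit
#' and the read end number at most `end_max_unaligned_read`. Any other hit is
#' a *middle* match and must be near-perfect: aligned length at least
#' `middle_min_len` and identity at least `middle_min_pid`.
#'
#' The numeric defaults are this package's documented configuration, chosen to
#' make middle matches near-exact while letting genuinely terminal partial
#' matches through.
#'
#' @param middle_min_len Minimum aligned length for middle matches (15).
#' @param middle_min_pid Minimum percent identity for middle matches (94).
#' @param end_min_pid Minimum percent identity for end matches (90).
#' @param end_max_unaligned_subj Maximum subject bases beyond the read end for
#'   an end match; `NULL` (default) means `len(subject) - 8`, i.e. at least 8
#'   subject bases must be present in the read.
#' @param end_max_unaligned_read Maximum read bases outside an end hit toward
#'   the read end (2).
#' @param end_zone Distance from a clean-interval end within which a hit
#'   counts as an end match; `NULL` (default) means
#'   `end_max_unaligned_read + 3`.
#' @return A list of class `match_criteria`.
#' @export
match_criteria <- function(middle_min_len = 15L, middle_min_pid = 94,
                           end_min_pid = 90, end_max_unaligned_subj = NULL,
                           end_max_unaligned_read = 2L, end_zone = NULL) {
  if (is.null(end_zone)) end_zone <- end_max_unaligned_read + 3L
  structure(list(middle_min_len = as.integer(middle_min_len),
                 middle_min_pid = middle_min_pid,
                 end_min_pid = end_min_pid,
                 end_max_unaligned_subj = end_max_unaligned_subj,
                 end_max_unaligned_read = as.integer(end_max_unaligned_read),
                 end_zone = as.integer(end_zone)),
            class = "match_criteria")
}

empty_hits <- function() {
  data.frame(name = character(0), role = character(0),
             orientation = character(0),
             read_start = integer(0), read_end = integer(0),
             subj_start = integer(0), subj_end = integer(0),
             subj_len = integer(0), pid = numeric(0), aln_len = integer(0),
             matches = integer(0), score = integer(0),
             oh_subj_left = integer(0), oh_subj_right = integer(0),
             gap_before = integer(0), gap_after = integer(0),
             kind = character(0), stringsAsFactors = FALSE)
}

#' Locate contaminant matches in a read
#'
#' Seed-and-extend search of each subject (adapter, primer or vector), in both
#' orientations, against the read's current clean interval: exact shared
#' `word_size`-mers ([seed_hits()]) are clustered by diagonal into anchors and
#' each anchor is extended with the banded aligner ([banded_nw_extend()]).
#' Hits are then filtered by the criteria in `criteria` -- the full-match
#' (middle) criterion applies to every hit and the partial-match end
#' criterion additionally accepts terminal hits -- and returned sorted by
#' read coordinate. Overlapping hits of the same subject
#' and orientation are collapsed to the best-scoring one. Matches shorter than
#' `word_size` carry no seed and are therefore undetectable; that is the
#' search's resolution limit.
#'
#' Read coordinates in the result are on the *original* read;
#' `gap_before`/`gap_after` count the clean-interval bases between the hit and
#' the clean start/end.
#'
#' @param read An active [scrub_read()].
#' @param subjects Data frame with columns `name`, `seq`, `role`.
#' @param criteria A [match_criteria()].
#' @param word_size Seed word length (default 11).
#' @param band Band half-width for extension (default 5).
#' @return A data.frame of accepted hits (possibly empty) with the columns of
#'   [banded_nw_extend()] plus `name`, `role`, `gap_before`, `gap_after` and
#'   `kind` (`"middle"`/`"end"`).
#' @export
locate_hits <- function(read, subjects, criteria = match_criteria(),
                        word_size = 11L, band = 5L) {
  if (!is_active(read) || nrow(subjects) == 0) return(empty_hits())
  s <- clean_seq(read)
  L <- nchar(s)
  if (L < word_size) return(empty_hits())
  rows <- list()
  row_name <- character(0); row_role <- character(0); row_ori <- character(0)
  for (k in seq_len(nrow(subjects))) {
    subj <- subjects$seq[k]
    m <- nchar(subj)
    seeds <- cpp_seed_hits(subj, s, as.integer(word_size))
    mg <- merge_seeds0(seeds$subj_pos, seeds$read_pos, seeds$orientation,
                       m, word_size, band)
    # Always probe flush placements at both interval ends, in both
    # orientations: sequencing errors at the read ends can destroy every
    # exact seed word, and the ends are exactly where partial matches are
    # expected. Probe alignments of unrelated sequence fail the identity
    # criteria and cost nothing.
    a_ori <- c(mg$orient, rep(c("forward", "reverse"), each = 2))
    a_ss <- c(mg$ss, rep(0L, 4))
    a_rs <- c(mg$rs, rep(c(0L, max(0L, L - m)), 2))
    for (a in seq_along(a_ori)) {
      oriented <- if (a_ori[a] == "reverse") revcomp_cached(subj) else subj
      v <- nw_extend0(oriented, s, a_ss[a], a_rs[a], band = band)
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <- v
      row_name <- c(row_name, subjects$name[k])
      row_role <- c(row_role, subjects$role[k])
      row_ori <- c(row_ori, a_ori[a])
    }
  }
  if (length(rows) == 0) return(empty_hits())
  mat <- do.call(rbind, rows)
  # collapse overlapping hits of the same subject and orientation, best
  # score first
  o <- order(-mat[, "score"], mat[, "read_start"])
  mat <- mat[o, , drop = FALSE]
  row_name <- row_name[o]; row_role <- row_role[o]; row_ori <- row_ori[o]
  keep <- rep(TRUE, nrow(mat))
  if (nrow(mat) > 1) for (a in seq_len(nrow(mat) - 1)) {
    if (!keep[a]) next
    for (b in (a + 1):nrow(mat)) {
      if (keep[b] && row_name[b] == row_name[a] && row_ori[b] == row_ori[a] &&
          mat[b, "read_start"] < mat[a, "read_end"] &&
          mat[b, "read_end"] > mat[a, "read_start"])
        keep[b] <- FALSE
    }
  }
  mat <- mat[keep, , drop = FALSE]
  hits <- data.frame(
    name = row_name[keep], role = row_role[keep], orientation = row_ori[keep],
    read_start = as.integer(mat[, "read_start"]),
    read_end = as.integer(mat[, "read_end"]),
    subj_start = as.integer(mat[, "subj_start"]),
    subj_end = as.integer(mat[, "subj_end"]),
    subj_len = nchar(subjects$seq)[match(row_name[keep], subjects$name)],
    pid = mat[, "pid"],
    aln_len = as.integer(mat[, "aln_len"]),
    matches = as.integer(mat[, "matches"]),
    score = as.integer(mat[, "score"]),
    oh_subj_left = as.integer(mat[, "oh_subj_left"]),
    oh_subj_right = as.integer(mat[, "oh_subj_right"]),
    stringsAsFactors = FALSE)
  hits$gap_before <- hits$read_start
  hits$gap_after <- L - hits$read_end
  near5 <- hits$gap_before <= criteria$end_zone
  near3 <- hits$gap_after <= criteria$end_zone
  max_subj <- if (is.null(criteria$end_max_unaligned_subj))
    pmax(0L, hits$subj_len - 8L) else criteria$end_max_unaligned_subj
  ok_end5 <- near5 & hits$pid >= criteria$end_min_pid &
    hits$oh_subj_left <= max_subj &
    hits$gap_before <= criteria$end_max_unaligned_read
  ok_end3 <- near3 & hits$pid >= criteria$end_min_pid &
    hits$oh_subj_right <= max_subj &
    hits$gap_after <= criteria$end_max_unaligned_read
  # The full-match criterion applies everywhere; the partial-match end
  # criterion additionally rescues genuinely terminal hits. Without this a
  # full-length near-perfect match sitting just inside the end zone (read
  # overhang above end_max_unaligned_read) would fall into a dead band
  # between the two rules.
  ok_mid <- hits$aln_len >= criteria$middle_min_len &
    hits$pid >= criteria$middle_min_pid
  ok_end <- ok_end5 | ok_end3
  hits$kind <- ifelse(ok_end, "end", "middle")
  hits <- hits[ok_end | ok_mid, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  cs <- read$clean[1]
  hits$read_start <- hits$read_start + cs
  hits$read_end <- hits$read_end + cs
  hits <- hits[order(hits$read_start, hits$read_end), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, names(empty_hits())]
}

read_error_types <- c("OK", "RF", "fr", "SF", "RE", "NF", "NR")

#' Classify a read by its amplification-primer hits
#'
#' An error-free read carries at most one forward primer match flush at the
#' 5' end of its clean interval and/or one reverse match flush at the 3' end.
#' Departures from that layout are protocol artifacts:
#'
#' * `RF` — a reverse match at the 5' end together with a forward match at the
#'   3' end (misoriented / chimeric construct);
#' * `fr` — forward and reverse matches of the *same* primer (self-ligation);
#' * `NF` / `NR` — two or more forward / reverse matches (primer
#'   concatenation);
#' * `SF` — a forward match with unaligned clean bases before it;
#' * `RE` — a reverse match with unaligned clean bases after it.
#'
#' When several patterns apply the biologically fatal ones win:
#' `RF > fr > NF > NR > SF > RE`. Reads matching no error pattern are `OK`.
#'
#' "Unaligned bases before/after" is judged with the tolerance
#' `end_max_unaligned_read` of the match criteria -- the same number of
#' terminal bases the end-match criterion already treats as negligible --
#' so that single-base boundary jitter from sequencing errors does not turn
#' a clean read into `SF`/`RE`. `SF`/`RE` additionally require the offending
#' hit not to sit flush at the opposite end, where the layout is a
#' misorientation (`RF`-type) signature instead.
#'
#' @param hits Hit table from [locate_hits()] restricted to amplification
#'   primers.
#' @param read The [scrub_read()] the hits belong to.
#' @param criteria The [match_criteria()] used for the search (supplies
#'   `end_zone`).
#' @return One of `"OK"`, `"RF"`, `"fr"`, `"SF"`, `"RE"`, `"NF"`, `"NR"`.
#' @export
classify_read <- function(hits, read, criteria = match_criteria()) {
  if (nrow(hits) == 0) return("OK")
  fwd <- hits[hits$orientation == "forward", , drop = FALSE]
  rev <- hits[hits$orientation == "reverse", , drop = FALSE]
  zone <- criteria$end_zone
  tol <- criteria$end_max_unaligned_read
  if (nrow(rev) && nrow(fwd) &&
      any(rev$gap_before <= zone) && any(fwd$gap_after <= zone))
    return("RF")
  if (length(intersect(fwd$name, rev$name)) > 0) return("fr")
  if (nrow(fwd) >= 2) return("NF")
  if (nrow(rev) >= 2) return("NR")
  if (nrow(fwd) && any(fwd$gap_before > tol & fwd$gap_after > zone))
    return("SF")
  if (nrow(rev) && any(rev$gap_after > tol & rev$gap_before > zone))
    return("RE")
  "OK"
}

#' Trim a read according to its primer hits and classification
#'
#' For `OK` reads the clean start advances past a flush 5' forward hit and the
#' clean end retreats before a flush 3' reverse hit. For erroneous types the
#' per-type policy applies: `"discard"` (default for `RF` and `fr`, whose
#' artifacts contaminate the whole insert) or `"salvage"` (default for `SF`,
#' `RE`, `NF`, `NR`), which keeps the longest hit-free sub-interval (leftmost
#' on ties). A read whose clean interval empties is discarded with reason
#' `primer_only`.
#'
#' @param read An active [scrub_read()].
#' @param hits Primer hit table from [locate_hits()].
#' @param type Classification from [classify_read()].
#' @param policy Named character vector mapping error types to `"discard"` or
#'   `"salvage"`.
#' @param criteria The [match_criteria()] used for the search (supplies the
#'   flush tolerance for `OK` trimming).
#' @param stage Stage label recorded in the trim log.
#' @return The updated read.
#' @export
trim_by_hits <- function(read, hits, type,
                         policy = c(RF = "discard", fr = "discard",
                                    SF = "salvage", RE = "salvage",
                                    NF = "salvage", NR = "salvage"),
                         criteria = match_criteria(),
                         stage = "primer") {
  if (!is_active(read) || nrow(hits) == 0) return(read)
  if (type == "OK") {
    tol <- criteria$end_max_unaligned_read
    cs <- read$clean[1]; ce <- read$clean[2]
    fwd <- hits[hits$orientation == "forward" & hits$gap_before <= tol, , drop = FALSE]
    rev <- hits[hits$orientation == "reverse" & hits$gap_after <= tol, , drop = FALSE]
    if (nrow(fwd)) cs <- max(fwd$read_end)
    if (nrow(rev)) ce <- min(ce, min(rev$read_start))
    if (cs >= ce) return(discard_read(read, "primer_only"))
    return(set_clean(read, cs, max(cs, ce), stage))
  }
  action <- policy[[type]]
  if (is.null(action) || action == "discard")
    return(discard_read(read, paste0("primer_", type)))
  iv <- longest_free_interval(read$clean, hits)
  if (is.null(iv)) return(discard_read(read, "primer_only"))
  set_clean(read, iv[1], iv[2], stage)
}

# Longest sub-interval of `clean` not covered by any hit (leftmost on ties);
# NULL when the hits cover everything.
longest_free_interval <- function(clean, hits) {
  if (nrow(hits) == 0) return(clean)
  iv <- hits[order(hits$read_start), c("read_start", "read_end"), drop = FALSE]
  iv$read_start <- pmax(iv$read_start, clean[1])
  iv$read_end <- pmin(iv$read_end, clean[2])
  merged <- list()
  cur <- c(iv$read_start[1], iv$read_end[1])
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    if (iv$read_start[k] <= cur[2]) cur[2] <- max(cur[2], iv$read_end[k])
    else { merged[[length(merged) + 1L]] <- cur; cur <- c(iv$read_start[k], iv$read_end[k]) }
  }
  merged[[length(merged) + 1L]] <- cur
  bounds <- c(clean[1], unlist(merged), clean[2])
  starts <- bounds[seq(1, length(bounds), by = 2)]
  ends <- bounds[seq(2, length(bounds), by = 2)]
  lens <- ends - starts
  if (max(lens) <= 0) return(NULL)
  k <- which.max(lens)  # first maximum = leftmost
  c(starts[k], ends[k])
}

# Salvage-style trimming for adapters and vectors: any accepted hit is
# contamination, keep the longest hit-free stretch.
trim_contaminants <- function(read, hits, stage, reason_if_consumed) {
  if (!is_active(read) || nrow(hits) == 0) return(read)
  iv <- longest_free_interval(read$clean, hits)
  if (is.null(iv)) return(discard_read(read, reason_if_consumed))
  set_clean(read, iv[1], iv[2], stage)
}
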