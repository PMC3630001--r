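#' A single sequencing read with its clean interval
#'
#' The unit record of the cleaning pipeline. A read keeps its full original
#' sequence throughout; trimming stages only narrow the `clean` interval
#' (0-based, half-open) and append to `trim_log`, so every stage's action can
#' be inspected afterwards and the QC report can be rebuilt from the logs.
#'
#' @param id Read identifier (unique within a set).
#' @param seq DNA sequence over `A`,`C`,`G`,`T`,`N` (case-insensitive input).
#' @param qual Optional integer vector of per-base Phred scores, same length
#'   as `seq`.
#' @return An object of class `scrub_read`: a list with fields `id`, `seq`,
#'   `qual`, `clean` (integer `c(start, end)`), `sample`, `status`
#'   (`"active"` or `"discarded"`), `discard_reason`, and `trim_log`.
#' @examples
#' r <- scrub_read("r1", "ACGTACGT")
#' clean_seq(r)
#' @export
scrub_read <- function(id, seq, qual = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("read '", id, "': sequence contains characters outside {A,C,G,T,N}")
  if (!is.null(qual)) {
    qual <- as.integer(qual)
    if (length(qual) != nchar(seq))
      stop("read '", id, "': quality length (", length(qual),
           ") does not match sequence length (", nchar(seq), ")")
    if (anyNA(qual) || any(qual < 0))
      stop("read '", id, "': quality scores must be non-negative integers")
  }
  structure(
    list(id = id, seq = seq, qual = qual,
         clean = c(0L, nchar(seq)),
         sample = NA_character_,
         status = "active",
         discard_reason = NA_character_,
         trim_log = list()),
    class = "scrub_read")
}

#' @export
print.scrub_read <- function(x, ...) {
  cat("<scrub_read> ", x$id, ": ", nchar(x$seq), " bp, clean [",
      x$clean[1], ",", x$clean[2], "), status ", x$status, sep = "")
  if (!is.na(x$sample)) cat(", sample ", x$sample, sep = "")
  if (!is.na(x$discard_reason)) cat(" (", x$discard_reason, ")", sep = "")
  cat("\n")
  invisible(x)
}

is_active <- function(read) read$status == "active"

#' Current clean subsequence / qualities of a read
#'
#' @param read A [scrub_read()].
#' @return `clean_seq`: the clean subsequence as a character scalar;
#'   `clean_qual`: the matching Phred scores (or `NULL`);
#'   `clean_length`: its length in bases.
#' @export
clean_seq <- function(read) {
  substr(read$seq, read$clean[1] + 1L, read$clean[2])
}

#' @rdname clean_seq
#' @export
clean_qual <- function(read) {
  if (is.null(read$qual)) return(NULL)
  if (read$clean[2] <= read$clean[1]) return(integer(0))
  read$qual[(read$clean[1] + 1L):read$clean[2]]
}

#' @rdname clean_seq
#' @export
clean_length <- function(read) read$clean[2] - read$clean[1]

# Narrow the clean interval and log the step. Stages may only narrow, never
# widen (nested trim_log invariant).
set_clean <- function(read, start, end, stage) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < read$clean[1] || end > read$clean[2] || start > end)
    stop("stage '", stage, "' on read '", read$id,
         "': new interval [", start, ",", end,
         ") is not nested in [", read$clean[1], ",", read$clean[2], ")")
  if (start == read$clean[1] && end == read$clean[2]) return(read)
  read$trim_log[[length(read$trim_log) + 1L]] <-
    list(stage = stage, before = read$clean, after = c(start, end))
  read$clean <- c(start, end)
  read
}

discard_read <- function(read, reason) {
  read$status <- "discarded"
  read$discard_reason <- reason
  read
}

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` maps to `N`.
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Tabulate the current trim intervals of a read set
#'
#' One row per read: its id, clean interval (0-based half-open coordinates on
#' the original sequence), clean length, assigned sample, status and discard
#' reason. This table is the interval input expected by [compare_trimming()].
#'
#' @param reads List of [scrub_read()] objects.
#' @return A data.frame with columns `id`, `start`, `end`, `length`, `sample`,
#'   `status`, `discard_reason`.
#' @export
trim_intervals <- function(reads) {
  data.frame(
    id = vapply(reads, `[[`, "", "id"),
    start = vapply(reads, function(r) r$clean[1], 0L),
    end = vapply(reads, function(r) r$clean[2], 0L),
    length = vapply(reads, clean_length, 0L),
    sample = vapply(reads, `[[`, "", "sample"),
    status = vapply(reads, `[[`, "", "status"),
    discard_reason = vapply(reads, `[[`, "", "discard_reason"),
    stringsAsFactors = FALSE)
}
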