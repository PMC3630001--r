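#' Per-step summary statistics
#'
#' Read/base counts and length/quality distributions of the *active* reads'
#' current clean intervals after a pipeline stage.
#'
#' @param reads List of [scrub_read()] objects.
#' @param step_name Label of the pipeline step.
#' @return A list of class `step_stats` with fields `step`, `n_reads`,
#'   `n_bases`, `min_len`, `max_len`, `len_hist` (named count vector) and
#'   `qual_hist` (named count vector over the clean-interval Phred scores; of
#'   length 0 when no read has qualities).
#' @export
collect_step <- function(reads, step_name) {
  active <- Filter(is_active, reads)
  lens <- vapply(active, clean_length, 0L)
  quals <- unlist(lapply(active, clean_qual))
  structure(list(
    step = step_name,
    n_reads = length(active),
    n_bases = sum(lens),
    min_len = if (length(lens)) min(lens) else 0L,
    max_len = if (length(lens)) max(lens) else 0L,
    len_hist = if (length(lens)) table(lens) else table(integer(0)),
    qual_hist = if (length(quals)) table(quals) else table(integer(0))),
    class = "step_stats")
}

#' Top over-represented k-mers of the cleaned sequences
#'
#' Counts all overlapping k-mers over the active reads' clean subsequences
#' (k-mers containing `N` are excluded from both numerator and denominator)
#' and reports the `top_n` most frequent as percentages of all counted
#' k-mers, descending, ties broken lexicographically.
#'
#' @param reads List of [scrub_read()] objects, or a character vector of
#'   sequences.
#' @param k k-mer length (default 6).
#' @param top_n Number of k-mers to report (default 30).
#' @return A data.frame with columns `kmer`, `count`, `percent`; empty when
#'   every sequence is shorter than `k`.
#' @export
top_kmers <- function(reads, k = 6L, top_n = 30L) {
  stopifnot(k >= 1)
  seqs <- if (is.character(reads)) toupper(reads) else
    vapply(Filter(is_active, reads), clean_seq, "")
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0)
    return(data.frame(kmer = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1), k:n)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0)
    return(data.frame(kmer = character(0), count = integer(0),
                      percent = numeric(0), stringsAsFactors = FALSE))
  tab <- table(kmers)
  df <- data.frame(kmer = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$percent <- 100 * df$count / sum(df$count)
  df <- df[order(-df$percent, df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_n)
}

# Assemble the full cleaning report from the per-stage artifacts gathered by
# clean_reads().
build_report <- function(steps, reads, classifications, primer_hits,
                         pos_offsets, k = 6L, top_n = 30L) {
  discarded <- Filter(Negate(is_active), reads)
  reasons <- vapply(discarded, `[[`, "", "discard_reason")
  combo <- table(factor(classifications$type, levels = read_error_types))
  sig <- table(classifications$signature)
  polya_len <- integer(0); polyt_len <- integer(0)
  for (r in reads) for (tl in r$trim_log) {
    if (tl$stage == "polya_a")
      polya_len <- c(polya_len, tl$before[2] - tl$after[2])
    if (tl$stage == "polya_t")
      polyt_len <- c(polyt_len, tl$after[1] - tl$before[1])
  }
  primer_hist <- if (nrow(primer_hits))
    table(paste0(primer_hits$name, ":", primer_hits$orientation)) else
      table(character(0))
  pos_hist <- if (nrow(primer_hits)) {
    off <- pos_offsets[primer_hits$id]
    table(primer_hits$read_start - off)
  } else table(integer(0))
  structure(list(
    steps = steps,
    kmer_top = top_kmers(reads, k = k, top_n = top_n),
    primer_match_hist = primer_hist,
    combo_table = combo,
    combo_signatures = sig,
    pos_hist = pos_hist,
    polya_hist = if (length(polya_len)) table(polya_len) else table(integer(0)),
    polyt_hist = if (length(polyt_len)) table(polyt_len) else table(integer(0)),
    discard_reasons = if (length(reasons)) table(reasons) else table(character(0)),
    n_input = length(reads),
    n_output = sum(vapply(reads, is_active, TRUE))),
    class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report> ", x$n_input, " reads in, ", x$n_output,
      " active after ", length(x$steps), " steps\n", sep = "")
  for (st in x$steps)
    cat(sprintf("  %-10s %7d reads %10d bases (len %d-%d)\n",
                st$step, st$n_reads, st$n_bases, st$min_len, st$max_len))
  if (length(x$discard_reasons)) {
    cat("  discards:\n")
    for (r in names(x$discard_reasons))
      cat("    ", r, ": ", x$discard_reasons[[r]], "\n", sep = "")
  }
  invisible(x)
}

hist_df <- function(tab, key) {
  k <- names(tab)
  if (is.null(k)) k <- character(0)
  df <- data.frame(k, as.integer(tab), stringsAsFactors = FALSE)
  names(df) <- c(key, "count")
  df
}

#' Write the cleaning report as TSV tables (and optional plots)
#'
#' Writes one tab-separated table per report component into `out_dir`:
#' `step_stats.tsv` (reads/bases/min/max per step), `length_hist.tsv` and
#' `qual_hist.tsv` (per-step distributions), `top_kmers.tsv`,
#' `primer_matches.tsv`, `read_classes.tsv` (error-type and hit-combination
#' tallies), `primer_positions.tsv` (hit positions relative to the
#' post-barcode clean start), `polya_lengths.tsv` (trimmed tail/head lengths)
#' and `discard_reasons.tsv`. With `plots = TRUE` a `report.pdf` of summary
#' charts is added.
#'
#' @param report A `cleaning_report` from [clean_reads()].
#' @param out_dir Output directory (created if missing).
#' @param plots Also draw the summary charts (default `FALSE`).
#' @return Invisibly, the output directory.
#' @export
render_report <- function(report, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  steps_df <- do.call(rbind, lapply(report$steps, function(st)
    data.frame(step = st$step, n_reads = st$n_reads, n_bases = st$n_bases,
               min_len = st$min_len, max_len = st$max_len,
               stringsAsFactors = FALSE)))
  if (is.null(steps_df))
    steps_df <- data.frame(step = character(0), n_reads = integer(0),
                           n_bases = integer(0), min_len = integer(0),
                           max_len = integer(0))
  tsv(steps_df, "step_stats.tsv")
  lh <- do.call(rbind, lapply(report$steps, function(st) {
    if (length(st$len_hist) == 0) return(NULL)
    data.frame(step = st$step, length = as.integer(names(st$len_hist)),
               count = as.integer(st$len_hist), stringsAsFactors = FALSE)
  }))
  if (is.null(lh)) lh <- data.frame(step = character(0), length = integer(0),
                                    count = integer(0))
  tsv(lh, "length_hist.tsv")
  qh <- do.call(rbind, lapply(report$steps, function(st) {
    if (length(st$qual_hist) == 0) return(NULL)
    data.frame(step = st$step, qual = as.integer(names(st$qual_hist)),
               count = as.integer(st$qual_hist), stringsAsFactors = FALSE)
  }))
  if (is.null(qh)) qh <- data.frame(step = character(0), qual = integer(0),
                                    count = integer(0))
  tsv(qh, "qual_hist.tsv")
  tsv(report$kmer_top, "top_kmers.tsv")
  tsv(hist_df(report$primer_match_hist, "primer_orientation"),
      "primer_matches.tsv")
  classes <- rbind(
    data.frame(class = names(report$combo_table),
               count = as.integer(report$combo_table), stringsAsFactors = FALSE),
    if (length(report$combo_signatures))
      data.frame(class = paste0("combo:", names(report$combo_signatures)),
                 count = as.integer(report$combo_signatures),
                 stringsAsFactors = FALSE))
  tsv(classes, "read_classes.tsv")
  tsv(hist_df(report$pos_hist, "position"), "primer_positions.tsv")
  pa <- rbind(
    if (length(report$polya_hist))
      data.frame(side = "polyA_tail", length = as.integer(names(report$polya_hist)),
                 count = as.integer(report$polya_hist), stringsAsFactors = FALSE),
    if (length(report$polyt_hist))
      data.frame(side = "polyT_head", length = as.integer(names(report$polyt_hist)),
                 count = as.integer(report$polyt_hist), stringsAsFactors = FALSE))
  if (is.null(pa)) pa <- data.frame(side = character(0), length = integer(0),
                                    count = integer(0))
  tsv(pa, "polya_lengths.tsv")
  tsv(hist_df(report$discard_reasons, "reason"), "discard_reasons.tsv")
  if (plots) {
    grDevices::pdf(file.path(out_dir, "report.pdf"), width = 8, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
    if (nrow(steps_df)) {
      graphics::barplot(steps_df$n_reads, names.arg = steps_df$step,
                        las = 2, main = "Reads per cleaning step",
                        ylab = "reads")
      graphics::barplot(steps_df$n_bases, names.arg = steps_df$step,
                        las = 2, main = "Bases per cleaning step",
                        ylab = "bases")
    }
    if (nrow(report$kmer_top))
      graphics::barplot(report$kmer_top$percent,
                        names.arg = report$kmer_top$kmer, las = 2,
                        cex.names = 0.6, main = "Top k-mers (%)")
    if (length(report$combo_table))
      graphics::barplot(as.integer(report$combo_table),
                        names.arg = names(report$combo_table),
                        main = "Read classes", ylab = "reads")
    if (nrow(pa))
      graphics::barplot(pa$count, names.arg = paste0(pa$side, ":", pa$length),
                        las = 2, cex.names = 0.6,
                        main = "Trimmed poly-A/poly-T lengths")
  }
  invisible(out_dir)
}
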