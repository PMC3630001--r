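#' Bundle of all cleaning-pipeline parameters
#'
#' @param barcode A [barcode_params()].
#' @param criteria A [match_criteria()] shared by the adapter, primer and
#'   vector searches.
#' @param polya A [polya_params()].
#' @param quality A [quality_params()].
#' @param word_size Seed word length of the contaminant search (default 11).
#' @param band Band half-width of the alignment extension (default 5).
#' @param policy Per-error-type trimming policy, see [trim_by_hits()].
#' @return A list of class `scrub_params`.
#' @export
scrub_params <- function(barcode = barcode_params(),
                         criteria = match_criteria(),
                         polya = polya_params(),
                         quality = quality_params(),
                         word_size = 11L, band = 5L,
                         policy = c(RF = "discard", fr = "discard",
                                    SF = "salvage", RE = "salvage",
                                    NF = "salvage", NR = "salvage")) {
  structure(list(barcode = barcode, criteria = criteria, polya = polya,
                 quality = quality, word_size = as.integer(word_size),
                 band = as.integer(band), policy = policy),
            class = "scrub_params")
}

default_stages <- c("barcode", "adapter", "primer", "vector", "polya", "quality")

#' Run the full read-cleaning pipeline
#'
#' Applies the requested stages in order (default: barcode demultiplexing,
#' adapter trimming, amplification-primer trimming with erroneous-read
#' classification, vector screening, poly-A/poly-T trimming, quality
#' trimming), collecting per-step statistics as it goes. Trimming is virtual:
#' reads keep their full sequence and only the clean interval narrows; use
#' [write_cleaned()] to materialise the results. Stages that need protocol
#' sequences the protocol does not define (e.g. `vector` with no vectors) are
#' skipped; the `quality` stage is skipped when no read carries qualities.
#'
#' @param reads List of [scrub_read()] objects.
#' @param protocol A [protocol_spec()].
#' @param params A [scrub_params()].
#' @param stages Character vector of stages to run, in order.
#' @return A list of class `scrub_result` with elements `reads` (the updated
#'   read list), `report` (a `cleaning_report`, see [render_report()]) and
#'   `classifications` (data.frame `id`, `type`, `signature` for every read
#'   that reached the primer stage).
#' @export
clean_reads <- function(reads, protocol, params = scrub_params(),
                        stages = default_stages) {
  stopifnot(inherits(protocol, "protocol_spec"))
  bad <- setdiff(stages, default_stages)
  if (length(bad)) stop("unknown stage '", bad[1], "'")
  steps <- list(collect_step(reads, "raw"))
  classifications <- data.frame(id = character(0), type = character(0),
                                signature = character(0),
                                stringsAsFactors = FALSE)
  primer_hits <- empty_hits()
  primer_hits$id <- character(0)
  pos_offsets <- setNames(vapply(reads, function(r) r$clean[1], 0L),
                          vapply(reads, `[[`, "", "id"))
  tab <- protocol_table(protocol)
  any_qual <- any(!vapply(reads, function(r) is.null(r$qual), TRUE))
  for (stage in stages) {
    if (stage == "barcode") {
      if (length(protocol$barcodes) == 0) next
      reads <- lapply(reads, trim_barcode, barcodes = protocol$barcodes,
                      params = params$barcode)
      pos_offsets <- setNames(vapply(reads, function(r) r$clean[1], 0L),
                              vapply(reads, `[[`, "", "id"))
    } else if (stage == "adapter") {
      subjects <- tab[tab$role %in% c("adapter5", "adapter3"), , drop = FALSE]
      if (nrow(subjects) == 0) next
      reads <- lapply(reads, function(r) {
        h <- locate_hits(r, subjects, params$criteria,
                         params$word_size, params$band)
        trim_contaminants(r, h, "adapter", "adapter_only")
      })
    } else if (stage == "vector") {
      subjects <- tab[tab$role == "vector", , drop = FALSE]
      if (nrow(subjects) == 0) next
      reads <- lapply(reads, function(r) {
        h <- locate_hits(r, subjects, params$criteria,
                         params$word_size, params$band)
        trim_contaminants(r, h, "vector", "vector_only")
      })
    } else if (stage == "primer") {
      subjects <- tab[tab$role %in% c("amp5", "amp3"), , drop = FALSE]
      if (nrow(subjects) == 0) next
      out <- vector("list", length(reads))
      cls_id <- character(0); cls_type <- character(0); cls_sig <- character(0)
      hit_acc <- list()
      for (k in seq_along(reads)) {
        r <- reads[[k]]
        if (!is_active(r)) { out[[k]] <- r; next }
        h <- locate_hits(r, subjects, params$criteria,
                         params$word_size, params$band)
        type <- classify_read(h, r, params$criteria)
        cls_id <- c(cls_id, r$id)
        cls_type <- c(cls_type, type)
        cls_sig <- c(cls_sig, hit_signature(h))
        if (nrow(h)) {
          h$id <- r$id
          hit_acc[[length(hit_acc) + 1L]] <- h
        }
        out[[k]] <- trim_by_hits(r, h, type, params$policy, params$criteria)
      }
      reads <- out
      classifications <- data.frame(id = cls_id, type = cls_type,
                                    signature = cls_sig,
                                    stringsAsFactors = FALSE)
      if (length(hit_acc))
        primer_hits <- do.call(rbind, c(list(primer_hits), hit_acc))
    } else if (stage == "polya") {
      reads <- lapply(reads, trim_polya, params = params$polya)
    } else if (stage == "quality") {
      if (!any_qual) next
      reads <- lapply(reads, trim_quality, params = params$quality)
    }
    steps[[length(steps) + 1L]] <- collect_step(reads, stage)
  }
  report <- build_report(steps, reads, classifications, primer_hits,
                         pos_offsets)
  structure(list(reads = reads, report = report,
                 classifications = classifications),
            class = "scrub_result")
}

# Compact primer-hit layout signature ("F+R", "F", "R", "none", "2F+R", ...)
# for the good/bad read-combination tally of the report.
hit_signature <- function(hits) {
  nf <- sum(hits$orientation == "forward")
  nr <- sum(hits$orientation == "reverse")
  if (nf == 0 && nr == 0) return("none")
  f <- if (nf == 0) "" else if (nf == 1) "F" else paste0(nf, "F")
  r <- if (nr == 0) "" else if (nr == 1) "R" else paste0(nr, "R")
  paste(Filter(nzchar, c(f, r)), collapse = "+")
}

#' @export
print.scrub_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Split cleaned reads by assigned sample
#'
#' Writes one FASTA per sample, named `<prefix>.<sample>.fasta`, containing
#' the clean subsequences of the active reads assigned to that sample.
#'
#' @param reads List of [scrub_read()] objects (after [clean_reads()]).
#' @param prefix Output path prefix.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_by_sample <- function(reads, prefix) {
  active <- Filter(function(r) is_active(r) && !is.na(r$sample), reads)
  samples <- vapply(active, `[[`, "", "sample")
  out <- character(0)
  for (sm in sort(unique(samples))) {
    path <- paste0(prefix, ".", sm, ".fasta")
    write_cleaned(active[samples == sm], path)
    out[sm] <- path
  }
  invisible(out)
}
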