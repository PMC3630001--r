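#' Barcode search parameters
#'
#' @param max_errors Maximum mismatches + indels tolerated between a barcode
#'   and the read's 5' end (default 2).
#' @param require_barcode Discard reads without an acceptable barcode
#'   (reason `no_barcode`)? Default `TRUE`.
#' @param max_offset Maximum number of read bases that may precede the
#'   barcode. The default 0 anchors the search at the very 5' end of the
#'   current clean interval.
#' @return A list of class `barcode_params`.
#' @export
barcode_params <- function(max_errors = 2L, require_barcode = TRUE,
                           max_offset = 0L) {
  stopifnot(max_errors >= 0, max_offset >= 0)
  structure(list(max_errors = as.integer(max_errors),
                 require_barcode = isTRUE(require_barcode),
                 max_offset = as.integer(max_offset)),
            class = "barcode_params")
}

#' Identify, assign and trim the 5' barcode of a read
#'
#' Each barcode is aligned semi-globally against the 5' end of the read's
#' current clean interval ([semiglobal_prefix_align()]). The barcode with the
#' fewest errors wins; the read's `sample` is set to its name and the clean
#' start advances past the barcode alignment. If no barcode aligns within
#' `max_errors` the read is discarded with reason `no_barcode` (when
#' `require_barcode`); if two *different* barcodes tie at the minimal error
#' count the read is discarded with reason `ambiguous_barcode`, so that the
#' QC report can count ambiguity separately.
#'
#' @param read An active [scrub_read()].
#' @param barcodes Named character vector of barcode sequences.
#' @param params A [barcode_params()].
#' @return The updated read.
#' @export
trim_barcode <- function(read, barcodes, params = barcode_params()) {
  if (!is_active(read)) return(read)
  stopifnot(length(barcodes) > 0, !is.null(names(barcodes)))
  s <- clean_seq(read)
  best_err <- rep(NA_integer_, length(barcodes))
  best_end <- rep(NA_integer_, length(barcodes))
  for (k in seq_along(barcodes)) {
    err <- NA_integer_; end <- NA_integer_
    for (off in 0:params$max_offset) {
      if (off >= nchar(s)) break
      r <- semiglobal_prefix_align(barcodes[[k]], substr(s, off + 1L, nchar(s)),
                                   params$max_errors)
      if (is.na(err) || r$errors < err) { err <- r$errors; end <- r$read_end + off }
    }
    best_err[k] <- err; best_end[k] <- end
  }
  ok <- which(!is.na(best_err) & best_err <= params$max_errors)
  if (length(ok) == 0) {
    if (params$require_barcode) return(discard_read(read, "no_barcode"))
    return(read)
  }
  minv <- min(best_err[ok])
  winners <- ok[best_err[ok] == minv]
  if (length(winners) > 1)
    return(discard_read(read, "ambiguous_barcode"))
  read$sample <- names(barcodes)[winners]
  set_clean(read, read$clean[1] + best_end[winners], read$clean[2], "barcode")
}
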