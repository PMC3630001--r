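#' Poly-A / poly-T trimming parameters
#'
#' The tail model: a window of bases anchored near a clean-interval end
#' qualifies as a tail when its length is at least `min_len`, the fraction of
#' `A` (3' side) or `T` (5' side) in it is strictly greater than
#' `min_fraction`, and its outer edge lies within `max_end_offset` bases of
#' the interval end. Among all qualifying windows the longest is trimmed
#' (ties resolved toward trimming more, i.e. the outermost longest window).
#'
#' @param min_len Minimum tail length (default 8).
#' @param min_fraction Minimum A (or T) fraction, exclusive bound, in (0, 1]
#'   (default 0.75).
#' @param max_end_offset Maximum distance of the window's outer edge from the
#'   clean-interval end (default 3).
#' @param both_sides Also trim poly-T heads at the 5' side (default `TRUE`).
#' @return A list of class `polya_params`.
#' @export
polya_params <- function(min_len = 8L, min_fraction = 0.75,
                         max_end_offset = 3L, both_sides = TRUE) {
  stopifnot(min_len >= 1, min_fraction > 0, min_fraction <= 1,
            max_end_offset >= 0)
  structure(list(min_len = as.integer(min_len),
                 min_fraction = min_fraction,
                 max_end_offset = as.integer(max_end_offset),
                 both_sides = isTRUE(both_sides)),
            class = "polya_params")
}

# New clean.end after 3'-side poly-A search on seq[clean), or NULL when no
# window qualifies. Enumerates, for each admissible window end e, the longest
# window [i, e) with A-fraction strictly above the cutoff and length >=
# min_len; the overall longest wins, outermost (largest trim) on ties.
polya_boundary3 <- function(seq, clean, p, base = "A") {
  L <- clean[2] - clean[1]
  if (L < p$min_len) return(NULL)
  s <- substr(seq, clean[1] + 1L, clean[2])
  isb <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == base)
  cum <- c(0L, cumsum(isb))
  best_len <- 0L; best_i <- NA_integer_
  for (e in seq(L, max(p$min_len, L - p$max_end_offset), by = -1L)) {
    i_cand <- 0:(e - p$min_len)
    len <- e - i_cand
    frac_ok <- (cum[e + 1L] - cum[i_cand + 1L]) > p$min_fraction * len
    if (!any(frac_ok)) next
    i_min <- i_cand[which(frac_ok)[1]]  # smallest i = longest window at this e
    if ((e - i_min) > best_len || ((e - i_min) == best_len && i_min < best_i)) {
      best_len <- e - i_min; best_i <- i_min
    }
  }
  if (best_len == 0L) return(NULL)
  clean[1] + best_i
}

# Mirror image for the 5'-side poly-T head: windows [s, j) with s within
# max_end_offset of the clean start; returns the new clean.start or NULL.
polya_boundary5 <- function(seq, clean, p, base = "T") {
  L <- clean[2] - clean[1]
  if (L < p$min_len) return(NULL)
  s <- substr(seq, clean[1] + 1L, clean[2])
  isb <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == base)
  cum <- c(0L, cumsum(isb))
  best_len <- 0L; best_j <- NA_integer_
  for (st in seq(0L, min(p$max_end_offset, L - p$min_len), by = 1L)) {
    j_cand <- (st + p$min_len):L
    len <- j_cand - st
    frac_ok <- (cum[j_cand + 1L] - cum[st + 1L]) > p$min_fraction * len
    if (!any(frac_ok)) next
    j_max <- j_cand[rev(which(frac_ok))[1]]  # largest j = longest window here
    if ((j_max - st) > best_len || ((j_max - st) == best_len && j_max > best_j)) {
      best_len <- j_max - st; best_j <- j_max
    }
  }
  if (best_len == 0L) return(NULL)
  clean[1] + best_j
}

#' Trim a poly-A tail (and optionally a poly-T head)
#'
#' Searches the 3' side of the clean interval for a qualifying poly-A window
#' and, when `both_sides`, the 5' side for a poly-T window (see
#' [polya_params()] for the model). The 3' side is trimmed first, then the 5'
#' side on the narrowed interval. A no-op when no window qualifies. Trim-log
#' stages are `polya_a` (tail) and `polya_t` (head), so the QC report can
#' histogram tail and head lengths separately.
#'
#' @param read An active [scrub_read()].
#' @param params A [polya_params()].
#' @return The updated read.
#' @export
trim_polya <- function(read, params = polya_params()) {
  if (!is_active(read)) return(read)
  e <- polya_boundary3(read$seq, read$clean, params)
  if (!is.null(e)) read <- set_clean(read, read$clean[1], e, "polya_a")
  if (params$both_sides) {
    s <- polya_boundary5(read$seq, read$clean, params)
    if (!is.null(s)) read <- set_clean(read, s, read$clean[2], "polya_t")
  }
  read
}
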