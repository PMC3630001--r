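#' Quality-trimming parameters
#'
#' @param window Sliding-window length in bases (default 10).
#' @param min_mean_q Minimum window mean Phred score (default 20).
#' @param min_len Minimum clean length a read must retain; shorter reads are
#'   discarded with reason `low_quality` (default 40).
#' @return A list of class `quality_params`.
#' @export
quality_params <- function(window = 10L, min_mean_q = 20, min_len = 40L) {
  stopifnot(window >= 1, min_mean_q >= 0, min_len >= 0)
  structure(list(window = as.integer(window), min_mean_q = min_mean_q,
                 min_len = as.integer(min_len)),
            class = "quality_params")
}

#' Trim low-quality ends using a sliding window of Phred scores
#'
#' From the 5' end of the clean interval, the boundary advances one base at a
#' time while the mean Phred score of the next `window` bases is below
#' `min_mean_q`; once an acceptable window is found the boundary settles on
#' its first base scoring at least `min_mean_q`, so a stretch of poor bases
#' rescued only by the window mean is still removed. The 3' boundary retreats
#' symmetrically over the remaining interval, and the two scans repeat until
#' the interval is stable. Windows are clipped where fewer than `window`
#' bases remain. If the surviving interval is shorter than `min_len` the read
#' is discarded with reason `low_quality`. Reads without quality scores are
#' left untouched (with a warning).
#'
#' @param read An active [scrub_read()] with per-base qualities.
#' @param params A [quality_params()].
#' @return The updated read.
#' @export
trim_quality <- function(read, params = quality_params()) {
  if (!is_active(read)) return(read)
  if (is.null(read$qual)) {
    warning("read '", read$id, "' has no quality scores; quality trimming skipped")
    return(read)
  }
  q <- clean_qual(read)
  L <- length(q)
  w <- params$window
  cum <- c(0, cumsum(as.numeric(q)))
  wmean <- function(s, e) {  # mean over q[(s+1)..e], 0-based half-open [s,e)
    (cum[e + 1] - cum[s + 1]) / (e - s)
  }
  s <- 0L
  e <- L
  repeat {
    s0 <- s; e0 <- e
    while (s < e && wmean(s, min(e, s + w)) < params$min_mean_q) s <- s + 1L
    if (s < e) {
      good <- which(q[(s + 1L):min(e, s + w)] >= params$min_mean_q)
      if (length(good)) s <- s + good[1] - 1L
    }
    while (e > s && wmean(max(s, e - w), e) < params$min_mean_q) e <- e - 1L
    if (e > s) {
      lo <- max(s, e - w)
      good <- which(q[(lo + 1L):e] >= params$min_mean_q)
      if (length(good)) e <- lo + good[length(good)]
    }
    if (s == s0 && e == e0) break
  }
  if ((e - s) < params$min_len) return(discard_read(read, "low_quality"))
  set_clean(read, read$clean[1] + s, read$clean[1] + e, "quality")
}
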