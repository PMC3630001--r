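#' Sequencing protocol specification
#'
#' Bundles the sample barcodes, sequencing adapters, amplification primers and
#' (optionally) vector sequences of a library protocol. All sequences are
#' uppercased and validated against the `{A,C,G,T,N}` alphabet; names must be
#' unique within each category.
#'
#' @param barcodes Named character vector of 5' barcode (MID) sequences.
#' @param adapters5,adapters3 Named character vectors of 5'/3' sequencing
#'   adapters.
#' @param primers Data frame with columns `name`, `seq`, `role`
#'   (`"amp5"` or `"amp3"`) describing amplification primers.
#' @param vectors Named character vector of vector sequences (optional).
#' @return An object of class `protocol_spec`.
#' @seealso [read_protocol()], [write_protocol()]
#' @export
protocol_spec <- function(barcodes = character(0),
                          adapters5 = character(0),
                          adapters3 = character(0),
                          primers = data.frame(name = character(0),
                                               seq = character(0),
                                               role = character(0)),
                          vectors = character(0)) {
  chk <- function(x, what) {
    if (length(x) == 0) return(setNames(character(0), character(0)))
    x <- setNames(toupper(x), names(x))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(what, ": every sequence must be named")
    if (anyDuplicated(names(x))) stop(what, ": duplicate names")
    if (any(!nzchar(x))) stop(what, ": empty sequence")
    if (any(grepl("[^ACGTN]", x))) stop(what, ": non-ACGTN characters")
    x
  }
  primers <- as.data.frame(primers, stringsAsFactors = FALSE)
  if (nrow(primers)) {
    primers$seq <- toupper(primers$seq)
    if (any(!primers$role %in% c("amp5", "amp3")))
      stop("primers: role must be 'amp5' or 'amp3'")
    if (anyDuplicated(primers$name)) stop("primers: duplicate names")
    if (any(!nzchar(primers$seq)) || any(grepl("[^ACGTN]", primers$seq)))
      stop("primers: invalid sequence")
  }
  structure(list(barcodes = chk(barcodes, "barcodes"),
                 adapters5 = chk(adapters5, "adapters5"),
                 adapters3 = chk(adapters3, "adapters3"),
                 primers = primers,
                 vectors = chk(vectors, "vectors")),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec> ",
      length(x$barcodes), " barcode(s), ",
      length(x$adapters5), "+", length(x$adapters3), " adapter(s), ",
      nrow(x$primers), " primer(s), ",
      length(x$vectors), " vector(s)\n", sep = "")
  invisible(x)
}

# All protocol sequences as one data.frame(name, seq, role).
protocol_table <- function(protocol) {
  rows <- list(
    data.frame(name = names(protocol$barcodes), seq = unname(protocol$barcodes),
               role = rep("barcode", length(protocol$barcodes)),
               stringsAsFactors = FALSE),
    data.frame(name = names(protocol$adapters5), seq = unname(protocol$adapters5),
               role = rep("adapter5", length(protocol$adapters5)),
               stringsAsFactors = FALSE),
    data.frame(name = names(protocol$adapters3), seq = unname(protocol$adapters3),
               role = rep("adapter3", length(protocol$adapters3)),
               stringsAsFactors = FALSE),
    if (nrow(protocol$primers))
      data.frame(name = protocol$primers$name, seq = protocol$primers$seq,
                 role = protocol$primers$role, stringsAsFactors = FALSE),
    data.frame(name = names(protocol$vectors), seq = unname(protocol$vectors),
               role = rep("vector", length(protocol$vectors)),
               stringsAsFactors = FALSE))
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Read a protocol definition from a role-encoded FASTA file
#'
#' The protocol FASTA dialect encodes each sequence's role in its header as
#' `name|role`, with role one of `barcode`, `adapter5`, `adapter3`, `amp5`,
#' `amp3`, `vector`. [write_protocol()] writes the same dialect back, so
#' protocols round-trip.
#'
#' @param path Path to the protocol FASTA file.
#' @return A [protocol_spec()].
#' @export
read_protocol <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("protocol file '", path, "' holds no sequences")
  hdr <- names(set)
  seqs <- toupper(as.character(set))
  parts <- strsplit(sub("\\s.*$", "", hdr), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("protocol header '", hdr[which(bad)[1]], "' is not of the form name|role")
  nm <- vapply(parts, `[[`, "", 1L)
  role <- vapply(parts, `[[`, "", 2L)
  known <- c("barcode", "adapter5", "adapter3", "amp5", "amp3", "vector")
  if (any(!role %in% known))
    stop("unknown role '", role[!role %in% known][1], "' in protocol file")
  if (any(!nzchar(seqs)))
    stop("protocol entry '", nm[!nzchar(seqs)][1], "' has an empty sequence")
  pick <- function(r) setNames(seqs[role == r], nm[role == r])
  pr <- role %in% c("amp5", "amp3")
  protocol_spec(barcodes = pick("barcode"),
                adapters5 = pick("adapter5"),
                adapters3 = pick("adapter3"),
                primers = data.frame(name = nm[pr], seq = seqs[pr],
                                     role = role[pr], stringsAsFactors = FALSE),
                vectors = pick("vector"))
}

#' @rdname read_protocol
#' @param protocol A [protocol_spec()] to export.
#' @export
write_protocol <- function(protocol, path) {
  tab <- protocol_table(protocol)
  set <- Biostrings::BStringSet(setNames(tab$seq, paste0(tab$name, "|", tab$role)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# --- 454-style QUAL files (plain text, space-separated Phred integers) ------

parse_qual_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("QUAL file '", path, "' holds no records")
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids)) stop("duplicate record id '", ids[duplicated(ids)][1],
                               "' in QUAL file")
  ends <- c(hdr[-1] - 1L, length(lines))
  quals <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    body <- if (hdr[k] + 1L > ends[k]) character(0) else lines[(hdr[k] + 1L):ends[k]]
    quals[[k]] <- as.integer(unlist(strsplit(paste(body, collapse = " "), "\\s+"))[
      nzchar(unlist(strsplit(paste(body, collapse = " "), "\\s+")))])
  }
  setNames(quals, ids)
}

write_qual_file <- function(quals, path, per_line = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(quals)) {
    writeLines(paste0(">", id), con)
    q <- quals[[id]]
    if (length(q)) {
      starts <- seq(1L, length(q), by = per_line)
      for (s in starts)
        writeLines(paste(q[s:min(s + per_line - 1L, length(q))], collapse = " "), con)
    }
  }
  invisible(path)
}

# --- reads ------------------------------------------------------------------

#' Read sequencing reads from FASTA (+ optional QUAL) or FASTQ
#'
#' Every read starts with a full-span clean interval and `active` status.
#' FASTQ qualities are decoded as Phred+33; QUAL files use the 454-style
#' space-separated integer format and are paired with FASTA records by id.
#'
#' @param path_seq Path to a FASTA or FASTQ file (auto-detected from the first
#'   record marker unless `format` is given).
#' @param path_qual Optional path to a QUAL file accompanying a FASTA input.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A list of [scrub_read()] objects.
#' @export
read_reads <- function(path_seq, path_qual = NULL,
                       format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path_seq, n = 1L)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    set <- Biostrings::readDNAStringSet(path_seq, format = "fastq",
                                        with.qualities = TRUE)
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
      stop("duplicate read id '", ids[duplicated(ids)][1], "' in '", path_seq, "'")
    qstr <- as.character(S4Vectors::mcols(set)$qualities)
    reads <- vector("list", length(set))
    for (k in seq_along(set)) {
      q <- utf8ToInt(qstr[k]) - 33L
      reads[[k]] <- scrub_read(ids[k], as.character(set[[k]]), q)
    }
    return(reads)
  }
  set <- Biostrings::readDNAStringSet(path_seq)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate read id '", ids[duplicated(ids)][1], "' in '", path_seq, "'")
  quals <- if (!is.null(path_qual)) parse_qual_file(path_qual) else NULL
  reads <- vector("list", length(set))
  for (k in seq_along(set)) {
    q <- NULL
    if (!is.null(quals)) {
      if (is.null(quals[[ids[k]]]))
        stop("read '", ids[k], "' has no matching QUAL record")
      q <- quals[[ids[k]]]
    }
    reads[[k]] <- scrub_read(ids[k], as.character(set[[k]]), q)
  }
  reads
}

#' Write cleaned reads (and, optionally, discarded reads)
#'
#' Active reads are emitted as their clean subsequence, with the clean
#' coordinates (on the original read) and the assigned sample recorded in the
#' FASTA description. Active reads whose clean interval has become empty are
#' moved to the discarded set with reason `empty_after_trim`. Discarded reads
#' are written with their full original sequence and the discard reason in the
#' header.
#'
#' @param reads List of [scrub_read()] objects.
#' @param out_fasta Output FASTA path for cleaned reads.
#' @param out_qual Optional output QUAL path (clean-interval scores).
#' @param discarded_fasta Optional output FASTA path for discarded reads.
#' @return Invisibly, the read list with any `empty_after_trim` discards
#'   applied.
#' @export
write_cleaned <- function(reads, out_fasta, out_qual = NULL,
                          discarded_fasta = NULL) {
  reads <- lapply(reads, function(r) {
    if (is_active(r) && clean_length(r) == 0L) discard_read(r, "empty_after_trim")
    else r
  })
  active <- Filter(is_active, reads)
  hdr <- vapply(active, function(r) {
    paste0(r$id, " clean=", r$clean[1], "-", r$clean[2],
           if (!is.na(r$sample)) paste0(" sample=", r$sample) else "")
  }, "")
  seqs <- vapply(active, clean_seq, "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(seqs, hdr)),
                              out_fasta)
  if (!is.null(out_qual)) {
    qs <- lapply(active, clean_qual)
    keep <- !vapply(qs, is.null, TRUE)
    write_qual_file(setNames(qs[keep], hdr[keep]), out_qual)
  }
  if (!is.null(discarded_fasta)) {
    disc <- Filter(Negate(is_active), reads)
    dh <- vapply(disc, function(r) paste0(r$id, " reason=", r$discard_reason), "")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(vapply(disc, `[[`, "", "seq"), dh)),
      discarded_fasta)
  }
  invisible(reads)
}

# --- PSL --------------------------------------------------------------------

psl_columns <- c("matches", "misMatches", "repMatches", "nCount",
                 "qNumInsert", "qBaseInsert", "tNumInsert", "tBaseInsert",
                 "strand", "qName", "qSize", "qStart", "qEnd",
                 "tName", "tSize", "tStart", "tEnd",
                 "blockCount", "blockSizes", "qStarts", "tStarts")

#' Read alignments in UCSC PSL format
#'
#' Accepts the 21-column tab-separated PSL body, with or without the 5-line
#' `psLayout` header. PSL coordinates are already 0-based half-open and are
#' kept as-is. Rows with fewer than 21 columns are an error.
#'
#' @param path Path to a PSL file.
#' @return A data.frame with the standard PSL columns.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1], "psLayout")) {
    dash <- grep("^-{5,}", lines)
    if (length(dash) == 0) stop("malformed psLayout header in '", path, "'")
    lines <- lines[-seq_len(dash[1])]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 21), psl_columns),
                         stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 21))
    stop("PSL row ", which(nf < 21)[1], " has ", nf[nf < 21][1],
         " columns; 21 expected")
  mat <- t(vapply(fields, function(f) f[1:21], character(21)))
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- psl_columns
  num <- setdiff(psl_columns, c("strand", "qName", "tName",
                                "blockSizes", "qStarts", "tStarts"))
  for (cn in num) out[[cn]] <- as.integer(out[[cn]])
  bad <- out$qEnd <= out$qStart | out$qEnd > out$qSize | out$qStart < 0 |
    out$tEnd <= out$tStart | out$tEnd > out$tSize | out$tStart < 0
  if (any(bad))
    stop("PSL row ", which(bad)[1], ": alignment interval outside sequence bounds")
  out
}

#' Construct a single PSL record
#'
#' Convenience constructor for building alignment tables in code (for the
#' trimming evaluator and for tests); fills the block-structure columns with a
#' single block consistent with the intervals.
#'
#' @param qName,qSize,qStart,qEnd Query id, length, aligned interval
#'   (0-based half-open).
#' @param tName,tSize,tStart,tEnd Target equivalents.
#' @param strand `"+"` or `"-"`.
#' @param matches Match count (defaults to the aligned query span).
#' @return A one-row data.frame with the standard PSL columns.
#' @export
psl_record <- function(qName, qSize, qStart, qEnd, tName, tSize, tStart, tEnd,
                       strand = "+", matches = qEnd - qStart) {
  data.frame(matches = as.integer(matches), misMatches = 0L, repMatches = 0L,
             nCount = 0L, qNumInsert = 0L, qBaseInsert = 0L,
             tNumInsert = 0L, tBaseInsert = 0L, strand = strand,
             qName = qName, qSize = as.integer(qSize),
             qStart = as.integer(qStart), qEnd = as.integer(qEnd),
             tName = tName, tSize = as.integer(tSize),
             tStart = as.integer(tStart), tEnd = as.integer(tEnd),
             blockCount = 1L,
             blockSizes = paste0(qEnd - qStart, ","),
             qStarts = paste0(qStart, ","),
             tStarts = paste0(tStart, ","),
             stringsAsFactors = FALSE)
}

#' @rdname read_psl
#' @param psl A data.frame of PSL records.
#' @export
write_psl <- function(psl, path) {
  write.table(psl[, psl_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
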