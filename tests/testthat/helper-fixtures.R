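# Small fixed fixtures shared by tests. The protocol sequences are arbitrary
# but chosen to be homopolymer-free and mutually dissimilar.

tiny_protocol <- function() {
  protocol_spec(
    barcodes = c(M1 = "ACGAGTGCGT", M2 = "TGATACGTCT"),
    adapters5 = c(A5 = "CGTATCGCCTCCCTCGCGCCA"),
    adapters3 = c(A3 = "CTGAGACTGCCAAGGCACAC"),
    primers = data.frame(
      name = c("P5", "P3"),
      seq = c("AAGCAGTGGTATCAACGCAGAGT", "ATTCTAGAGGCCGAGGCGGCCGA"),
      role = c("amp5", "amp3"), stringsAsFactors = FALSE))
}

# A read assembled from explicit parts; returns the read plus the 0-based
# part boundaries so tests can assert exact coordinates.
build_read <- function(..., id = "r1", qual = NULL) {
  parts <- list(...)
  seq <- paste(unlist(parts), collapse = "")
  ends <- cumsum(vapply(parts, nchar, 0L))
  starts <- c(0L, ends[-length(ends)])
  names(starts) <- names(parts)
  names(ends) <- names(parts)
  list(read = scrub_read(id, seq, qual), starts = starts, ends = ends)
}

write_tmp <- function(lines, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
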