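BASES <- c("A", "C", "G", "T")

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(len) paste(sample(BASES, len, replace = TRUE), collapse = "")

has_homopolymer <- function(seq, run = 5L) {
  grepl(paste0("A{", run, "}|C{", run, "}|G{", run, "}|T{", run, "}"), seq)
}

shares_word <- function(a, b, word_size = 11L) {
  if (nchar(a) < word_size || nchar(b) < word_size) return(FALSE)
  nrow(seed_hits(a, b, word_size)) > 0
}

#' Generate a synthetic sequencing protocol
#'
#' Builds a random but reproducible [protocol_spec()] for simulation and
#' testing: `n_barcodes` barcodes at pairwise edit distance at least
#' `barcode_min_dist`, one 5' and one 3' sequencing adapter, and a 5'/3'
#' amplification primer pair. Sequences are rejection-sampled so that no two
#' protocol sequences share an exact 11-mer in either orientation and none
#' contains a homopolymer of 5 or more bases; this keeps the planted
#' contaminants of [simulate_reads()] unambiguously identifiable, so that a
#' per-read ground truth is well defined.
#'
#' @param n_barcodes Number of barcodes (default 8).
#' @param barcode_len Barcode length (default 10).
#' @param barcode_min_dist Minimum pairwise edit distance between barcodes
#'   (default 5).
#' @param seed RNG seed.
#' @return A [protocol_spec()].
#' @export
sim_protocol <- function(n_barcodes = 8L, barcode_len = 10L,
                         barcode_min_dist = 5L, seed = 101L) {
  with_seed(seed, {
    pool <- character(0)      # sequences already accepted (for 11-mer guard)
    draw <- function(len, extra_ok = function(s) TRUE) {
      repeat {
        s <- rand_dna(len)
        if (has_homopolymer(s)) next
        if (any(vapply(pool, function(p) shares_word(p, s) ||
                         shares_word(revcomp(p), s), TRUE))) next
        if (!extra_ok(s)) next
        return(s)
      }
    }
    barcodes <- character(0)
    for (k in seq_len(n_barcodes)) {
      bc <- draw(barcode_len, extra_ok = function(s) {
        length(barcodes) == 0 ||
          all(utils::adist(s, barcodes) >= barcode_min_dist)
      })
      barcodes <- c(barcodes, bc)
      pool <- c(pool, bc)
    }
    names(barcodes) <- sprintf("MID%02d", seq_len(n_barcodes))
    ad5 <- draw(25L); pool <- c(pool, ad5)
    ad3 <- draw(22L); pool <- c(pool, ad3)
    p5 <- draw(23L); pool <- c(pool, p5)
    p3 <- draw(23L); pool <- c(pool, p3)
    protocol_spec(
      barcodes = barcodes,
      adapters5 = c(ADAPT_A = ad5),
      adapters3 = c(ADAPT_B = ad3),
      primers = data.frame(name = c("AMP5", "AMP3"), seq = c(p5, p3),
                           role = c("amp5", "amp3"), stringsAsFactors = FALSE))
  })
}

#' Simulation configuration
#'
#' Defines the study conditions of the synthetic-read generator: reads are
#' assembled as `[barcode][adapter5][primer layout per artifact
#' type][insert][poly-A tail][revcomp(3' primer)][adapter3]` and then
#' corrupted by per-base substitutions and indels. `artifact_mix` gives the
#' probability of each read class; the error classes plant the corresponding
#' primer-layout artifact (misoriented primers for `RF`, a self-ligated primer
#' pair for `fr`, leading junk before the 5' primer for `SF`, trailing junk
#' after the 3' primer for `RE`, tandem primer copies for `NF`/`NR`). A
#' fraction `polyt_prob` of `OK` reads is built in head-to-tail orientation
#' with a 5' poly-T head instead of the 3' poly-A tail.
#'
#' Inserts are rejection-sampled to share no exact 11-mer (either orientation)
#' with any protocol sequence, and planted tails are at least `polya$min_len`
#' long; the annotated true interval applies the poly-A window model of
#' `polya` to the noise-free read, because transcript bases indistinguishable
#' from the tail have no observable boundary (see the methods vignette).
#'
#' Quality scores emulate a 454-like profile: a high plateau with a linear 3'
#' decay plus Gaussian noise.
#'
#' @param protocol A [protocol_spec()] with at least one barcode and an
#'   `amp5`/`amp3` primer pair.
#' @param n_reads Number of reads.
#' @param insert_len `c(min, max)` insert length (default `c(150, 400)`).
#' @param artifact_mix Named probabilities over
#'   `OK, RF, fr, SF, RE, NF, NR` (must sum to 1).
#' @param polya_len `c(min, max)` planted tail length (default `c(10, 30)`).
#' @param sub_rate,indel_rate Per-base substitution / indel probabilities.
#' @param seed RNG seed; a fixed seed yields byte-identical output.
#' @param polyt_prob Fraction of `OK` reads carrying a 5' poly-T head
#'   (default 0.15).
#' @param polya A [polya_params()] used to annotate the true tail boundary.
#' @param qual_plateau,qual_floor,qual_decay_start,qual_sd Quality-profile
#'   shape: plateau level, 3'-end floor, relative position where the decay
#'   starts, and Gaussian noise SD.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(protocol, n_reads = 1000L,
                       insert_len = c(150L, 400L),
                       artifact_mix = c(OK = 0.4, RF = 0.1, fr = 0.1,
                                        SF = 0.1, RE = 0.1, NF = 0.1,
                                        NR = 0.1),
                       polya_len = c(10L, 30L),
                       sub_rate = 0, indel_rate = 0, seed = 1L,
                       polyt_prob = 0.15,
                       polya = polya_params(),
                       qual_plateau = 38, qual_floor = 25,
                       qual_decay_start = 0.85, qual_sd = 2) {
  stopifnot(inherits(protocol, "protocol_spec"),
            length(protocol$barcodes) >= 1,
            all(c("amp5", "amp3") %in% protocol$primers$role),
            n_reads >= 1, insert_len[1] >= 1, insert_len[1] <= insert_len[2],
            sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  if (abs(sum(artifact_mix) - 1) > 1e-8)
    stop("artifact_mix probabilities must sum to 1")
  if (any(!names(artifact_mix) %in% read_error_types))
    stop("artifact_mix names must be among ",
         paste(read_error_types, collapse = ", "))
  structure(list(protocol = protocol, n_reads = as.integer(n_reads),
                 insert_len = as.integer(insert_len),
                 artifact_mix = artifact_mix,
                 polya_len = as.integer(polya_len),
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 seed = as.integer(seed), polyt_prob = polyt_prob,
                 polya = polya,
                 qual_plateau = qual_plateau, qual_floor = qual_floor,
                 qual_decay_start = qual_decay_start, qual_sd = qual_sd),
            class = "sim_config")
}

# Corrupt a sequence with per-base substitutions and indels; returns the new
# sequence plus the emitted-length cumsum so original boundaries can be
# mapped into corrupted coordinates (boundary b -> cum[b + 1]).
corrupt_seq <- function(seq, sub_rate, indel_rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (sub_rate + indel_rate == 0)
    return(list(seq = seq, cum = 0:L))
  ev <- sample(c("n", "s", "i", "d"), L, replace = TRUE,
               prob = c(1 - sub_rate - indel_rate, sub_rate,
                        indel_rate / 2, indel_rate / 2))
  pieces <- chars
  subs <- which(ev == "s")
  if (length(subs))
    pieces[subs] <- vapply(chars[subs], function(b)
      sample(setdiff(BASES, b), 1L), "")
  pieces[ev == "d"] <- ""
  ins <- which(ev == "i")
  if (length(ins))
    pieces[ins] <- paste0(sample(BASES, length(ins), replace = TRUE),
                          chars[ins])
  list(seq = paste(pieces, collapse = ""),
       cum = c(0L, cumsum(nchar(pieces))))
}

sim_quals <- function(len, cfg) {
  rel <- seq_len(len) / len
  mu <- ifelse(rel <= cfg$qual_decay_start, cfg$qual_plateau,
               cfg$qual_plateau - (cfg$qual_plateau - cfg$qual_floor) *
                 (rel - cfg$qual_decay_start) / (1 - cfg$qual_decay_start))
  q <- round(mu + stats::rnorm(len, 0, cfg$qual_sd))
  pmin(40L, pmax(2L, as.integer(q)))
}

#' Simulate protocol-contaminated reads with ground truth
#'
#' Builds `config$n_reads` synthetic reads according to the study conditions
#' in `config` (see [sim_config()]). Deterministic for a fixed seed. When
#' `out_dir` is given, writes `reads.fasta`, `reads.qual` and `truth.tsv`
#' there.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @return Invisibly when writing, otherwise visibly: a list with `reads` (a
#'   list of [scrub_read()] with simulated qualities) and `truth` (data.frame
#'   `id`, `clean_start`, `clean_end`, `sample`, `type`, `polya_len`,
#'   `tail_side`), where `clean_start`/`clean_end` are the true clean interval
#'   in the coordinates of the corrupted read.
#' @export
simulate_reads <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pro <- config$protocol
  amp5 <- pro$primers$seq[pro$primers$role == "amp5"][1]
  amp3 <- pro$primers$seq[pro$primers$role == "amp3"][1]
  ad5 <- if (length(pro$adapters5)) pro$adapters5[[1]] else ""
  ad3 <- if (length(pro$adapters3)) pro$adapters3[[1]] else ""
  guard_seqs <- protocol_table(pro)$seq
  res <- with_seed(config$seed, {
    reads <- vector("list", config$n_reads)
    truth <- vector("list", config$n_reads)
    types <- sample(names(config$artifact_mix), config$n_reads,
                    replace = TRUE, prob = config$artifact_mix)
    for (k in seq_len(config$n_reads)) {
      type <- types[k]
      id <- sprintf("read%05d", k)
      bc_name <- sample(names(pro$barcodes), 1L)
      bc <- pro$barcodes[[bc_name]]
      ilen <- sample(config$insert_len[1]:config$insert_len[2], 1L)
      repeat {
        insert <- rand_dna(ilen)
        clash <- any(vapply(guard_seqs, function(p)
          shares_word(p, insert), TRUE))
        if (!clash) break
      }
      tail_side <- "A3"
      tl <- sample(config$polya_len[1]:config$polya_len[2], 1L)
      if (type == "OK" && stats::runif(1) < config$polyt_prob) tail_side <- "T5"
      if (type %in% c("RF", "fr")) { tail_side <- "none"; tl <- 0L }
      junk <- function() rand_dna(sample(5:10, 1L))
      # parts between adapter5 and adapter3; `pre`/`post` flank the region the
      # ideal primer trim leaves over
      tail_a <- if (tail_side == "A3") strrep("A", tl) else ""
      head_t <- if (tail_side == "T5") strrep("T", tl) else ""
      mid <- switch(type,
        OK = if (tail_side == "T5")
               list(pre = amp3, core = paste0(head_t, insert), post = revcomp(amp5))
             else
               list(pre = amp5, core = paste0(insert, tail_a), post = revcomp(amp3)),
        RF = list(pre = revcomp(amp3), core = insert, post = amp5),
        fr = list(pre = amp5, core = insert, post = revcomp(amp5)),
        SF = list(pre = paste0(junk(), amp5), core = paste0(insert, tail_a),
                  post = revcomp(amp3)),
        RE = list(pre = amp5, core = paste0(insert, tail_a),
                  post = paste0(revcomp(amp3), junk())),
        NF = list(pre = paste0(amp5, amp5), core = paste0(insert, tail_a),
                  post = revcomp(amp3)),
        NR = list(pre = amp5, core = paste0(insert, tail_a),
                  post = paste0(revcomp(amp3), revcomp(amp3))))
      seq <- paste0(bc, ad5, mid$pre, mid$core, mid$post, ad3)
      core_start <- nchar(bc) + nchar(ad5) + nchar(mid$pre)
      core_end <- core_start + nchar(mid$core)
      # true clean interval: the poly-A window model applied to the noise-free
      # post-primer-trim interval (tail bases have no boundary of their own)
      civ <- c(core_start, core_end)
      e3 <- polya_boundary3(seq, civ, config$polya)
      if (!is.null(e3)) civ[2] <- e3
      if (config$polya$both_sides) {
        s5 <- polya_boundary5(seq, civ, config$polya)
        if (!is.null(s5)) civ[1] <- s5
      }
      cor <- corrupt_seq(seq, config$sub_rate, config$indel_rate)
      cs <- cor$cum[civ[1] + 1L]
      ce <- cor$cum[civ[2] + 1L]
      reads[[k]] <- scrub_read(id, cor$seq,
                               sim_quals(nchar(cor$seq), config))
      truth[[k]] <- data.frame(id = id, clean_start = cs, clean_end = ce,
                               sample = bc_name, type = type,
                               polya_len = tl, tail_side = tail_side,
                               stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, truth))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seqs <- vapply(res$reads, `[[`, "", "seq")
    ids <- vapply(res$reads, `[[`, "", "id")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(seqs, ids)),
      file.path(out_dir, "reads.fasta"))
    write_qual_file(setNames(lapply(res$reads, `[[`, "qual"), ids),
                    file.path(out_dir, "reads.qual"))
    write.table(res$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(res))
  }
  res
}
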