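#' Write genome or element sequences as FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] (or named character vector).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

# rebuild a read's stored sequence (reference-forward orientation) from the
# mutated genome and the fragment's conversion calls
.read_seq <- function(chars, rs, re, template, meth_pos) {
  v <- chars[(rs + 1L):re]
  if (template == "+") {
    conv <- which(v == "C") + rs - 1L   # 0-based positions
    conv <- setdiff(conv, meth_pos)
    v[conv - rs + 1L] <- "T"
  } else {
    conv <- which(v == "G") + rs - 1L
    conv <- setdiff(conv, meth_pos)
    v[conv - rs + 1L] <- "A"
  }
  paste(v, collapse = "")
}

#' Write simulated alignments as SAM
#'
#' Serializes one of the simulator's alignment sets (against the genome or
#' against the extracted element) as SAM 1.6 with soft-clip CIGARs.
#' Positions are converted from the package's internal 0-based half-open
#' convention to SAM's 1-based coordinates. When the mutated genome is
#' supplied, read sequences are reconstructed from the planted conversion
#' calls (stored in reference-forward orientation); otherwise `SEQ` is `*`.
#' Base qualities are a constant placeholder.
#'
#' @param reads an `emseq_reads` object from [simulate_emseq_reads()].
#' @param seqs reference sequences for the `@SQ` header lines
#'   ([Biostrings::DNAStringSet]).
#' @param path output file.
#' @param reference which alignment set to write.
#' @param mutated optional mutated genome to reconstruct read sequences.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, seqs, path, reference = c("genome", "te"),
                      mutated = NULL) {
  reference <- match.arg(reference)
  aln <- if (reference == "genome") as.data.table(reads$genome_aln)
         else {
           t <- as.data.table(reads$te_aln)
           t[, `:=`(contig = "TE", mode = "single")]
           t
         }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs),
                   vapply(seq_along(seqs), function(i) length(seqs[[i]]), 1L)))
  setorder(aln, contig, start)
  flag <- 1L +
    ifelse(aln$mode == "paired", 2L, 0L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  cigar <- paste0(
    ifelse(aln$clip_left > 0L, paste0(aln$clip_left, "S"), ""),
    aln$end - aln$start, "M",
    ifelse(aln$clip_right > 0L, paste0(aln$clip_right, "S"), ""))
  seq_field <- rep("*", nrow(aln)); qual <- rep("*", nrow(aln))
  if (!is.null(mutated)) {
    frg <- as.data.table(reads$fragments)
    setkey(frg, qname)
    calls <- as.data.table(reads$calls)
    meth_by <- calls[meth == TRUE, .(mp = list(pos)), by = .(qname, mate)]
    setkey(meth_by, qname, mate)
    chars_cache <- lapply(names(mutated), function(ctg)
      strsplit(as.character(mutated[[ctg]]), "", fixed = TRUE)[[1]])
    names(chars_cache) <- names(mutated)
    fr <- frg[aln$qname]
    for (i in seq_len(nrow(aln))) {
      f <- fr[i]
      rs <- if (aln$mate[i] == 1L) f$r1s else f$r2s
      re <- if (aln$mate[i] == 1L) f$r1e else f$r2e
      mp <- meth_by[.(aln$qname[i], aln$mate[i]), mp][[1]]
      seq_field[i] <- .read_seq(chars_cache[[f$contig]], rs, re, f$template,
                                if (is.null(mp)) integer() else mp)
      qual[i] <- strrep("I", re - rs)
    }
  }
  body <- paste(aln$qname, flag, aln$contig, aln$start + 1L, 42L, cigar,
                "*", 0L, 0L, seq_field, qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into the package's alignment-table convention
#'
#' Uses Rsamtools to parse the file and returns 0-based half-open intervals
#' with soft-clip lengths split out of the CIGAR. Records flagged as proper
#' pairs get `mode == "paired"`, others `mode == "single"`.
#'
#' @param path SAM or BAM file.
#' @return data.table: `qname`, `mate`, `contig`, `start`, `end`, `strand`,
#'   `clip_left`, `clip_right`, `mode`.
#' @export
read_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_sam requires the Rsamtools package")
  bam <- path
  if (!grepl("\\.bam$", path)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  clip_l <- as.integer(sub("^([0-9]+)S.*", "\\1",
                           ifelse(grepl("^[0-9]+S", x$cigar), x$cigar, "0S")))
  clip_r <- as.integer(sub(".*?([0-9]+)S$", "\\1",
                           ifelse(grepl("[0-9]+S$", x$cigar), x$cigar, "0S")))
  mlen <- vapply(x$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(sub("[A-Z=]", "", ops[grepl("[MD=X]$", ops)])))
  }, 1L, USE.NAMES = FALSE)
  data.table(
    qname = x$qname,
    mate = ifelse(bitwAnd(x$flag, 64L) > 0L, 1L, 2L),
    contig = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L + mlen,
    strand = ifelse(bitwAnd(x$flag, 16L) > 0L, "-", "+"),
    clip_left = clip_l, clip_right = clip_r,
    mode = ifelse(bitwAnd(x$flag, 2L) > 0L, "paired", "single"))
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open; the package keeps that convention internally,
#' so intervals round-trip unchanged. Reading goes through rtracklayer.
#'
#' @param x data.frame with columns `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path file path.
#' @return `read_bed` returns a data.frame in the same convention;
#'   `write_bed` returns `path` invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.frame(x)
  cols <- data.frame(contig = x$contig, start = x$start, end = x$end,
                     name = if ("name" %in% names(x)) x$name else ".",
                     score = if ("score" %in% names(x)) x$score else 0L,
                     strand = if ("strand" %in% names(x)) x$strand else ".")
  fwrite(cols, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_bed requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0L,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' Read / write a simulation configuration as JSON
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  # serialize named vectors as objects so names survive auto_unbox
  x$contig_lengths <- as.list(x$contig_lengths)
  x$methylation_profile <- lapply(x$methylation_profile, as.list)
  if (!is.null(x$site_flank_shift))
    x$site_flank_shift$shift <- as.list(x$site_flank_shift$shift)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$contig_lengths <- unlist(x$contig_lengths)
  x$methylation_profile <- lapply(x$methylation_profile, unlist)
  if (!is.null(x$site_flank_shift))
    x$site_flank_shift$shift <- unlist(x$site_flank_shift$shift)
  do.call(sim_config, x)
}

#' Write the simulator's truth table as TSV
#'
#' One row per planted insertion, 1-based `site` column labelled as such;
#' internal coordinates are 0-based half-open.
#'
#' @param truth a `truth_table` from [plant_insertions()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  fwrite(truth$insertions, path, sep = "\t")
  invisible(path)
}
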