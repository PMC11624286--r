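#' Build a per-cytosine methylation report from read observations
#'
#' Aggregates per-read conversion calls into a genome-wide cytosine report in
#' the seven-column CX dialect: one row per cytosine on each strand of the
#' reference sequences (including uncovered cytosines with zero counts), with
#' 1-based positions, methylated/unmethylated counts, context (CG/CHG/CHH)
#' and trinucleotide. Counts are consistent with the read pile-up; the
#' simulator has already assigned overlapping mate bases to one mate only.
#'
#' @param obs observation table with columns `contig`, `pos` (0-based),
#'   `strand`, `meth` (e.g. `obs_genome`/`obs_te` from
#'   [simulate_emseq_reads()]); may be pre-filtered to a read subset.
#' @param seqs [Biostrings::DNAStringSet] of the reference sequences the
#'   observations refer to.
#' @return data.frame with columns `contig`, `pos` (1-based), `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `trinuc`.
#' @export
emit_cytosine_report <- function(obs, seqs) {
  obs <- as.data.table(obs)
  out <- list()
  for (ctg in names(seqs)) {
    chars <- strsplit(as.character(seqs[[ctg]]), "", fixed = TRUE)[[1]]
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "C" else "G"
      pos1 <- which(chars == base)  # 1-based
      if (!length(pos1)) next
      ctx <- if (strand == "+") .context_plus(chars, pos1)
             else .context_minus(chars, pos1)
      tri <- .trinuc(chars, pos1, strand)
      cm <- integer(length(pos1)); cu <- integer(length(pos1))
      if (nrow(obs)) {
        o <- obs[obs$contig == ctg & obs$strand == strand]
        if (nrow(o)) {
          agg <- o[, .(m = sum(meth), u = sum(!meth)), by = pos]
          ix <- match(agg$pos + 1L, pos1)
          ok <- !is.na(ix)
          cm[ix[ok]] <- agg$m[ok]
          cu[ix[ok]] <- agg$u[ok]
        }
      }
      out[[paste(ctg, strand)]] <- data.table(
        contig = ctg, pos = pos1, strand = strand,
        count_meth = cm, count_unmeth = cu, context = ctx, trinuc = tri)
    }
  }
  res <- rbindlist(out)
  setorder(res, contig, pos)
  setDF(res)
  res
}

#' Read / write a seven-column cytosine report
#'
#' Tab-separated, no header: contig, 1-based position, strand, count
#' methylated, count unmethylated, context, trinucleotide. This matches the
#' `--cytosine_report --CX_context` dialect of common bisulfite pipelines,
#' so reports round-trip without loss.
#'
#' @param x report data.frame (see [emit_cytosine_report()]).
#' @param path file path.
#' @return `read_cytosine_report` returns the report data.frame;
#'   `write_cytosine_report` returns `path` invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  fwrite(as.data.table(x)[, .(contig, pos, strand, count_meth, count_unmeth,
                              context, trinuc)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("contig", "pos", "strand", "count_meth",
                            "count_unmeth", "context", "trinuc"),
              colClasses = list(character = c(1, 3, 6, 7),
                                integer = c(2, 4, 5)))
  if (!all(dt$context %in% c("CG", "CHG", "CHH")))
    stop("unknown context labels in ", path,
         ": expected CG/CHG/CHH (CX dialect)")
  setDF(dt)
  dt
}
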