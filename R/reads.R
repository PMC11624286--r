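#' Simulate converted paired-end reads with truth-derived alignments
#'
#' Draws fragments uniformly from the mutated genome (insert sizes uniform in
#' `config$insert_size_range`, 150 bp mates by default), converts cytosines
#' according to the planted methylome (a cytosine is read as C with its
#' methylation probability, and otherwise escapes conversion with probability
#' `config$conversion_failure`), and emits alignment records derived from the
#' planted truth rather than from an aligner. Fragments are strand-symmetric:
#' half the fragments present the top-strand conversion view (C/T
#' polymorphisms), half the bottom strand (G/A on the plus-strand
#' coordinate).
#'
#' Alignment emulation follows the two-pass mapping scheme of a bisulfite
#' aligner run first paired-end against the genome and then single-end
#' against the genome and the extracted element:
#' \itemize{
#'   \item pairs fully outside planted elements align paired-end to the
#'     reference genome at their true coordinates;
#'   \item pairs fully inside one planted element align paired-end to the
#'     single reference element copy (coordinates shifted to the reference
#'     locus), unless the whole fragment falls within one LTR, in which case
#'     the pair is ambiguous between the two identical LTRs and removed;
#'   \item pairs straddling an element boundary (or an internal junction of a
#'     nested insertion) are re-mapped single-end: the genome-derived portion
#'     aligns to the genome with the element-derived bases soft-clipped, and
#'     mates inside the element align to the extracted element sequence;
#'   \item on the extracted element, reads falling entirely within an LTR are
#'     multi-mapping between the two identical LTRs and are removed, unless
#'     they overlap the region whose 3' LTR copy is masked — such reads are
#'     reported at the 5' LTR coordinates (reads genuinely from the 3' LTR
#'     are thereby mis-assigned to the 5' LTR, mirroring the masking
#'     strategy); reads overlapping the masked bases at a true 3' LTR
#'     placement that extends into the internal region cannot align and are
#'     dropped.
#' }
#' Aligned portions shorter than `config$min_mapped` are treated as
#' unalignable. Overlapping mate bases are counted once (the overlap is
#' assigned to the first mate), mirroring `--no_overlap` methylation
#' extraction.
#'
#' @param mutated mutated genome ([Biostrings::DNAStringSet]) from
#'   [plant_insertions()].
#' @param truth the matching `truth_table`.
#' @param config the [sim_config()].
#' @return an object of class `emseq_reads`: a list with
#'   \describe{
#'     \item{fragments}{data.table of drawn fragments.}
#'     \item{genome_aln}{alignments against the reference genome, 0-based
#'       half-open: `qname`, `mate`, `contig`, `start`, `end`, `strand`,
#'       `clip_left`, `clip_right`, `mode` (`"paired"` first-pass concordant,
#'       `"single"` second-pass).}
#'     \item{te_aln}{alignments against the extracted element: `qname`,
#'       `mate`, `start`, `end` (element coordinates, after any 3' LTR
#'       rescue), `strand`, `clip_left`, `clip_right`, `rescued`,
#'       `true_ltr`, `ins_id`.}
#'     \item{obs_genome, obs_te}{per-read cytosine observations (0-based
#'       `pos`, `strand`, logical `meth`) on the reference genome and element
#'       coordinate systems.}
#'     \item{calls}{fragment-level conversion calls in mutated-genome
#'       coordinates (used to reconstruct read sequences).}
#'     \item{log}{named counts of fragments and reads dropped at each step.}
#'   }
#' @export
simulate_emseq_reads <- function(mutated, truth, config) {
  stopifnot(inherits(truth, "truth_table"), inherits(config, "sim_config"))
  ann <- truth$annotation
  set.seed(config$seed + 2L)
  rl <- config$read_length
  segs_all <- truth$segments

  ## fragments ----------------------------------------------------------
  frag_list <- list()
  for (ctg in names(mutated)) {
    L <- length(mutated[[ctg]])
    N <- as.integer(round(config$coverage * L / (2 * rl)))
    if (N == 0L) next
    isz <- as.integer(floor(runif(N, config$insert_size_range[1],
                                  config$insert_size_range[2] + 1L)))
    isz <- pmin(pmax(isz, rl), L)
    fstart <- as.integer(floor(runif(N, 0, L - isz + 1)))
    frag_list[[ctg]] <- data.table(
      qname = sprintf("frag_%s_%07d", ctg, seq_len(N)),
      contig = ctg, fstart = fstart, insert = isz,
      template = sample(c("+", "-"), N, replace = TRUE))
  }
  frags <- rbindlist(frag_list)
  if (nrow(frags) == 0L) stop("requested coverage yields zero fragments")
  frags[, `:=`(r1s = fstart, r1e = fstart + rl,
               r2s = fstart + insert - rl, r2e = fstart + insert)]

  ## per-read placement against the segment map -------------------------
  reads <- rbind(
    frags[, .(qname, contig, mate = 1L, rs = r1s, re = r1e, gstrand = "+")],
    frags[, .(qname, contig, mate = 2L, rs = r2s, re = r2e, gstrand = "-")])
  rd_list <- list()
  for (ctg in names(mutated)) {
    segs <- segs_all[contig == ctg]
    rd <- reads[contig == ctg]
    idx <- findInterval(rd$rs, segs$mut_start)
    segend <- segs$mut_end[idx]
    spans <- rd$re > segend
    wA <- pmin(rd$re, segend) - rd$rs
    wB <- pmax(rd$re - segend, 0L)
    useB <- spans & wB > wA
    seg_sel <- idx + as.integer(useB)
    p_start <- as.integer(ifelse(useB, segend, rd$rs))
    p_end <- as.integer(ifelse(spans & !useB, segend, rd$re))
    rd[, `:=`(
      seg_type = segs$type[seg_sel],
      seg_mut_start = segs$mut_start[seg_sel],
      seg_orig_start = segs$orig_start[seg_sel],
      seg_te_start = segs$te_start[seg_sel],
      seg_te_end = segs$te_end[seg_sel],
      seg_strand = segs$seg_strand[seg_sel],
      ins_id = segs$ins_id[seg_sel],
      p_start = p_start, p_end = p_end)]
    rd_list[[ctg]] <- rd
  }
  rd <- rbindlist(rd_list)
  rd[, `:=`(clip_left = p_start - rs, clip_right = re - p_end,
            width = p_end - p_start)]
  rd[, short := width < config$min_mapped]

  ## coordinates on each reference frame --------------------------------
  rd[, `:=`(g_start = NA_integer_, g_end = NA_integer_,
            ts = NA_integer_, tee = NA_integer_, tstrand = NA_character_)]
  rd[seg_type == "flank",
     `:=`(g_start = p_start - seg_mut_start + seg_orig_start,
          g_end = p_end - seg_mut_start + seg_orig_start)]
  rd[seg_type == "elt" & seg_strand == "+",
     `:=`(ts = seg_te_start + (p_start - seg_mut_start))]
  rd[seg_type == "elt" & seg_strand == "-",
     `:=`(ts = seg_te_end - (p_end - seg_mut_start))]
  rd[seg_type == "elt", tee := ts + width]
  rd[seg_type == "elt",
     tstrand := ifelse(seg_strand == "+", gstrand,
                       ifelse(gstrand == "+", "-", "+"))]

  ## element-side mapping status ----------------------------------------
  ltrL <- ann$ltr_length; l3s <- ann$ltr3[1]
  mrel <- ann$mask_rel; mabs <- ann$mask
  rd[, `:=`(te_status = NA_character_, true_ltr = NA_character_)]
  el <- which(rd$seg_type == "elt")
  if (length(el)) {
    ts <- rd$ts[el]; tee <- rd$tee[el]
    in5 <- tee <= ltrL
    in3 <- ts >= l3s
    offs <- ifelse(in3, ts - l3s, ts)
    offe <- offs + (tee - ts)
    ov_rel <- offs < mrel[2] & mrel[1] < offe
    ov_abs <- ts < mabs[2] & mabs[1] < tee
    status <- rep("unique", length(el))
    status[in5 & !ov_rel] <- "multimap"
    status[in3 & !ov_rel] <- "multimap"
    status[in3 & ov_rel] <- "rescued"
    status[!in5 & !in3 & ov_abs] <- "masked"
    mid <- (ts + tee) / 2
    ltr <- ifelse(mid < ltrL, "5p", ifelse(mid >= l3s, "3p", "internal"))
    set(rd, i = el, j = "te_status", value = status)
    set(rd, i = el, j = "true_ltr", value = ltr)
  }

  ## pair-level routing ---------------------------------------------------
  setkey(rd, qname, mate)
  m1 <- rd[mate == 1L]; m2 <- rd[mate == 2L]
  stopifnot(identical(m1$qname, m2$qname))
  clean <- function(m) !m$short & m$clip_left == 0L & m$clip_right == 0L
  both_flank <- m1$seg_type == "flank" & m2$seg_type == "flank" &
    clean(m1) & clean(m2)
  both_elt <- m1$seg_type == "elt" & m2$seg_type == "elt" &
    clean(m1) & clean(m2) &
    m1$seg_strand == m2$seg_strand & m1$ins_id == m2$ins_id
  span_lo <- pmin(m1$ts, m2$ts); span_hi <- pmax(m1$tee, m2$tee)
  pure_ltr <- both_elt & (span_hi <= ltrL | span_lo >= l3s)
  pass1 <- both_flank | (both_elt & !pure_ltr)
  category <- rep("pass2", nrow(m1))
  category[both_flank] <- "paired_flank"
  category[both_elt & !pure_ltr] <- "paired_ref"
  category[pure_ltr] <- "ambiguous_pair"
  pairing <- data.table(qname = m1$qname, category = category)
  rd <- pairing[rd, on = "qname"]

  rd[, role := "none"]
  rd[category == "paired_flank", role := "genome_paired"]
  rd[category == "paired_ref", role := "genome_paired_ref"]
  rd[category == "pass2" & seg_type == "flank" & !short, role := "genome_single"]
  rd[category == "pass2" & seg_type == "elt" & !short &
       te_status %in% c("unique", "rescued"), role := "te"]

  log <- list(
    n_fragments = nrow(frags),
    n_pairs_concordant = sum(pass1),
    n_pairs_ambiguous_ltr = sum(pure_ltr),
    n_reads_short = sum(rd$short),
    n_reads_multimap = sum(rd$category == "pass2" &
                             rd$te_status %in% "multimap", na.rm = TRUE),
    n_reads_masked = sum(rd$category == "pass2" &
                           rd$te_status %in% "masked", na.rm = TRUE))

  ## conversion calls per fragment (mutated-genome frame) ----------------
  cf <- config$conversion_failure
  call_list <- list()
  for (ctg in names(mutated)) {
    for (tmpl in c("+", "-")) {
      M <- if (tmpl == "+") truth$meth[[ctg]]$plus else truth$meth[[ctg]]$minus
      if (!nrow(M)) next
      fs <- frags[contig == ctg & template == tmpl]
      if (!nrow(fs)) next
      expand <- function(lo_coord, hi_coord, mate_no) {
        lo <- findInterval(lo_coord - 1L, M$pos) + 1L
        hi <- findInterval(hi_coord - 1L, M$pos)
        n <- pmax(hi - lo + 1L, 0L)
        keep <- n > 0L
        if (!any(keep)) return(NULL)
        cyt <- sequence(n[keep]) + rep(lo[keep] - 1L, n[keep])
        data.table(qname = rep(fs$qname[keep], n[keep]),
                   mate = mate_no,
                   pos = M$pos[cyt], prob = M$prob[cyt])
      }
      e1 <- expand(fs$r1s, fs$r1e, 1L)
      # overlap bases belong to mate 1 (mirrors --no_overlap)
      e2 <- expand(pmax(fs$r2s, fs$r1e), fs$r2e, 2L)
      ee <- rbindlist(list(e1, e2))
      if (nrow(ee) == 0L) next
      ee[, `:=`(contig = ctg, cstrand = tmpl,
                meth = runif(.N) < prob + (1 - prob) * cf)]
      ee[, prob := NULL]
      call_list[[paste(ctg, tmpl)]] <- ee
    }
  }
  calls <- rbindlist(call_list)
  if (nrow(calls) == 0L)
    calls <- data.table(qname = character(), mate = integer(),
                        pos = integer(), contig = character(),
                        cstrand = character(), meth = logical())

  ## per-read observations translated to each reference frame ------------
  keep_cols <- c("qname", "mate", "role", "p_start", "p_end", "seg_mut_start",
                 "seg_orig_start", "seg_te_start", "seg_te_end", "seg_strand",
                 "te_status", "ts", "tee", "contig", "gstrand", "tstrand",
                 "clip_left", "clip_right", "g_start", "g_end", "true_ltr",
                 "ins_id")
  rdk <- rd[, ..keep_cols]
  obs <- merge(calls, rdk, by = c("qname", "mate"), all = FALSE,
               suffixes = c("", ".rd"))
  obs <- obs[pos >= p_start & pos < p_end]

  flip <- function(s) ifelse(s == "+", "-", "+")
  genome_roles <- c("genome_paired", "genome_single")
  og1 <- obs[role %in% genome_roles,
             .(qname, mate, contig,
               pos = pos - seg_mut_start + seg_orig_start,
               strand = cstrand, meth)]
  og2 <- obs[role == "genome_paired_ref"]
  if (nrow(og2)) {
    tp <- ifelse(og2$seg_strand == "+",
                 og2$seg_te_start + (og2$pos - og2$seg_mut_start),
                 og2$seg_te_end - 1L - (og2$pos - og2$seg_mut_start))
    og2 <- og2[, .(qname, mate, contig = ann$ref_contig,
                   pos = ann$ref_start + tp,
                   strand = ifelse(seg_strand == "+", cstrand, flip(cstrand)),
                   meth)]
  } else og2 <- NULL
  obs_genome <- rbind(og1, og2)

  ot <- obs[role == "te"]
  if (nrow(ot)) {
    tp <- ifelse(ot$seg_strand == "+",
                 ot$seg_te_start + (ot$pos - ot$seg_mut_start),
                 ot$seg_te_end - 1L - (ot$pos - ot$seg_mut_start))
    tp <- tp - ifelse(ot$te_status == "rescued", l3s, 0L)
    obs_te <- ot[, .(qname, mate, contig = "TE", pos = tp,
                     strand = ifelse(seg_strand == "+", cstrand, flip(cstrand)),
                     meth)]
  } else {
    obs_te <- data.table(qname = character(), mate = integer(),
                         contig = character(), pos = integer(),
                         strand = character(), meth = logical())
  }

  ## alignment tables -----------------------------------------------------
  ga1 <- rd[role == "genome_paired",
            .(qname, mate, contig, start = g_start, end = g_end,
              strand = gstrand, clip_left = 0L, clip_right = 0L,
              mode = "paired")]
  ga2 <- rd[role == "genome_paired_ref",
            .(qname, mate, contig = ann$ref_contig,
              start = ann$ref_start + ts, end = ann$ref_start + tee,
              strand = tstrand, clip_left = 0L, clip_right = 0L,
              mode = "paired")]
  ga3 <- rd[role == "genome_single",
            .(qname, mate, contig, start = g_start, end = g_end,
              strand = gstrand, clip_left, clip_right, mode = "single")]
  genome_aln <- rbind(ga1, ga2, ga3)
  setorder(genome_aln, contig, start, qname)

  te_aln <- rd[role == "te",
               .(qname, mate,
                 start = ts - ifelse(te_status == "rescued", l3s, 0L),
                 end = tee - ifelse(te_status == "rescued", l3s, 0L),
                 strand = tstrand, clip_left, clip_right,
                 rescued = te_status == "rescued", true_ltr, ins_id)]
  setorder(te_aln, start, qname)

  structure(list(fragments = frags, reads = rd, genome_aln = genome_aln,
                 te_aln = te_aln, obs_genome = obs_genome, obs_te = obs_te,
                 calls = calls, log = log),
            class = "emseq_reads")
}

#' @export
print.emseq_reads <- function(x, ...) {
  cat("<emseq_reads>\n")
  cat(sprintf("  %d fragments; %d genome alignments (%d paired), %d element alignments\n",
              x$log$n_fragments, nrow(x$genome_aln),
              sum(x$genome_aln$mode == "paired"), nrow(x$te_aln)))
  invisible(x)
}

#' Run the full simulator for one sample
#'
#' Convenience wrapper chaining [simulate_genome()], [plant_insertions()] and
#' [simulate_emseq_reads()], and emitting the cytosine reports for both
#' reference frames.
#'
#' @param config a [sim_config()].
#' @param genome optional pre-built output of [simulate_genome()] so that
#'   several samples (e.g. a cohort) share one reference genome.
#' @return a list: `config`, `reference` (the [simulate_genome()] output),
#'   `mutated`, `truth`, `reads` (see [simulate_emseq_reads()]),
#'   `report_genome` and `report_te` (cytosine reports).
#' @export
simulate_sample <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  planted <- plant_insertions(genome$genome, genome$annotation, config)
  reads <- simulate_emseq_reads(planted$genome, planted$truth, config)
  report_genome <- emit_cytosine_report(reads$obs_genome, genome$genome)
  report_te <- emit_cytosine_report(reads$obs_te,
                                    Biostrings::DNAStringSet(
                                      setNames(as.character(genome$te), "TE")))
  list(config = config, reference = genome, mutated = planted$genome,
       truth = planted$truth, reads = reads,
       report_genome = report_genome, report_te = report_te)
}

#' Simulate a cohort of samples sharing one reference genome
#'
#' Each sample gets its own insertion draw and library, with a seed derived
#' from `config$seed` and the sample index, on a common reference genome.
#'
#' @param config base [sim_config()].
#' @param samples data.frame with columns `sample_id`, `genotype`, `status`
#'   and optionally `n_insertions` (overriding the config per sample).
#' @return list with `reference` and a named list `samples` of
#'   [simulate_sample()] outputs.
#' @export
simulate_cohort <- function(config, samples) {
  stopifnot(all(c("sample_id", "genotype", "status") %in% names(samples)))
  genome <- simulate_genome(config)
  out <- list()
  for (i in seq_len(nrow(samples))) {
    cfg <- config
    cfg$seed <- config$seed + 1000L * i
    if ("n_insertions" %in% names(samples))
      cfg$n_insertions <- as.integer(samples$n_insertions[i])
    out[[samples$sample_id[i]]] <- simulate_sample(cfg, genome = genome)
  }
  list(reference = genome, samples = out, info = samples)
}
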