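#' Plant new element insertions into a simulated genome
#'
#' Inserts `config$n_insertions` copies of the element at random positions on
#' the nuclear contigs, each with a target-site duplication (TSD) drawn from
#' `config$tsd_range` and a strand drawn from `config$strand_prob_plus`.
#' An insertion at 0-based site `s` with TSD length `t` duplicates the `t`
#' reference bases `[s, s+t)` so that one copy flanks each side of the
#' element. If `config$nested` is set, one extra copy is planted antisense
#' inside the first insertion at the spacings given by
#' `config$nested_spacing`.
#'
#' Planted sites avoid the reference copy, its normalization windows, the
#' chloroplast control contig and each other (minimum separation 4.2 kb);
#' placement is retried a bounded number of times and fails with an error if
#' the contigs cannot accommodate the request.
#'
#' Alongside the mutated genome the function returns the complete ground
#' truth: the insertion table, a segment map relating mutated coordinates to
#' reference-genome or element coordinates (used to derive alignments without
#' an aligner), and the per-cytosine methylation probabilities of the mutated
#' genome assigned from `config$methylation_profile` by region class.
#'
#' @param genome reference genome as returned by [simulate_genome()]
#'   (a [Biostrings::DNAStringSet]).
#' @param annotation the matching [te_annotation()].
#' @param config the [sim_config()].
#' @return a list with `genome` (mutated [Biostrings::DNAStringSet]) and
#'   `truth`, an object of class `truth_table`: a list with
#'   \describe{
#'     \item{insertions}{data.table: `ins_id`, `contig`, `site` (0-based
#'       insertion point on the reference genome; `NA` for the nested child),
#'       `tsd`, `strand`, `parent`, `gap5`, `gap3` (nested child only:
#'       distances between parent and child LTRs, bp), `block_start`,
#'       `block_end` (mutated coordinates of the inserted block), `f5`, `f3`
#'       (per-LTR methylation scaling factors).}
#'     \item{segments}{data.table mapping mutated coordinates to reference
#'       (`type == "flank"`, via `orig_start`) or element coordinates
#'       (`type == "elt"`, via `te_start`/`te_end`/`seg_strand`).}
#'     \item{meth}{per-contig list of `plus`/`minus` data.tables with 0-based
#'       cytosine positions, context and methylation probability.}
#'   }
#' @export
plant_insertions <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "te_annotation"))
  set.seed(config$seed + 1L)
  te_len <- annotation$te_length
  te_str <- substr(as.character(genome[[annotation$ref_contig]]),
                   annotation$ref_start + 1L, annotation$ref_start + te_len)

  ins <- .draw_insertions(genome, annotation, config)
  built <- .build_mutated(genome, annotation, config, ins, te_str)
  meth <- .build_methylome(built$genome, built$segments, built$insertions,
                           annotation, config)

  truth <- structure(list(
    insertions = built$insertions,
    segments = built$segments,
    meth = meth,
    te_seq = te_str,
    annotation = annotation
  ), class = "truth_table")
  list(genome = built$genome, truth = truth)
}

# draw non-overlapping insertion sites outside exclusion zones
.draw_insertions <- function(genome, annotation, config) {
  n <- config$n_insertions
  if (n == 0L) {
    return(data.table(ins_id = integer(), contig = character(),
                      site = integer(), tsd = integer(), strand = character(),
                      parent = integer()))
  }
  margin <- 1500L
  min_dist <- 4200L
  nuclear <- setdiff(names(genome), config$chloroplast_name)
  lens <- setNames(vapply(nuclear, function(x) length(genome[[x]]), 1L), nuclear)
  excl_lo <- annotation$flank_upstream[1] - 800L
  excl_hi <- annotation$flank_downstream[2] + 800L

  sites <- data.table(contig = character(n), site = integer(n))
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n) {
    if ((tries <- tries + 1L) > max_tries)
      stop("could not place ", n, " insertions: contigs too crowded")
    ctg <- sample(nuclear, 1L, prob = lens)
    s <- as.integer(floor(runif(1, margin, lens[[ctg]] - margin)))
    if (ctg == annotation$ref_contig && s >= excl_lo && s < excl_hi) next
    if (placed > 0L) {
      prev <- sites[seq_len(placed)]
      if (any(prev$contig == ctg & abs(prev$site - s) < min_dist)) next
    }
    placed <- placed + 1L
    sites[placed, `:=`(contig = ctg, site = s)]
  }
  ins <- data.table(
    ins_id = seq_len(n),
    contig = sites$contig,
    site = sites$site,
    tsd = as.integer(floor(runif(n, config$tsd_range[1], config$tsd_range[2] + 1L))),
    strand = ifelse(runif(n) < config$strand_prob_plus, "+", "-"),
    parent = NA_integer_)
  if (config$nested) {
    sp <- config$nested_spacing
    internal_len <- annotation$internal[2] - annotation$internal[1]
    if (sum(sp) != internal_len)
      stop("nested_spacing must sum to the element internal length (",
           internal_len, " bp)")
    child <- data.table(
      ins_id = n + 1L, contig = ins$contig[1], site = NA_integer_,
      tsd = as.integer(floor(runif(1, config$tsd_range[1], config$tsd_range[2] + 1L))),
      strand = if (ins$strand[1] == "+") "-" else "+",
      parent = 1L)
    ins <- rbind(ins, child)
  }
  setorder(ins, contig, site, na.last = TRUE)
  ins
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# assemble the mutated genome and the mutated->reference/element segment map
.build_mutated <- function(genome, annotation, config, ins, te_str) {
  te_len <- annotation$te_length
  sp <- config$nested_spacing
  segs <- list()
  seqs <- list()
  ins[, `:=`(block_start = NA_integer_, block_end = NA_integer_,
             gap5 = NA_integer_, gap3 = NA_integer_)]

  for (ctg in names(genome)) {
    orig <- as.character(genome[[ctg]])
    L <- nchar(orig)
    top <- ins[contig == ctg & is.na(parent)]
    cur_orig <- 0L; cur_mut <- 0L
    pieces_seq <- character(0)
    add_seg <- function(row) segs[[length(segs) + 1L]] <<- row

    if (nrow(top)) {
      for (k in seq_len(nrow(top))) {
        i <- top$ins_id[k]; s <- top$site[k]; t <- top$tsd[k]; st <- top$strand[k]
        # left flank incl. first TSD copy: orig [cur_orig, s+t)
        flank_len <- s + t - cur_orig
        add_seg(data.table(contig = ctg, mut_start = cur_mut,
                           mut_end = cur_mut + flank_len, type = "flank",
                           orig_start = cur_orig, ins_id = NA_integer_,
                           te_start = NA_integer_, te_end = NA_integer_,
                           seg_strand = NA_character_))
        pieces_seq <- c(pieces_seq, substr(orig, cur_orig + 1L, s + t))
        cur_mut <- cur_mut + flank_len

        # element block (possibly containing the nested child)
        child <- ins[parent == i & !is.na(parent)]
        if (nrow(child)) {
          o <- annotation$ltr5[2] + sp[1]       # child offset in parent coords
          ct <- child$tsd[1]
          pieces <- list(
            list(seq = substr(te_str, 1L, o + ct), ts = 0L, te = o + ct,
                 rel = "+", id = i),
            list(seq = .revcomp(te_str), ts = 0L, te = te_len, rel = "-",
                 id = child$ins_id[1]),
            list(seq = substr(te_str, o + 1L, te_len), ts = o, te = te_len,
                 rel = "+", id = i))
          ins[ins_id == child$ins_id[1],
              `:=`(gap5 = sp[1], gap3 = sp[2])]
        } else {
          pieces <- list(list(seq = te_str, ts = 0L, te = te_len, rel = "+",
                              id = i))
        }
        if (st == "-") {
          pieces <- rev(pieces)
          pieces <- lapply(pieces, function(p) {
            p$seq <- .revcomp(p$seq)
            p$rel <- if (p$rel == "+") "-" else "+"
            p
          })
        }
        blk_start <- cur_mut
        for (p in pieces) {
          plen <- nchar(p$seq)
          add_seg(data.table(contig = ctg, mut_start = cur_mut,
                             mut_end = cur_mut + plen, type = "elt",
                             orig_start = NA_integer_, ins_id = p$id,
                             te_start = p$ts, te_end = p$te,
                             seg_strand = p$rel))
          pieces_seq <- c(pieces_seq, p$seq)
          cur_mut <- cur_mut + plen
        }
        ins[ins_id == i, `:=`(block_start = blk_start, block_end = cur_mut)]
        child_rows <- ins[parent == i & !is.na(parent), ins_id]
        if (length(child_rows)) {
          # child block = middle piece
          mid <- segs[[length(segs) - 1L]]
          ins[ins_id == child_rows,
              `:=`(block_start = mid$mut_start, block_end = mid$mut_end)]
        }
        cur_orig <- s  # downstream flank restarts at the TSD copy
      }
    }
    add_seg(data.table(contig = ctg, mut_start = cur_mut,
                       mut_end = cur_mut + (L - cur_orig), type = "flank",
                       orig_start = cur_orig, ins_id = NA_integer_,
                       te_start = NA_integer_, te_end = NA_integer_,
                       seg_strand = NA_character_))
    pieces_seq <- c(pieces_seq, substr(orig, cur_orig + 1L, L))
    seqs[[ctg]] <- paste(pieces_seq, collapse = "")
  }
  mutated <- Biostrings::DNAStringSet(unlist(seqs))
  segments <- rbindlist(segs)
  segments <- segments[mut_end > mut_start]
  setorder(segments, contig, mut_start)

  # per-LTR methylation scaling factors
  nin <- nrow(ins)
  f <- switch(config$ltr_meth_mode,
    uniform = cbind(rep(1, nin), rep(1, nin)),
    shared = { x <- runif(nin, 0.2, 1); cbind(x, x) },
    independent = cbind(runif(nin, 0.2, 1), runif(nin, 0.2, 1)))
  ins[, `:=`(f5 = f[, 1], f3 = f[, 2])]

  list(genome = mutated, segments = segments, insertions = ins)
}

# assign a methylation probability to every cytosine of the mutated genome
.build_methylome <- function(mutated, segments, ins, annotation, config) {
  prof <- config$methylation_profile
  shift <- config$site_flank_shift
  out <- list()
  for (ctg in names(mutated)) {
    chars <- strsplit(as.character(mutated[[ctg]]), "", fixed = TRUE)[[1]]
    segs <- segments[contig == ctg]
    res <- list()
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "C" else "G"
      pos <- which(chars == base) - 1L  # 0-based
      if (!length(pos)) {
        res[[strand]] <- data.table(pos = integer(), context = character(),
                                    prob = numeric())
        next
      }
      ctx <- if (strand == "+") .context_plus(chars, pos + 1L)
             else .context_minus(chars, pos + 1L)
      if (ctg == config$chloroplast_name) {
        prob <- rep(0, length(pos))
      } else {
        # locate each cytosine's segment
        si <- findInterval(pos, segs$mut_start)
        type <- segs$type[si]
        prob <- numeric(length(pos))
        fl <- type == "flank"
        if (any(fl)) {
          orig <- pos[fl] - segs$mut_start[si[fl]] + segs$orig_start[si[fl]]
          cls <- rep("background", sum(fl))
          peri <- annotation$pericentromere
          if (!is.null(peri)) {
            pr <- peri[peri$contig == ctg, , drop = FALSE]
            if (nrow(pr)) {
              inperi <- rep(FALSE, sum(fl))
              for (r in seq_len(nrow(pr)))
                inperi <- inperi | (orig >= pr$start[r] & orig < pr$end[r])
              cls[inperi] <- "pericentromere"
            }
          }
          if (ctg == annotation$ref_contig) {
            inref <- orig >= annotation$ref_start &
                     orig < annotation$ref_start + annotation$te_length
            cls[inref] <- "te"
          }
          pmat <- do.call(rbind, prof[cls])
          prob[fl] <- pmat[cbind(seq_len(sum(fl)),
                                 match(ctx[fl], c("CG", "CHG", "CHH")))] / 100
        }
        el <- type == "elt"
        if (any(el)) {
          iid <- segs$ins_id[si[el]]
          segst <- segs$seg_strand[si[el]]
          off <- pos[el] - segs$mut_start[si[el]]
          tepos <- ifelse(segst == "+", segs$te_start[si[el]] + off,
                          segs$te_end[si[el]] - 1L - off)
          fac <- rep(1, sum(el))
          in5 <- tepos < annotation$ltr5[2]
          in3 <- tepos >= annotation$ltr3[1]
          f5 <- ins$f5[match(iid, ins$ins_id)]
          f3 <- ins$f3[match(iid, ins$ins_id)]
          fac[in5] <- f5[in5]
          fac[in3] <- f3[in3]
          base_p <- prof$te[match(ctx[el], c("CG", "CHG", "CHH"))] / 100
          prob[el] <- pmin(1, base_p * fac)
        }
        # optional methylation gain in the flanks of every planted site
        if (!is.null(shift)) {
          blk <- ins[contig == ctg & !is.na(block_start)]
          if (nrow(blk)) {
            near <- rep(FALSE, length(pos))
            for (r in seq_len(nrow(blk))) {
              near <- near |
                (pos >= blk$block_start[r] - shift$radius & pos < blk$block_start[r]) |
                (pos >= blk$block_end[r] & pos < blk$block_end[r] + shift$radius)
            }
            near <- near & type == "flank"
            if (any(near)) {
              d <- shift$shift[match(ctx[near], c("CG", "CHG", "CHH"))] / 100
              prob[near] <- pmin(1, pmax(0, prob[near] + d))
            }
          }
        }
      }
      res[[strand]] <- data.table(pos = pos, context = ctx, prob = prob)
    }
    out[[ctg]] <- list(plus = res[["+"]], minus = res[["-"]])
  }
  out
}
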