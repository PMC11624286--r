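#' Pair discordant read mates between the genome and the element
#'
#' A fragment is discordant evidence for a non-reference insertion when one
#' mate aligns (second-pass, single-end) to the genome and the other to the
#' extracted element sequence. Reads that align to both references are
#' discarded together with their mates; read names with other than exactly
#' one genome-side and one element-side mate are skipped and counted.
#'
#' @param genome_aln genome alignment table (0-based `start`/`end`; records
#'   with `mode == "single"` are used when a `mode` column is present).
#' @param te_aln element alignment table.
#' @return data.table of discordant pairs: `qname`, `contig`, `g_start`,
#'   `g_end`, `g_strand`, `g_mate`, `clip_left`, `clip_right`, `te_start`,
#'   `te_end`, `te_strand`, with a `log` attribute carrying discard counts.
#' @export
find_discordant <- function(genome_aln, te_aln) {
  g <- as.data.table(genome_aln)
  if ("mode" %in% names(g)) g <- g[mode == "single"]
  t <- as.data.table(te_aln)
  both <- merge(g[, .(qname, mate)], t[, .(qname, mate)],
                by = c("qname", "mate"))
  n_both_refs <- length(unique(both$qname))
  if (n_both_refs) {
    g <- g[!qname %in% both$qname]
    t <- t[!qname %in% both$qname]
  }
  ng <- g[, .N, by = qname]
  nt <- t[, .N, by = qname]
  ok <- merge(ng[N == 1L, .(qname)], nt[N == 1L, .(qname)], by = "qname")
  pairs <- merge(
    g[qname %in% ok$qname,
      .(qname, contig, g_start = start, g_end = end, g_strand = strand,
        g_mate = mate, clip_left, clip_right)],
    t[qname %in% ok$qname,
      .(qname, te_start = start, te_end = end, te_strand = strand,
        te_mate = mate)],
    by = "qname")
  pairs <- pairs[g_mate != te_mate]
  pairs[, te_mate := NULL]
  setorder(pairs, contig, g_start)
  n_candidates <- length(union(ng$qname, nt$qname))
  setattr(pairs, "log", list(
    n_discarded_both_refs = n_both_refs,
    n_skipped_unpaired = n_candidates - nrow(pairs) ))
  pairs[]
}

#' Cluster discordant pairs by genomic proximity
#'
#' Genome-side mates on the same contig whose successive start coordinates
#' are at most `max_gap` apart are grouped into one cluster. The default gap
#' equals the maximum library insert size, the span over which mates of one
#' insertion can scatter.
#'
#' @param pairs output of [find_discordant()].
#' @param max_gap maximum start-to-start distance within a cluster (bp).
#' @return the pairs table with an integer `cluster` column, sorted by
#'   contig and start.
#' @export
cluster_reads <- function(pairs, max_gap = 700L) {
  dt <- as.data.table(pairs)
  setorder(dt, contig, g_start)
  if (nrow(dt) == 0L) {
    dt[, cluster := integer()]
    return(dt[])
  }
  newc <- c(TRUE, dt$contig[-1] != dt$contig[-nrow(dt)] |
              diff(dt$g_start) > max_gap)
  dt[, cluster := cumsum(newc)]
  dt[]
}

#' Validate a cluster's read directionality
#'
#' A cluster is valid evidence for one insertion when, sorted by start
#' coordinate, it consists of a prefix of `m >= min_m` reads pointing toward
#' the contig 3' end (plus strand) followed by a suffix of `n >= min_n`
#' reads pointing toward the 5' end (minus strand) — all reads face the
#' insertion site between them. Any other direction pattern (interleaved
#' directions, reversed order, too few reads on a side) is invalid.
#'
#' @param cluster one cluster's rows from [cluster_reads()].
#' @param min_m,min_n minimum reads on the upstream / downstream side.
#' @return list with `valid`, `m`, `n`, and `n_switches` (number of
#'   direction changes along the sorted cluster).
#' @export
validate_cluster <- function(cluster, min_m = 3L, min_n = 3L) {
  dt <- as.data.table(cluster)
  setorder(dt, g_start)
  dir <- dt$g_strand == "+"
  r <- rle(dir)
  ok <- length(r$values) == 2L && r$values[1] &&
    r$lengths[1] >= min_m && r$lengths[2] >= min_n
  list(valid = ok,
       m = if (length(r$values) >= 1 && r$values[1]) r$lengths[1] else 0L,
       n = if (length(r$values) >= 1 && !r$values[length(r$values)])
         r$lengths[length(r$lengths)] else 0L,
       n_switches = length(r$values) - 1L)
}

# split a multi-switch cluster into stretches with at most one 3'->5' switch
# (two nearby insertions produce the pattern + + + - - - + + + - - -)
.split_cluster <- function(cluster) {
  dt <- as.data.table(cluster)
  setorder(dt, g_start)
  dir <- dt$g_strand == "+"
  grp <- cumsum(dir & !c(TRUE, dir[-length(dir)]))  # new group at -(...)+ edge
  split(dt, grp)
}

#' Infer the insertion site interval of a valid cluster
#'
#' The insertion site lies between the end coordinate of the m-th read (last
#' upstream read) and the start coordinate of the (m+1)-st read (first
#' downstream read). When the two boundary reads overlap, the interval has
#' negative width and the overlap is a target-site-duplication candidate.
#'
#' @param cluster a valid cluster (see [validate_cluster()]).
#' @return list with `end_mth`, `start_m1` (0-based), `site_lo`, `site_hi`
#'   (the sorted interval) and `overlap` (bp, 0 when the reads do not
#'   overlap).
#' @export
infer_site <- function(cluster) {
  dt <- as.data.table(cluster)
  setorder(dt, g_start)
  v <- validate_cluster(dt)
  if (!v$valid) stop("infer_site requires a valid cluster")
  end_mth <- dt$g_end[v$m]
  start_m1 <- dt$g_start[v$m + 1L]
  list(end_mth = end_mth, start_m1 = start_m1,
       site_lo = min(end_mth, start_m1), site_hi = max(end_mth, start_m1),
       overlap = max(0L, end_mth - start_m1))
}

#' Detect a target-site duplication from boundary soft-clips
#'
#' A TSD is present when the m-th read is soft-clipped on its
#' insertion-proximal (reference-right) end, the (m+1)-st read is
#' soft-clipped on its insertion-proximal (reference-left) end, and the two
#' reads' reference spans overlap; the TSD size is the overlap length. The
#' clip sides are evaluated in reference orientation, i.e. the
#' insertion-facing end of each boundary read.
#'
#' @param cluster a valid cluster.
#' @return TSD length in bp, or `NA_integer_` when the soft-clip pattern is
#'   absent.
#' @export
detect_tsd <- function(cluster) {
  dt <- as.data.table(cluster)
  setorder(dt, g_start)
  v <- validate_cluster(dt)
  if (!v$valid) stop("detect_tsd requires a valid cluster")
  s <- infer_site(dt)
  clip_ok <- dt$clip_right[v$m] > 0L && dt$clip_left[v$m + 1L] > 0L
  if (clip_ok && s$overlap > 0L) as.integer(s$overlap) else NA_integer_
}

#' Infer insertion strand and each read's LTR of origin
#'
#' The orientation of the element-side mates relative to their genome-side
#' mates determines the insertion strand: for a sense insertion the upstream
#' border pairs carry element mates on the element minus strand (they come
#' from the 5' LTR) and the downstream border pairs carry plus-strand
#' element mates from the 3' LTR; both relations reverse for an antisense
#' insertion. Conflicting orientations within the cluster flag the strand as
#' ambiguous and leave the LTR labels `NA`.
#'
#' @param cluster a valid cluster with element-side columns.
#' @return list with `strand` (`"+"`, `"-"` or `"ambiguous"`) and `labels`,
#'   a data.table of `qname`, `border` (`"up"`/`"down"`) and `ltr`
#'   (`"5p"`/`"3p"`/`NA`).
#' @export
infer_strand_and_ltr <- function(cluster) {
  dt <- as.data.table(cluster)
  setorder(dt, g_start)
  up <- dt$g_strand == "+"
  vote <- ifelse(up == (dt$te_strand == "-"), "+", "-")
  strand <- if (length(unique(vote)) == 1L) vote[1] else "ambiguous"
  ltr <- if (strand == "+") ifelse(up, "5p", "3p")
         else if (strand == "-") ifelse(up, "3p", "5p")
         else rep(NA_character_, nrow(dt))
  list(strand = strand,
       labels = data.table(qname = dt$qname,
                           border = ifelse(up, "up", "down"), ltr = ltr))
}

#' Classify call locations as chromosome arm or pericentromeric
#'
#' A call is pericentromeric when its site midpoint falls inside a
#' pericentromere interval; calls on contigs absent from the annotation
#' default to `"arm"`.
#'
#' @param calls call table with columns `contig` and `site` (0-based
#'   midpoint).
#' @param pericentromere data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @return character vector `"arm"`/`"pericentromeric"` along the calls.
#' @export
classify_location <- function(calls, pericentromere) {
  calls <- as.data.frame(calls)
  out <- rep("arm", nrow(calls))
  if (is.null(pericentromere) || nrow(calls) == 0L) return(out)
  peri <- as.data.frame(pericentromere)
  for (r in seq_len(nrow(peri))) {
    hit <- calls$contig == peri$contig[r] &
      calls$site >= peri$start[r] & calls$site < peri$end[r]
    out[hit] <- "pericentromeric"
  }
  out
}

#' Filter calls by per-border support
#'
#' Retains calls supported by at least `min_support_per_border` discordant
#' mates on each border.
#'
#' @param calls call table with columns `m` and `n`.
#' @param min_support_per_border threshold (default 3).
#' @return the retained rows.
#' @export
filter_calls <- function(calls, min_support_per_border = 3L) {
  dt <- as.data.table(calls)
  dt[m >= min_support_per_border & n >= min_support_per_border][]
}

#' Call new element insertions from discordant read mates
#'
#' Full calling pipeline: pair discordant mates, cluster them by proximity,
#' validate cluster directionality (optionally splitting clusters that
#' contain two direction switches, the signature of two nearby insertions),
#' infer the site interval, TSD, strand and per-read LTR of origin, classify
#' the location, and filter on per-border support. When two retained calls
#' claim overlapping site intervals the one with higher total support is
#' kept and the loser is logged.
#'
#' @param genome_aln,te_aln alignment tables (see [find_discordant()]).
#' @param pericentromere optional pericentromere intervals (see
#'   [classify_location()]).
#' @param max_gap cluster gap (bp).
#' @param min_support_per_border per-border support threshold.
#' @param split_ambiguous split multi-switch clusters before validation
#'   instead of discarding them wholesale.
#' @return list with `calls` (data.table: `call_id`, `contig`, `site_lo`,
#'   `site_hi`, `site` (midpoint), `strand`, `tsd`, `m`, `n`, `location`),
#'   `read_ltr` (per-read LTR-of-origin labels keyed by `call_id`), and
#'   `log` (discard tallies).
#' @export
call_insertions <- function(genome_aln, te_aln, pericentromere = NULL,
                            max_gap = 700L, min_support_per_border = 3L,
                            split_ambiguous = TRUE) {
  pairs <- find_discordant(genome_aln, te_aln)
  plog <- attr(pairs, "log")
  clustered <- cluster_reads(pairs, max_gap = max_gap)
  calls <- list(); labels <- list()
  n_invalid <- 0L
  cid <- 0L
  for (cl in split(clustered, by = "cluster")) {
    parts <- {
      v0 <- validate_cluster(cl)
      if (!v0$valid && v0$n_switches > 1L && split_ambiguous)
        .split_cluster(cl) else list(cl)
    }
    for (part in parts) {
      v <- validate_cluster(part)
      if (!v$valid) { n_invalid <- n_invalid + 1L; next }
      s <- infer_site(part)
      sl <- infer_strand_and_ltr(part)
      cid <- cid + 1L
      calls[[cid]] <- data.table(
        call_id = cid, contig = part$contig[1],
        site_lo = s$site_lo, site_hi = s$site_hi,
        site = as.integer(floor((s$site_lo + s$site_hi) / 2)),
        strand = sl$strand, tsd = detect_tsd(part), m = v$m, n = v$n)
      labels[[cid]] <- cbind(call_id = cid, sl$labels)
    }
  }
  calls <- if (length(calls)) rbindlist(calls) else
    data.table(call_id = integer(), contig = character(),
               site_lo = integer(), site_hi = integer(), site = integer(),
               strand = character(), tsd = integer(), m = integer(),
               n = integer())
  read_ltr <- if (length(labels)) rbindlist(labels) else
    data.table(call_id = integer(), qname = character(),
               border = character(), ltr = character())
  calls <- filter_calls(calls, min_support_per_border)
  # resolve competing calls on overlapping site intervals
  n_ties <- 0L
  if (nrow(calls) > 1L) {
    setorder(calls, contig, site_lo)
    keep <- rep(TRUE, nrow(calls))
    for (i in 2:nrow(calls)) {
      j <- i - 1L
      while (j >= 1L && !keep[j]) j <- j - 1L
      if (j >= 1L && calls$contig[i] == calls$contig[j] &&
          calls$site_lo[i] <= calls$site_hi[j]) {
        n_ties <- n_ties + 1L
        if (calls$m[i] + calls$n[i] > calls$m[j] + calls$n[j])
          keep[j] <- FALSE else keep[i] <- FALSE
      }
    }
    calls <- calls[keep]
  }
  calls[, location := classify_location(calls, pericentromere)]
  read_ltr <- read_ltr[call_id %in% calls$call_id]
  list(calls = calls[], read_ltr = read_ltr[],
       log = c(plog, list(n_invalid_clusters = n_invalid,
                          n_tied_calls_dropped = n_ties)))
}

#' Screen for antisense nested insertions of the element into itself
#'
#' Collects read pairs whose two mates both align to the extracted element in
#' the same orientation (the anomaly produced by an antisense junction) with
#' at least one mate overlapping an LTR, and tallies the supporting mates at
#' each LTR. The per-sample status is `"Y"` when each LTR has at least
#' `min_mates_per_ltr` supporting mates, `"y"` when at least one supporting
#' mate exists anywhere, and `"N"` otherwise.
#'
#' @param te_aln element alignment table.
#' @param annotation a [te_annotation()].
#' @param min_mates_per_ltr confident-call threshold (default 2).
#' @return list with `status` (`"N"`/`"y"`/`"Y"`), `n5`, `n3` (supporting
#'   mates overlapping the 5'/3' LTR) and `pairs` (the anomalous pairs).
#' @export
find_nested <- function(te_aln, annotation, min_mates_per_ltr = 2L) {
  t <- as.data.table(te_aln)
  empty <- list(status = "N", n5 = 0L, n3 = 0L,
                pairs = t[0])
  if (nrow(t) == 0L) return(empty)
  nn <- t[, .N, by = qname]
  t2 <- t[qname %in% nn[N == 2L, qname]]
  if (nrow(t2) == 0L) return(empty)
  setorder(t2, qname, mate)
  m1 <- t2[seq(1, .N, by = 2)]
  m2 <- t2[seq(2, .N, by = 2)]
  anom <- m1$strand == m2$strand
  if (!any(anom)) return(empty)
  pairs <- t2[qname %in% m1$qname[anom]]
  ov <- function(s, e, iv) s < iv[2] & iv[1] < e
  on5 <- ov(pairs$start, pairs$end, annotation$ltr5)
  on3 <- ov(pairs$start, pairs$end, annotation$ltr3)
  n5 <- sum(on5); n3 <- sum(on3)
  status <- if (n5 >= min_mates_per_ltr && n3 >= min_mates_per_ltr) "Y"
            else if (n5 + n3 >= 1L) "y" else "N"
  list(status = status, n5 = n5, n3 = n3, pairs = pairs)
}

#' Screen for LTR hairpin configurations
#'
#' Candidate hairpins are read pairs whose mates both align to LTR sequence
#' in the same mapped orientation (two LTRs in antisense within one
#' fragment) and whose outer span does not exceed the library insert size —
#' inverted LTR pairs further apart than the insert size cannot be captured.
#'
#' @param te_aln element alignment table.
#' @param annotation a [te_annotation()].
#' @param max_insert maximum fragment span detectable (bp).
#' @return data.table of candidate pairs (possibly empty).
#' @export
find_hairpins <- function(te_aln, annotation, max_insert = 700L) {
  t <- as.data.table(te_aln)
  if (nrow(t) == 0L) return(t[0])
  nn <- t[, .N, by = qname]
  t2 <- t[qname %in% nn[N == 2L, qname]]
  if (nrow(t2) == 0L) return(t2[0])
  setorder(t2, qname, mate)
  m1 <- t2[seq(1, .N, by = 2)]
  m2 <- t2[seq(2, .N, by = 2)]
  ov <- function(s, e, iv) s < iv[2] & iv[1] < e
  onltr <- function(m) ov(m$start, m$end, annotation$ltr5) |
    ov(m$start, m$end, annotation$ltr3)
  cand <- m1$strand == m2$strand & onltr(m1) & onltr(m2) &
    (pmax(m1$end, m2$end) - pmin(m1$start, m2$start)) <= max_insert
  t2[qname %in% m1$qname[cand]]
}
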