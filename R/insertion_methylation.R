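#' Split a call's supporting reads by LTR of origin
#'
#' Partitions the cluster's element-side mates into a 5' LTR and a 3' LTR
#' subset according to the per-read LTR-of-origin labels inferred from
#' orientation; reads with ambiguous labels go in neither subset, so the
#' subsets are disjoint.
#'
#' @param read_ltr per-read label table for one call (columns `qname`,
#'   `ltr`), e.g. from [call_insertions()].
#' @return list with character vectors `ltr5` and `ltr3` of read names.
#' @export
subset_reads_by_ltr <- function(read_ltr) {
  dt <- as.data.table(read_ltr)
  list(ltr5 = dt[ltr == "5p", unique(qname)],
       ltr3 = dt[ltr == "3p", unique(qname)])
}

#' Weighted LTR methylation from a read subset
#'
#' Computes weighted methylation per context over the LTR cytosines covered
#' by the given reads. Because the two LTRs are sequence-identical and
#' multi-mapping suppression reports LTR reads at 5' LTR coordinates,
#' observations on either LTR are first canonicalized to the shared LTR
#' offset coordinate system; the masked 3' LTR bases are thereby naturally
#' excluded (reads cannot map across them). Contexts with zero covered
#' cytosines are undefined (`NA`), not 0.
#'
#' @param obs_te element-frame observation table (`obs_te` from
#'   [simulate_emseq_reads()] or an equivalent extraction).
#' @param qnames read names of the subset.
#' @param te_seq element sequence (character or [Biostrings::DNAString]).
#' @param annotation a [te_annotation()].
#' @return data.frame per context: `context`, `weighted_pct`, `meth_count`,
#'   `total_count`, `n_cytosines`, plus an `n_reads` attribute-free column.
#' @export
per_ltr_methylation <- function(obs_te, qnames, te_seq, annotation) {
  obs <- as.data.table(obs_te)
  obs <- obs[qname %in% qnames]
  # canonical LTR offsets: positions on either LTR, expressed from its start
  in5 <- obs$pos >= annotation$ltr5[1] & obs$pos < annotation$ltr5[2]
  in3 <- obs$pos >= annotation$ltr3[1] & obs$pos < annotation$ltr3[2]
  obs <- obs[in5 | in3]
  obs[, pos := ifelse(pos >= annotation$ltr3[1], pos - annotation$ltr3[1],
                      pos - annotation$ltr5[1])]
  ltr_chars <- strsplit(substr(as.character(te_seq), annotation$ltr5[1] + 1L,
                               annotation$ltr5[2]), "", fixed = TRUE)[[1]]
  res <- list()
  for (strand in c("+", "-")) {
    base <- if (strand == "+") "C" else "G"
    pos1 <- which(ltr_chars == base)
    if (!length(pos1)) next
    ctx <- if (strand == "+") .context_plus(ltr_chars, pos1)
           else .context_minus(ltr_chars, pos1)
    o <- obs[obs$strand == strand]
    agg <- o[, .(m = sum(meth), u = sum(!meth)), by = pos]
    ix <- match(agg$pos + 1L, pos1)
    cm <- integer(length(pos1)); cu <- integer(length(pos1))
    ok <- !is.na(ix)
    cm[ix[ok]] <- agg$m[ok]; cu[ix[ok]] <- agg$u[ok]
    res[[strand]] <- data.table(context = ctx, count_meth = cm,
                                count_unmeth = cu)
  }
  dt <- rbindlist(res)
  out <- dt[, .(meth_count = sum(count_meth),
                total_count = sum(count_meth) + sum(count_unmeth),
                n_cytosines = sum(count_meth + count_unmeth > 0)),
            by = context]
  out <- out[match(c("CG", "CHG", "CHH"), context)]
  out[, context := c("CG", "CHG", "CHH")]
  out[is.na(meth_count), `:=`(meth_count = 0L, total_count = 0L,
                              n_cytosines = 0L)]
  out[, weighted_pct := ifelse(total_count > 0, 100 * meth_count / total_count,
                               NA_real_)]
  out[, n_reads := length(unique(qnames))]
  setcolorder(out, c("context", "weighted_pct", "meth_count", "total_count",
                     "n_cytosines", "n_reads"))
  setDF(out)
  out
}

#' Per-insertion, per-LTR methylation for all calls
#'
#' Applies [subset_reads_by_ltr()] and [per_ltr_methylation()] to every
#' retained call.
#'
#' @param calls_result output of [call_insertions()].
#' @param obs_te element-frame observations.
#' @param te_seq element sequence.
#' @param annotation a [te_annotation()].
#' @return data.frame: `call_id`, `ltr` (`"5p"`/`"3p"`), `context`,
#'   `weighted_pct`, counts and `n_reads`.
#' @export
insertion_ltr_methylation <- function(calls_result, obs_te, te_seq,
                                      annotation) {
  out <- list()
  for (id in calls_result$calls$call_id) {
    subsets <- subset_reads_by_ltr(
      calls_result$read_ltr[calls_result$read_ltr$call_id == id, ])
    for (side in c("ltr5", "ltr3")) {
      qn <- subsets[[side]]
      if (!length(qn)) next
      m <- per_ltr_methylation(obs_te, qn, te_seq, annotation)
      m$call_id <- id
      m$ltr <- if (side == "ltr5") "5p" else "3p"
      out[[length(out) + 1L]] <- m
    }
  }
  if (!length(out))
    return(data.frame(call_id = integer(), ltr = character(),
                      context = character(), weighted_pct = numeric()))
  res <- do.call(rbind, out)
  res[, c("call_id", "ltr", setdiff(names(res), c("call_id", "ltr")))]
}

#' Concordance between 5' and 3' LTR methylation across insertions
#'
#' Squared Pearson correlation of paired per-insertion 5' vs 3' LTR
#' methylation levels for one context. Requires at least 3 insertions with
#' both LTRs defined; returns `NA` otherwise.
#'
#' @param ltr5,ltr3 numeric vectors of per-insertion methylation percentages
#'   (pairs with an `NA` on either side are dropped).
#' @return R-squared (numeric scalar or `NA`).
#' @export
ltr_concordance <- function(ltr5, ltr3) {
  stopifnot(length(ltr5) == length(ltr3))
  ok <- !is.na(ltr5) & !is.na(ltr3)
  if (sum(ok) < 3L) return(NA_real_)
  cor(ltr5[ok], ltr3[ok])^2
}
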