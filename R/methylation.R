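# context of a cytosine on the plus strand at 1-based positions `pos`
# (bases beyond the sequence end are treated as non-G, i.e. CHH)
.context_plus <- function(chars, pos) {
  n <- length(chars)
  nxt <- ifelse(pos + 1L <= n, chars[pmin(pos + 1L, n)], "N")
  nxt2 <- ifelse(pos + 2L <= n, chars[pmin(pos + 2L, n)], "N")
  ifelse(nxt == "G", "CG", ifelse(nxt2 == "G", "CHG", "CHH"))
}

# context of a cytosine on the minus strand: the record sits on a plus-strand
# G; its downstream neighbours are the complemented upstream plus-strand bases
.context_minus <- function(chars, pos) {
  prv <- ifelse(pos - 1L >= 1L, chars[pmax(pos - 1L, 1L)], "N")
  prv2 <- ifelse(pos - 2L >= 1L, chars[pmax(pos - 2L, 1L)], "N")
  ifelse(prv == "C", "CG", ifelse(prv2 == "C", "CHG", "CHH"))
}

.trinuc <- function(chars, pos, strand) {
  n <- length(chars)
  get <- function(p) ifelse(p >= 1L & p <= n, chars[pmin(pmax(p, 1L), n)], "N")
  if (strand == "+") {
    paste0(get(pos), get(pos + 1L), get(pos + 2L))
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste0(comp[get(pos)], comp[get(pos - 1L)], comp[get(pos - 2L)])
  }
}

#' Classify the sequence context of a cytosine
#'
#' Returns `"CG"`, `"CHG"` or `"CHH"` (H = A, C or T) for a cytosine at the
#' given 1-based position. On the minus strand the position must carry a G on
#' the given (plus-strand) sequence and the context is evaluated on the
#' reverse complement, i.e. leftwards.
#'
#' @param sequence a character string or [Biostrings::DNAString].
#' @param position integer vector of 1-based positions.
#' @param strand `"+"` or `"-"` (recycled).
#' @return character vector of contexts.
#' @examples
#' classify_context("CGA", 1, "+")  # "CG"
#' classify_context("CAG", 1, "+")  # "CHG"
#' classify_context("TCG", 3, "-")  # "CG": G pairs with a C on the minus strand
#' @export
classify_context <- function(sequence, position, strand = "+") {
  chars <- strsplit(as.character(sequence), "", fixed = TRUE)[[1]]
  strand <- rep_len(strand, length(position))
  base <- chars[position]
  want <- ifelse(strand == "+", "C", "G")
  if (any(base != want))
    stop("position ", paste(position[base != want], collapse = ","),
         " does not carry a cytosine on strand ",
         paste(unique(strand[base != want]), collapse = ","))
  out <- character(length(position))
  p <- strand == "+"
  if (any(p)) out[p] <- .context_plus(chars, position[p])
  if (any(!p)) out[!p] <- .context_minus(chars, position[!p])
  out
}

#' Weighted average methylation over a set of cytosine records
#'
#' Computes, per context, the coverage-weighted methylation percentage
#' `100 * sum(methylated) / sum(methylated + unmethylated)` — never a mean of
#' per-site fractions, so deeply covered cytosines weigh more. Cytosines with
#' zero coverage contribute nothing to either sum; a context with zero total
#' coverage is flagged undefined (`NA`), not 0.
#'
#' @param records cytosine report data.frame (see [read_cytosine_report()]):
#'   columns `contig`, `pos` (1-based), `strand`, `count_meth`,
#'   `count_unmeth`, `context`.
#' @param contig optional contig to restrict to.
#' @param start,end optional 1-based inclusive interval to restrict to.
#' @param contexts contexts to summarize.
#' @return data.frame with one row per context: `context`, `weighted_pct`
#'   (NA when coverage is zero), `meth_count`, `total_count`, `n_cytosines`
#'   (covered cytosines).
#' @export
weighted_methylation <- function(records, contig = NULL, start = NULL,
                                 end = NULL, contexts = c("CG", "CHG", "CHH")) {
  dt <- as.data.table(records)
  if (!is.null(contig)) {
    ctg_keep <- contig
    dt <- dt[dt$contig %in% ctg_keep]
  }
  if (!is.null(start)) dt <- dt[pos >= start]
  if (!is.null(end)) dt <- dt[pos <= end]
  out <- lapply(contexts, function(cx) {
    d <- dt[context == cx]
    m <- sum(d$count_meth)
    tot <- m + sum(d$count_unmeth)
    data.frame(context = cx,
               weighted_pct = if (tot > 0) 100 * m / tot else NA_real_,
               meth_count = m, total_count = tot,
               n_cytosines = sum(d$count_meth + d$count_unmeth > 0))
  })
  do.call(rbind, out)
}

#' Enzymatic conversion rate from an unmethylated control contig
#'
#' The chloroplast-like control contig carries no methylation, so any
#' methylated call there reflects a conversion failure. The conversion rate
#' is `100 - weighted methylation` pooled over all contexts on the control
#' contig.
#'
#' @param records cytosine report data.frame.
#' @param control_contig name of the unmethylated control contig.
#' @return conversion rate as a percentage.
#' @export
conversion_rate <- function(records, control_contig) {
  dt <- as.data.table(records)
  d <- dt[contig == control_contig]
  if (!nrow(d)) stop("control contig '", control_contig, "' absent from report")
  m <- sum(d$count_meth)
  tot <- m + sum(d$count_unmeth)
  if (tot == 0) stop("control contig has zero coverage")
  100 - 100 * m / tot
}

#' Compare per-cytosine methylation between two groups
#'
#' Two-sided Wilcoxon rank-sum test per context on per-cytosine methylation
#' fractions (each cytosine is one observation), with Benjamini-Hochberg
#' adjustment across the comparisons performed in this invocation. Ties are
#' handled by the normal approximation with tie correction.
#'
#' @param group_a,group_b data.frames with columns `context` and `value`
#'   (per-cytosine methylation, any common scale).
#' @param contexts contexts to test.
#' @param alpha significance boundary reported in the `signif` column.
#' @return data.frame: `context`, `n_a`, `n_b`, `p`, `p_adj`, `signif`.
#' @export
compare_methylation <- function(group_a, group_b,
                                contexts = c("CG", "CHG", "CHH"),
                                alpha = 0.05) {
  a <- as.data.table(group_a); b <- as.data.table(group_b)
  res <- lapply(contexts, function(cx) {
    va <- a[context == cx, value]
    vb <- b[context == cx, value]
    p <- if (length(va) < 2 || length(vb) < 2) NA_real_ else
      suppressWarnings(wilcox.test(va, vb, exact = FALSE)$p.value)
    data.frame(context = cx, n_a = length(va), n_b = length(vb), p = p)
  })
  res <- do.call(rbind, res)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$signif <- !is.na(res$p_adj) & res$p_adj < alpha
  res
}

#' Wilson score confidence interval for a proportion
#'
#' Closed-form Wilson score bounds, as used for confidence intervals on the
#' percentage of methylated sites.
#'
#' @param successes,trials non-negative integers with
#'   `0 <= successes <= trials`, `trials > 0`; vectorized.
#' @param confidence confidence level.
#' @return matrix with columns `lower`, `upper` (proportions in \[0, 1\]).
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (any(trials <= 0)) stop("trials must be positive")
  if (any(successes < 0 | successes > trials))
    stop("successes must be within [0, trials]")
  z <- qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  center <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  cbind(lower = pmax(0, center - half), upper = pmin(1, center + half))
}
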