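#' Per-base depth of coverage from alignment records
#'
#' Computes zero-filled per-base depth (every position reported, mirroring
#' `samtools depth -aa`) from first-pass paired alignments.
#'
#' @param aln alignment table (`genome_aln` from [simulate_emseq_reads()] or
#'   [read_sam()]): columns `contig`, `start`, `end` (0-based half-open),
#'   optionally `mode`.
#' @param contig_lengths named integer vector of contig lengths.
#' @param paired_only use only `mode == "paired"` records when a `mode`
#'   column is present (the concordant first-pass alignments).
#' @return named list of integer vectors, one per contig, `depth[[ctg]][i]`
#'   being the depth at 0-based position `i - 1`.
#' @export
depth_from_alignments <- function(aln, contig_lengths, paired_only = TRUE) {
  dt <- as.data.table(aln)
  if (paired_only && "mode" %in% names(dt)) dt <- dt[mode == "paired"]
  out <- list()
  for (ctg in names(contig_lengths)) {
    d <- dt[contig == ctg]
    L <- contig_lengths[[ctg]]
    if (nrow(d)) {
      cov <- IRanges::coverage(IRanges::IRanges(d$start + 1L, d$end),
                               width = L)
      out[[ctg]] <- as.integer(cov)
    } else {
      out[[ctg]] <- integer(L)
    }
  }
  out
}

#' Coverage ratio of the element over its flanking windows
#'
#' Ratio of the mean per-base depth over the element's internal interval at
#' the reference copy to the mean depth over the pooled (base-wise union of
#' the) two flanking normalization windows. Because every additional element
#' copy in the sample piles its reads onto the single reference copy, this
#' ratio scales with copy number.
#'
#' @param depth per-contig depth list from [depth_from_alignments()].
#' @param annotation a [te_annotation()] with `ref_contig`, `ref_start`,
#'   `depth_interval` and the two flank windows set.
#' @return the depth ratio (numeric scalar).
#' @export
coverage_ratio <- function(depth, annotation) {
  stopifnot(inherits(annotation, "te_annotation"), !is.na(annotation$ref_contig))
  d <- depth[[annotation$ref_contig]]
  if (is.null(d)) stop("reference contig absent from depth")
  te_iv <- annotation$ref_start + annotation$depth_interval
  te_depth <- d[(te_iv[1] + 1L):te_iv[2]]
  fl <- c(d[(annotation$flank_upstream[1] + 1L):annotation$flank_upstream[2]],
          d[(annotation$flank_downstream[1] + 1L):annotation$flank_downstream[2]])
  if (mean(fl) == 0) stop("flank windows have zero mean depth")
  mean(te_depth) / mean(fl)
}

#' Normalization factor from single-copy control samples
#'
#' The mean of the inverse coverage ratios of control samples that carry only
#' the reference insertion, used to express every other sample's ratio in
#' copies relative to one reference copy.
#'
#' @param control_ratios numeric vector of [coverage_ratio()] values from
#'   control samples; all must be positive.
#' @return the normalization factor (numeric scalar).
#' @export
normalization_factor <- function(control_ratios) {
  if (length(control_ratios) < 1) stop("at least one control ratio required")
  if (any(control_ratios <= 0)) stop("control ratios must be positive")
  mean(1 / control_ratios)
}

#' Copy number from a coverage ratio
#'
#' `copies = ratio * factor`, expressed relative to the single reference
#' insertion (a control sample normalized by its own factor gives 1).
#'
#' @param sample_ratio [coverage_ratio()] of the sample.
#' @param factor [normalization_factor()] from the controls.
#' @return estimated copies (numeric).
#' @export
estimate_copies_coverage <- function(sample_ratio, factor) {
  if (factor <= 0) stop("normalization factor must be positive")
  sample_ratio * factor
}

.mean_ct <- function(ct, sample, target) {
  v <- ct$ct[ct$sample == sample & ct$target == target]
  if (!length(v)) stop("no Ct values for sample '", sample, "', target '",
                       target, "'")
  if (any(!is.finite(v))) stop("non-finite Ct for sample '", sample, "'")
  mean(v)  # technical replicates averaged on the Ct scale
}

#' Element copy number from a qPCR delta-delta-Ct table
#'
#' Copies are estimated by absolute quantification relative to a calibrator
#' sample: `copies = 2^(-ddCt) * 2`, where
#' `ddCt = (Ct_te - Ct_ref)_sample - (Ct_te - Ct_ref)_calibrator` and the
#' final doubling reflects the inherent two copies (one per haploid genome
#' equivalent of the diploid) of both the element and the reference gene in
#' wild-type plants. Assumes 100% primer efficiency (exact doubling per
#' cycle). Technical replicates are averaged on the Ct scale first.
#'
#' @param ct long-format Ct table: columns `sample`, `target`, `ct`
#'   (and optionally `replicate`); see [read_ct_table()].
#' @param sample sample to quantify.
#' @param calibrator calibrator sample (wild-type-like, two copies).
#' @param te_target,ref_target target names of the element amplicon and the
#'   single-copy reference gene (e.g. ACT2).
#' @return estimated copy number (numeric scalar).
#' @export
qpcr_copy_number <- function(ct, sample, calibrator,
                             te_target = "EVD", ref_target = "ACT2") {
  ct <- as.data.frame(ct)
  if (!calibrator %in% ct$sample) stop("calibrator '", calibrator,
                                       "' absent from Ct table")
  dct_s <- .mean_ct(ct, sample, te_target) - .mean_ct(ct, sample, ref_target)
  dct_c <- .mean_ct(ct, calibrator, te_target) -
    .mean_ct(ct, calibrator, ref_target)
  2^(-(dct_s - dct_c)) * 2
}

#' Relative expression from a qPCR Ct table
#'
#' Fold change of the target over the reference gene, `2^(-dCt)` with
#' `dCt = Ct_target - Ct_ref`, optionally expressed relative to a calibrator
#' sample (`2^(-ddCt)`).
#'
#' @inheritParams qpcr_copy_number
#' @param target target-of-interest name.
#' @param calibrator optional calibrator sample.
#' @return fold change (numeric scalar).
#' @export
qpcr_relative_expression <- function(ct, sample, target,
                                     ref_target = "ACT2", calibrator = NULL) {
  ct <- as.data.frame(ct)
  dct <- .mean_ct(ct, sample, target) - .mean_ct(ct, sample, ref_target)
  if (!is.null(calibrator)) {
    if (!calibrator %in% ct$sample) stop("calibrator '", calibrator,
                                         "' absent from Ct table")
    dct <- dct - (.mean_ct(ct, calibrator, target) -
                    .mean_ct(ct, calibrator, ref_target))
  }
  2^(-dct)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header columns `sample`, `target`, `replicate`, `ct`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(dt)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  setDF(dt)
  dt
}
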