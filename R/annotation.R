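#' Annotation of the reference transposable element
#'
#' Describes the geometry of the element the pipeline tracks: its length, the
#' two (sequence-identical) long terminal repeats, the sub-interval of the
#' 3' LTR that is masked in the extracted element reference so that reads
#' cannot map exactly to both LTRs, the internal interval used for depth-based
#' copy-number estimation, and the position of the single reference copy in
#' the genome together with its two flanking normalization windows.
#'
#' All intervals are 0-based half-open. The element coordinate system runs
#' from 0 to `te_length` on the element's own sense strand; genome intervals
#' refer to the reference (insertion-free) genome.
#'
#' The default geometry mirrors a Ty1/Copia LTR retrotransposon of ~5.3 kb
#' with 416 bp LTRs and a ~106 bp masked window in the 3' LTR.
#'
#' @param te_length element length in bp.
#' @param ltr_length LTR length in bp (applies to both LTRs).
#' @param mask 0-based half-open interval masked inside the 3' LTR, in
#'   element coordinates. Must lie within the 3' LTR.
#' @param depth_interval element interval over which per-base depth is
#'   averaged for copy-number estimation (analogous to the span between the
#'   element's UTRs, avoiding LTR edge effects).
#' @param ref_contig,ref_start contig and 0-based start of the reference copy
#'   in the genome (`NA` if the element is not embedded).
#' @param flank_upstream,flank_downstream 0-based half-open genome intervals
#'   (numeric length-2) used as depth-normalization windows.
#' @param pericentromere data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) of pericentromeric intervals, or NULL.
#' @return an object of class `te_annotation` (a list).
#' @export
te_annotation <- function(te_length = 5336L,
                          ltr_length = 416L,
                          mask = c(5074L, 5180L),
                          depth_interval = c(500L, te_length - 500L),
                          ref_contig = NA_character_,
                          ref_start = NA_integer_,
                          flank_upstream = NULL,
                          flank_downstream = NULL,
                          pericentromere = NULL) {
  te_length <- as.integer(te_length)
  ltr_length <- as.integer(ltr_length)
  stopifnot(te_length > 2L * ltr_length, ltr_length > 0L)
  ltr5 <- c(0L, ltr_length)
  ltr3 <- c(te_length - ltr_length, te_length)
  mask <- as.integer(mask)
  if (mask[1] < ltr3[1] || mask[2] > ltr3[2] || mask[1] >= mask[2])
    stop("mask interval must be a proper sub-interval of the 3' LTR")
  depth_interval <- as.integer(depth_interval)
  if (depth_interval[1] >= depth_interval[2])
    stop("depth_interval must have positive width")
  structure(list(
    te_length = te_length,
    ltr_length = ltr_length,
    ltr5 = ltr5,
    ltr3 = ltr3,
    internal = c(ltr5[2], ltr3[1]),
    mask = mask,
    mask_rel = mask - ltr3[1],  # offsets of the mask within an LTR
    depth_interval = depth_interval,
    ref_contig = ref_contig,
    ref_start = as.integer(ref_start),
    flank_upstream = flank_upstream,
    flank_downstream = flank_downstream,
    pericentromere = pericentromere
  ), class = "te_annotation")
}

#' @export
print.te_annotation <- function(x, ...) {
  cat("<te_annotation>\n")
  cat(sprintf("  element: %d bp, LTRs %d bp, masked [%d,%d) in 3' LTR\n",
              x$te_length, x$ltr_length, x$mask[1], x$mask[2]))
  if (!is.na(x$ref_contig))
    cat(sprintf("  reference copy: %s:%d-%d\n", x$ref_contig, x$ref_start,
                x$ref_start + x$te_length))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic EM-seq experiment: the miniature
#' genome, the planted element, the methylome, and the converted paired-end
#' library. Defaults describe the study conditions the package is tested
#' under: a ~200 kb two-contig genome plus an unmethylated chloroplast-like
#' control contig, a 5.3 kb element with 416 bp LTRs, target-site
#' duplications of 5-8 bp, 150 bp paired-end reads with 300-700 bp inserts
#' at 30-fold coverage, and an enzymatic conversion failure rate of 0.1%.
#'
#' @param seed integer seed; every downstream stage derives its RNG stream
#'   from it, so identical configs give byte-identical output.
#' @param contig_lengths named integer vector of nuclear contig lengths (bp).
#' @param chloroplast_name name of the control contig.
#' @param chloroplast_length length of the control contig (bp).
#' @param te_length,ltr_length,mask element geometry, see [te_annotation()].
#' @param n_insertions number of new element copies to plant.
#' @param tsd_range integer length-2: min/max target-site duplication (bp);
#'   must lie within \[0, 50\].
#' @param strand_prob_plus probability a planted insertion is on the plus
#'   strand.
#' @param nested logical: plant one additional element antisense inside the
#'   first planted insertion.
#' @param nested_spacing numeric length-2: distances (bp) from the end of the
#'   parent 5' LTR to the start of the nested child, and from the end of the
#'   child to the start of the parent 3' LTR, measured on the parent element
#'   coordinate system before the child's TSD is applied.
#' @param coverage haploid fold-coverage of the library.
#' @param read_length read length (bp).
#' @param insert_size_range integer length-2: min/max insert size (bp).
#' @param conversion_failure probability an unmethylated cytosine escapes
#'   conversion and is read as C; must be in \[0, 1\].
#' @param methylation_profile named list mapping region class to a named
#'   numeric vector `c(CG=, CHG=, CHH=)` of methylation percentages. Classes
#'   `background`, `pericentromere`, `te` and `chloroplast` are required;
#'   the chloroplast profile must be all-zero (it is the conversion control).
#' @param ltr_meth_mode how per-insertion LTR methylation levels are drawn:
#'   `"uniform"` (all LTRs at the `te` profile), `"shared"` (one scaling
#'   factor per insertion applied to both LTRs) or `"independent"`
#'   (a separate factor per LTR).
#' @param site_flank_shift NULL, or `list(radius =, shift = c(CG=,CHG=,CHH=))`
#'   adding `shift` percentage points to the methylation profile within
#'   `radius` bp of every planted insertion point (used to emulate
#'   methylation spreading from new insertions into their flanks).
#' @param flank_width,flank_gap width of, and gap before, each of the two
#'   depth-normalization windows around the reference copy (bp).
#' @param min_mapped minimum aligned portion (bp) for a boundary read to be
#'   reported (shorter portions are treated as unalignable).
#' @return an object of class `sim_config` (a list).
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(chr1 = 120000L, chr2 = 80000L),
                       chloroplast_name = "chrC",
                       chloroplast_length = 20000L,
                       te_length = 5336L,
                       ltr_length = 416L,
                       mask = c(5074L, 5180L),
                       n_insertions = 20L,
                       tsd_range = c(5L, 8L),
                       strand_prob_plus = 0.5,
                       nested = FALSE,
                       nested_spacing = c(2562L, 1942L),
                       coverage = 30,
                       read_length = 150L,
                       insert_size_range = c(300L, 700L),
                       conversion_failure = 0.001,
                       methylation_profile = list(
                         background     = c(CG = 20, CHG = 6,  CHH = 2),
                         pericentromere = c(CG = 85, CHG = 60, CHH = 20),
                         te             = c(CG = 80, CHG = 55, CHH = 12),
                         chloroplast    = c(CG = 0,  CHG = 0,  CHH = 0)
                       ),
                       ltr_meth_mode = c("uniform", "shared", "independent"),
                       site_flank_shift = NULL,
                       flank_width = 9300L,
                       flank_gap = 700L,
                       min_mapped = 30L) {
  ltr_meth_mode <- match.arg(ltr_meth_mode)
  stopifnot(length(contig_lengths) >= 1, !is.null(names(contig_lengths)))
  tsd_range <- as.integer(tsd_range)
  if (tsd_range[1] < 0L || tsd_range[2] > 50L || tsd_range[1] > tsd_range[2])
    stop("tsd_range must be within [0, 50]")
  if (conversion_failure < 0 || conversion_failure > 1)
    stop("conversion_failure must be in [0, 1]")
  insert_size_range <- as.integer(insert_size_range)
  if (insert_size_range[1] > insert_size_range[2])
    stop("insert_size_range must be increasing")
  needed <- c("background", "pericentromere", "te", "chloroplast")
  if (!all(needed %in% names(methylation_profile)))
    stop("methylation_profile must define classes: ",
         paste(needed, collapse = ", "))
  if (any(methylation_profile$chloroplast != 0))
    stop("chloroplast methylation profile must be all-zero (conversion control)")
  for (p in methylation_profile)
    if (any(p < 0 | p > 100)) stop("methylation percentages must be in [0, 100]")
  if (!is.null(site_flank_shift))
    stopifnot(is.list(site_flank_shift),
              all(c("radius", "shift") %in% names(site_flank_shift)))
  structure(list(
    seed = as.integer(seed),
    contig_lengths = setNames(as.integer(contig_lengths), names(contig_lengths)),
    chloroplast_name = chloroplast_name,
    chloroplast_length = as.integer(chloroplast_length),
    te_length = as.integer(te_length),
    ltr_length = as.integer(ltr_length),
    mask = as.integer(mask),
    n_insertions = as.integer(n_insertions),
    tsd_range = tsd_range,
    strand_prob_plus = strand_prob_plus,
    nested = isTRUE(nested),
    nested_spacing = as.integer(nested_spacing),
    coverage = coverage,
    read_length = as.integer(read_length),
    insert_size_range = insert_size_range,
    conversion_failure = conversion_failure,
    methylation_profile = methylation_profile,
    ltr_meth_mode = ltr_meth_mode,
    site_flank_shift = site_flank_shift,
    flank_width = as.integer(flank_width),
    flank_gap = as.integer(flank_gap),
    min_mapped = as.integer(min_mapped)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s + %s (%d bp control); seed %d\n",
              paste(sprintf("%s=%d", names(x$contig_lengths), x$contig_lengths),
                    collapse = ", "),
              x$chloroplast_name, x$chloroplast_length, x$seed))
  cat(sprintf("  element: %d bp (LTR %d bp); %d insertions, TSD %d-%d bp\n",
              x$te_length, x$ltr_length, x$n_insertions,
              x$tsd_range[1], x$tsd_range[2]))
  cat(sprintf("  library: %gx, %d bp reads, inserts %d-%d bp, conv. failure %g\n",
              x$coverage, x$read_length, x$insert_size_range[1],
              x$insert_size_range[2], x$conversion_failure))
  invisible(x)
}
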