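#' Simulate a miniature reference genome with one embedded element copy
#'
#' Draws random nuclear contigs plus an unmethylated chloroplast-like control
#' contig, builds the element sequence (identical 5' and 3' LTRs flanking an
#' internal region), and embeds a single reference copy of the element in the
#' first nuclear contig together with two flanking depth-normalization
#' windows. Pericentromeric intervals default to the first quarter of every
#' nuclear contig.
#'
#' Sequences are deterministic given `config$seed`: the same configuration
#' always yields byte-identical sequences.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{genome}{[Biostrings::DNAStringSet] of all contigs (reference,
#'       i.e. insertion-free, but containing the reference element copy).}
#'     \item{te}{[Biostrings::DNAString] of the extracted element (unmasked).}
#'     \item{te_masked}{the extracted element with the 3' LTR mask applied
#'       (Ns), as used as alignment reference.}
#'     \item{annotation}{a [te_annotation()].}
#'   }
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  main <- names(config$contig_lengths)[1]
  if (config$contig_lengths[1] < 10L * config$te_length)
    stop("main contig must be at least 10x the element length")
  set.seed(config$seed)

  # base composition roughly matching a plant euchromatic genome (GC ~ 0.36)
  freqs <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)
  rand_dna <- function(n) {
    paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
  }

  seqs <- lapply(config$contig_lengths, rand_dna)
  seqs[[config$chloroplast_name]] <- rand_dna(config$chloroplast_length)
  genome <- Biostrings::DNAStringSet(unlist(seqs))

  # element: random internal region flanked by two identical LTRs
  ltr <- rand_dna(config$ltr_length)
  internal <- rand_dna(config$te_length - 2L * config$ltr_length)
  te <- Biostrings::DNAString(paste0(ltr, internal, ltr))

  # embed the reference copy mid-contig with room for both flank windows
  ref_start <- as.integer(floor(config$contig_lengths[1] / 2))
  fw <- config$flank_width
  gap <- config$flank_gap
  if (ref_start - gap - fw < 0 ||
      ref_start + config$te_length + gap + fw > config$contig_lengths[1])
    stop("main contig too short for the reference copy and its flank windows")
  genome[[main]] <- Biostrings::replaceAt(
    genome[[main]],
    IRanges::IRanges(ref_start + 1L, ref_start + config$te_length),
    as.character(te))

  peri <- data.frame(
    contig = names(config$contig_lengths),
    start = 0L,
    end = as.integer(floor(config$contig_lengths / 4)),
    stringsAsFactors = FALSE)

  ann <- te_annotation(
    te_length = config$te_length,
    ltr_length = config$ltr_length,
    mask = config$mask,
    ref_contig = main,
    ref_start = ref_start,
    flank_upstream = c(ref_start - gap - fw, ref_start - gap),
    flank_downstream = c(ref_start + config$te_length + gap,
                         ref_start + config$te_length + gap + fw),
    pericentromere = peri)

  te_masked <- Biostrings::replaceAt(
    te, IRanges::IRanges(ann$mask[1] + 1L, ann$mask[2]),
    paste(rep("N", ann$mask[2] - ann$mask[1]), collapse = ""))

  list(genome = genome, te = te, te_masked = te_masked, annotation = ann)
}
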