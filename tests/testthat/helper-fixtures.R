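# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# the standard study conditions: 20 insertions, 30x, ~200 kb nuclear genome
std_config <- function(seed = 3L, ...) sim_config(seed = seed, ...)

std_sim <- function() fixture("std_sim", function() {
  simulate_sample(std_config())
})

std_calls <- function() fixture("std_calls", function() {
  s <- std_sim()
  call_insertions(s$reads$genome_aln, s$reads$te_aln,
                  pericentromere = s$reference$annotation$pericentromere)
})

# insertion-free control on the same reference genome
control_sim <- function() fixture("control_sim", function() {
  simulate_sample(sim_config(seed = 4L, n_insertions = 0L),
                  genome = std_sim()$reference)
})

# small, fast configuration for determinism / toy-region tests
toy_config <- function(seed = 7L, n_insertions = 3L, coverage = 10, ...) {
  sim_config(seed = seed, contig_lengths = c(chr1 = 60000L),
             chloroplast_length = 5000L, n_insertions = n_insertions,
             coverage = coverage, ...)
}

toy_sim <- function() fixture("toy_sim", function() simulate_sample(toy_config()))

# compact element geometry for conversion-rate simulations (small main
# contig, deep chloroplast)
conversion_config <- function(seed) {
  sim_config(seed = seed, contig_lengths = c(chr1 = 15000L),
             chloroplast_length = 20000L, te_length = 1200L,
             ltr_length = 150L, mask = c(1080L, 1130L), n_insertions = 0L,
             coverage = 40, flank_width = 3000L, flank_gap = 300L,
             conversion_failure = 0.001)
}

# four-sample cohort (two genotypes) with a planted CHH gain in the flanks
# of every insertion, for landing-site and metaplot tests
cohort_sim <- function() fixture("cohort_sim", function() {
  cfg <- sim_config(seed = 9L, n_insertions = 6L, coverage = 15,
                    site_flank_shift = list(radius = 100L,
                                            shift = c(CG = 0, CHG = 0, CHH = 20)))
  samples <- data.frame(sample_id = c("wtA", "wtB", "muA", "muB"),
                        genotype = c("wt", "wt", "mu", "mu"),
                        status = c("active", "silenced", "active", "silenced"),
                        n_insertions = c(6, 5, 6, 5))
  coh <- simulate_cohort(cfg, samples)
  calls <- data.table::rbindlist(lapply(names(coh$samples), function(sn) {
    s <- coh$samples[[sn]]
    r <- call_insertions(s$reads$genome_aln, s$reads$te_aln)
    data.table::data.table(sample_id = sn, r$calls[, c("contig", "site")])
  }))
  list(cohort = coh, samples = samples, calls = calls,
       reports = lapply(coh$samples, function(s) s$report_genome))
})

# hand-built cluster rows in the find_discordant() output convention
make_cluster <- function(starts, strands, te_strands = NULL,
                         clip_left = 0L, clip_right = 0L, len = 150L) {
  n <- length(starts)
  data.table::data.table(
    qname = sprintf("r%02d", seq_len(n)),
    contig = "chr1",
    g_start = as.integer(starts),
    g_end = as.integer(starts + len),
    g_strand = strands,
    g_mate = 1L,
    clip_left = rep_len(as.integer(clip_left), n),
    clip_right = rep_len(as.integer(clip_right), n),
    te_start = 10L, te_end = 160L,
    te_strand = if (is.null(te_strands))
      ifelse(strands == "+", "-", "+") else te_strands,
    cluster = 1L)
}
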