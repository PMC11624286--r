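# emburst

Tools to follow the genomic burst of an active LTR retrotransposon from
enzymatic methyl-sequencing (EM-seq) data.

When a silenced retrotransposon — the model here is the *Arabidopsis*
Ty1/Copia element ÉVADÉ (EVD) — escapes epigenetic control, it multiplies
across the genome over generations until the host re-silences it. A single
EM-seq experiment captures the whole process: read pairs that connect
genomic flanks to element sequence reveal where new copies landed, excess
coverage over the single reference copy counts them, and C/T conversion
reports the DNA methylation of the element, of each new copy's regulatory
LTRs, and of the sites it inserted into. `emburst` is for genomicists and
epigeneticists who want that workflow as tested, reusable R functions
rather than a one-off analysis.

## What it computes

* **Insertion calling** from discordant read mates: genome-side mates are
  clustered; a valid cluster is *m* ≥ 3 reads pointing toward the contig 3'
  end followed by *n* ≥ 3 pointing back, the insertion site lying between
  the *m*-th and (*m*+1)-st read. Boundary soft-clips give the target-site
  duplication (TSD) as the overlap of the two boundary reads; element-mate
  orientation gives the insertion strand and each read's LTR of origin.
  Antisense nested insertions and LTR hairpin candidates are screened from
  same-orientation element pairs.
* **Copy number** as the normalized depth ratio
  `mean depth(element interval) / mean depth(pooled ±10 kb flanks)`, scaled
  by the mean inverse ratio of single-copy controls; plus the qPCR
  companion `copies = 2^(-ΔΔCt) × 2`.
* **Methylation** as weighted averages per CG/CHG/CHH context
  (`100·Σmeth/Σtotal`, never a mean of per-site fractions), conversion
  rates from an unmethylated chloroplast control, Wilcoxon + BH group
  comparisons, and Wilson 95% intervals.
* **Per-LTR methylation** of every new insertion from its cluster's reads,
  with 5'/3' LTR concordance (R²).
* **Landing sites**: polymorphic insertions are classified from
  same-genotype non-carriers as unmethylated / mCG-only / non-CG (10%
  rules), non-CG sites sub-labelled RdDM/CMT2/independent from an
  annotation BED, and carrier-vs-non-carrier methylation shifts summarized
  as metaplots.
* **A seeded simulator** that builds a miniature genome, plants insertions
  with 5–8 bp TSDs, assigns a region-class methylome, and emits converted
  paired-end reads with truth-derived alignments and cytosine reports — so
  the entire pipeline is testable against known truth with no downloads.

See `vignettes/emburst-methods.Rmd` for the full model description and
design choices.

## Worked example

Simulate the standard conditions — 20 insertions at 30× on a ~200 kb
genome plus an unmethylated control contig — then call insertions, estimate
copy number, and quantify methylation:

```r
library(emburst)

cfg    <- sim_config(seed = 3)
sample <- simulate_sample(cfg)
ctrl   <- simulate_sample(sim_config(seed = 4, n_insertions = 0),
                          genome = sample$reference)

res <- call_insertions(sample$reads$genome_aln, sample$reads$te_aln,
                       pericentromere = sample$reference$annotation$pericentromere)
head(res$calls[, c("contig","site_lo","site_hi","strand","tsd","m","n","location")], 5)
#>    contig site_lo site_hi strand   tsd     m     n        location
#> 1:   chr1    2546    2554      +     8    42    32 pericentromeric
#> 2:   chr1    9834    9840      +     6    25    30 pericentromeric
#> 3:   chr1   17084   17090      -     6    17    32 pericentromeric
#> 4:   chr1   22665   22671      -     6    25    17 pericentromeric
#> 5:   chr1   29457   29462      -     5    28    28 pericentromeric
```

All 20 planted insertions are recovered (each site interval is the TSD
itself, 5–8 bp, supported by ≥ 17 discordant mates per border). Copy number
and conversion rate:

```r
lens <- vapply(names(sample$reference$genome),
               function(n) length(sample$reference$genome[[n]]), 1L)
ann  <- sample$reference$annotation
r    <- coverage_ratio(depth_from_alignments(sample$reads$genome_aln, lens), ann)
r0   <- coverage_ratio(depth_from_alignments(ctrl$reads$genome_aln, lens), ann)
estimate_copies_coverage(r, normalization_factor(r0))
#> [1] 22.9          # 20 planted + 1 reference copy, within depth noise at 30x
conversion_rate(sample$report_genome, "chrC")
#> [1] 99.89         # simulated conversion failure was 0.1%
```

Per-LTR methylation of the first called insertion (the simulated element is
methylated at CG/CHG/CHH = 80/55/12%):

```r
lm <- insertion_ltr_methylation(res, sample$reads$obs_te, sample$reference$te, ann)
head(lm[, c("call_id","ltr","context","weighted_pct","n_reads")], 6)
#>   call_id ltr context weighted_pct n_reads
#> 1       1  5p      CG     76.36364      42
#> 2       1  5p     CHG     52.60417      42
#> 3       1  5p     CHH     11.85567      42
#> 4       1  3p      CG     85.60606      32
#> 5       1  3p     CHG     50.69444      32
#> 6       1  3p     CHH     14.00709      32
```

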