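---
title: "Methods: tracking an LTR retrotransposon burst from EM-seq"
author: "emburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking an LTR retrotransposon burst from EM-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`emburst` implements the computational workflow used to follow the genomic
proliferation of an active LTR retrotransposon — modelled on the
*Arabidopsis* Ty1/Copia element ÉVADÉ (EVD) — from whole-genome enzymatic
methyl-sequencing (EM-seq) libraries. EM-seq converts unmethylated cytosines
to uracil (read as T) while methylated cytosines stay C, so a single
sequencing experiment simultaneously reports (i) where new element copies
have inserted, through read pairs that connect genomic flanks to element
sequence, (ii) how many copies the genome carries, through excess coverage
over the single reference copy, and (iii) the DNA methylation state of the
element and of its integration sites, through C/T conversion counts.

The package operates downstream of read alignment: it consumes alignment
records and per-cytosine count reports, or produces both itself with a
seeded simulator so that every stage can be exercised, and its statistical
behaviour measured, against planted ground truth without any external
dataset.

# The insertion caller

## Discordant pairs

Reads are taken from two alignment sets: single-end alignments to the
reference genome and to the extracted element sequence. A fragment is
*discordant* when one mate aligns to the genome and the other to the
element; such fragments arise when the sequenced fragment straddles the
junction of a non-reference insertion. Reads that align to both references
are unreliable and are discarded together with their mates; read names
without exactly one mate on each reference are skipped and counted in the
run log, so the filter behaviour is auditable.

## Clusters, directionality, and the site interval

Genome-side mates are sorted by contig and start coordinate and grouped into
clusters whenever successive starts are at most `max_gap` apart. The default
`max_gap = 700` bp equals the maximum library insert size — the farthest a
genome-side mate can sit from the junction it witnesses. Around a true
insertion, every upstream mate must point toward the contig 3' end and every
downstream mate toward the 5' end (all reads face the insertion), so a valid
cluster is a prefix of `m >= 3` plus-strand reads followed by a suffix of
`n >= 3` minus-strand reads with a single direction switch. The insertion
site is bracketed between the end of the m-th and the start of the (m+1)-st
read.

A cluster containing *two* direction switches (`+++---+++---`) is the
signature of two nearby insertions; by default the caller splits such
clusters at the downstream-to-upstream transition and validates each part
separately (`split_ambiguous = FALSE` restores the stricter behaviour of
discarding them). When two retained calls still claim overlapping site
intervals, the call with higher total support wins and the loser is logged.

## Target-site duplications

Integration duplicates a short stretch of the target site (5–8 bp for this
element family) on both sides of the element. On the reference coordinate
system the two flanks therefore *overlap* by exactly the TSD length, and the
boundary reads show it: the m-th read is soft-clipped on its
insertion-proximal end (the element-derived bases), the (m+1)-st read on its
insertion-proximal end, and their reference spans overlap. The TSD length is
that overlap. The clip sides are evaluated in reference orientation —
"insertion-proximal end of each boundary read" — which is the reading
consistent with both possible nomenclatures for clip sides. With 0-based
half-open intervals the overlap is simply `end(m-th) - start((m+1)-st)`,
and planted TSDs are recovered exactly whenever both boundary reads carry
the clip pattern.

## Strand and LTR of origin

The element-side mate of each discordant pair aligns in an orientation that
is fixed by the insertion strand and the border the pair comes from: for a
sense insertion, upstream-border pairs carry element mates on the element
minus strand (they originate in the 5' LTR) and downstream-border pairs
carry plus-strand mates from the 3' LTR; both relations reverse for an
antisense insertion. Each read votes; a unanimous cluster fixes the
insertion strand and labels every read's LTR of origin, while any conflict
flags the call ambiguous and leaves labels `NA`. This orientation-based
labelling is what later allows methylation to be measured separately on the
two LTRs of every new insertion even though the LTRs are sequence-identical.

## Nested insertions and hairpins

An element copy inserted antisense *inside* another copy produces read
pairs whose mates both align to the element in the same orientation — a
strand anomaly impossible for a concordant fragment. Pairs with this
anomaly and a mate overlapping an LTR are tallied per LTR: a sample is
scored `Y` (confident nested insertion) at `>= 2` supporting mates at each
LTR, `y` when at least one such mate exists anywhere, and `N` otherwise.
The related hairpin screen looks for same-orientation mates that both fall
in LTR sequence within one fragment; it is blind to inverted LTR pairs
farther apart than the library insert size (~300–700 bp), a stated limit of
the approach rather than a defect.

# Copy number

Every additional element copy contributes reads whose only unique placement
is the single reference copy, so the mean depth over the element interval
scales with copy number while the flanking depth reflects the ordinary
genome. The estimator is the ratio of mean per-base depth over the
element's internal interval (between the LTRs, avoiding edge effects from
junction-spanning fragments) to the mean depth over the base-wise pool of
two ~10 kb flanking windows. Flanks are pooled as one union of bases, not
averaged per flank, so a length imbalance cannot bias the ratio. Control
samples carrying only the reference copy provide the normalization: the
mean of their inverse ratios rescales every other sample so that one
reference copy reads as 1. The estimator is scale-invariant — multiplying
all depths by a constant changes nothing.

The qPCR calculator implements the companion delta-delta-Ct arithmetic:
`copies = 2^(-ddCt) * 2`, the final factor being the two inherent copies of
both target and reference gene in a wild-type diploid; relative expression
is `2^(-dCt)` against the reference gene. Technical replicates are averaged
on the Ct scale before differencing, and 100% primer efficiency (exact
doubling per cycle) is assumed throughout, as no efficiency calibration is
modelled. Extra-chromosomal element DNA can inflate qPCR estimates relative
to coverage-based ones; the package reports both and does not attempt to
reconcile them.

# Methylation quantification

All summaries use *weighted* methylation: `100 * sum(methylated reads) /
sum(all reads)` over the cytosines of a region and context, never a mean of
per-site fractions — deeply covered cytosines carry proportionally more
weight, and the statistic is invariant to how records are partitioned into
batches. Cytosines with zero coverage contribute nothing to either sum; a
region/context with zero total coverage is *undefined* (`NA`), never 0.
Contexts follow the standard CG / CHG / CHH classification (H = A, C or T),
evaluated on the reverse complement for minus-strand cytosines; a cytosine
at the extreme end of a sequence, whose context is truncated, falls to CHH.

The enzymatic conversion rate is estimated from the chloroplast-like
control contig, which is biologically unmethylated: the conversion rate is
100 minus its weighted methylation over all contexts. Group comparisons use
the two-sided Wilcoxon rank-sum test per context on per-cytosine fractions
(each cytosine is one observation), with ties handled by the normal
approximation; Benjamini–Hochberg adjustment is applied across the
comparisons of one invocation, matching per-figure adjustment granularity.
Binomial proportions are interval-estimated with the closed-form Wilson
score at 95%.

## Per-LTR methylation of new insertions

For each retained call, the element-side mates are partitioned by their
inferred LTR of origin (ambiguous reads excluded, so the subsets are
disjoint) and a cytosine report is computed from each subset over LTR
coordinates. Because multi-mapping suppression reports purely-LTR reads at
5' LTR coordinates, observations are first canonicalized to the shared LTR
offset frame; the masked 3' LTR bases are naturally absent (no read can
align across them). Only element-side mates are used — they alone carry LTR
sequence — and mate-overlap double counting is removed exactly as in the
global extraction. Concordance between the two LTRs of individual
insertions is summarized as the squared Pearson correlation over insertions
with both LTRs defined (minimum 3 pairs).

# Landing sites

The methylation state of an integration site *before* transposition is read
from same-genotype individuals that do not carry the insertion. Calls from
all samples are grouped into sites (within 100 bp); sites carried by every
sequenced sample are discarded as uninformative, and each remaining site's
same-genotype non-carriers form its informative set. Counts are pooled
across informative samples over a ±200 bp window (the window is a package
default — the analysis is annotation-free — and configurable). Sites are
classified by the 10% rules: unmethylated (all three contexts < 10%),
mCG-only (CG > 10%, CHG and CHH < 10%), or non-CG (CHG or CHH > 10%).
Values exactly at 10% fall to the less-methylated class and are flagged
borderline, making the classification exhaustive over all percentage
triples. Non-CG sites are sub-labelled RdDM / CMT2 / independent by any
overlap of the window with an externally supplied pathway annotation BED
(RdDM taking precedence when both overlap); the package consumes this
annotation, it does not derive it.

The methylation-shift metaplot contrasts carriers with non-carriers around
each site: per 50 bp bin of distance (±2 kb by default) and context, the
difference of pooled weighted methylation (carrier − non-carrier), averaged
over sites within each genotype × silencing-status group. Distances are
measured on the insertion-free (reference) coordinate frame, where
element-internal bases do not exist, so only flanking sequence enters.
Empty bins are `NA` and excluded from the average.

# The simulator

The simulator generates the complete study in miniature and is itself
first-class, tested code.

* **Genome.** Random nuclear contigs (~200 kb total by default, base
  composition GC ≈ 0.36) plus a 20 kb chloroplast-like control contig. One
  reference element copy (5,336 bp with identical 416 bp LTRs, a ~106 bp
  masked window in the 3' LTR) is embedded mid-contig with two 9.3 kb
  normalization windows 700 bp away — geometry scaled from the element this
  package models.
* **Insertions.** `n_insertions` copies (default 20) are planted at random
  positions with TSDs uniform in 5–8 bp and random strands, avoiding the
  reference locus, the control contig and each other (≥ 4.2 kb separation,
  so clusters never merge). An optional nested configuration plants one
  copy antisense inside the first at inter-LTR spacings of 2,562 and 1,942
  bp, the arrangement whose default element geometry (5,336 = 2 × 416 +
  2,562 + 1,942) reproduces exactly. Excising each element plus one TSD
  copy restores the original genome byte-for-byte — the round-trip the test
  suite checks.
* **Methylome.** Every cytosine of the mutated genome gets a methylation
  probability from its region class: background euchromatin (CG/CHG/CHH =
  20/6/2%), pericentromere (85/60/20%), element (80/55/12%), chloroplast
  (0/0/0 — it is the conversion control). These defaults are ordinary
  plant-genome values; per-insertion LTR levels can be scaled uniformly,
  shared between the two LTRs, or drawn independently (for concordance
  experiments), and an optional carrier-only gain within a radius of every
  insertion point emulates methylation spreading into the flanks.
* **Library.** Fragments are drawn uniformly at 30× with insert sizes
  uniform in 300–700 bp and 150 bp mates; half present the top-strand
  conversion view, half the bottom (the library is strand-symmetric — real
  EM protocols do not guarantee this but nothing downstream depends on it).
  A cytosine is read as C with its methylation probability and otherwise
  escapes conversion with probability 0.001; there is no other error model,
  no PCR duplicates, and base qualities are a constant placeholder.
  Overlapping mate bases are assigned to the first mate once, mirroring
  `--no_overlap` extraction.
* **Alignments.** Records are derived from the planted truth, not an
  aligner, but reproduce the two-pass semantics of a bisulfite aligner:
  concordant pairs (fully outside, or fully inside one element) align
  paired-end — element-interior pairs at the reference copy, which is what
  makes coverage-based copy number work; junction-straddling pairs are
  re-mapped single-end with element bases soft-clipped on the genome side;
  purely-LTR reads are ambiguous between the two identical LTRs and are
  removed unless they overlap the region whose 3' LTR copy is masked, in
  which case they are reported at 5' LTR coordinates (knowingly
  mis-assigned for genuine 3' LTR reads — the cost the masking strategy
  accepts to retain LTR coverage). Aligned portions shorter than 30 bp are
  treated as unalignable.

## What the simulator does not emulate

Passing tests demonstrate the pipeline's correctness under its own model of
the data, not robustness to everything real libraries do: there are no
sequencing errors, chimeras, PCR duplicates, mappability or GC biases, no
partial or truncated element insertions, no genuinely repeated genomic
sequence beyond the element itself, and conversion failure is uniform
rather than fragment-specific. Site recovery at 30× is therefore close to
perfect by construction; on real data the same thresholds trade recall for
precision in ways the simulation cannot measure.

# Numerical and design choices

* Coordinates are 0-based half-open internally; emitted cytosine reports
  are 1-based (stated in each writer), BED output is 0-based half-open.
* The cluster gap, per-border support (3), nested-mate threshold (2),
  classification boundary (10%), landing-site window (±200 bp) and metaplot
  geometry (50 bp bins over ±2 kb) are all exposed as arguments with the
  defaults above.
* Placement of planted insertions retries up to 200 × n times before
  failing with a sizing error; site grouping across samples uses single
  linkage at 100 bp.
* Degenerate inputs fail loudly: zero-coverage summaries are `NA`-flagged
  rather than 0, zero fragments / empty flank depth / absent control contig
  / malformed report dialects raise errors, and empty call sets propagate
  as empty tables.
* Test and acceptance runs use a ~200 kb nuclear genome at 30× (about
  22,000 fragments) and four-sample cohorts at 15× — sizes chosen so the
  full suite exercises every stage end-to-end in about a minute while
  leaving estimator noise (binomial counting, depth fluctuation) large
  enough to be tested against rather than hidden.

# Known limitations

Beyond the simulator's idealizations: the caller assumes exactly one active
element family and cannot separate two insertions closer than a fragment
length; copy-number normalization requires at least one genuine single-copy
control; per-LTR methylation inherits the 5'/3' blurring of mask-rescued
reads that the masking strategy itself introduces; and the landing-site
classification depends on cohort structure — a genotype sequenced once
contributes no informative sites, which the run log reports.
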