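test_that("simulated genome has configured lengths and element geometry", {
  cfg <- toy_config()
  g <- simulate_genome(cfg)
  expect_equal(length(g$genome[["chr1"]]), 60000L)
  expect_equal(length(g$genome[["chrC"]]), 5000L)
  expect_equal(length(g$te), cfg$te_length)
  # identical LTRs before masking
  ann <- g$annotation
  ltr5 <- substr(as.character(g$te), ann$ltr5[1] + 1L, ann$ltr5[2])
  ltr3 <- substr(as.character(g$te), ann$ltr3[1] + 1L, ann$ltr3[2])
  expect_identical(ltr5, ltr3)
  # masked reference carries Ns exactly over the mask
  masked <- as.character(g$te_masked)
  expect_true(all(strsplit(substr(masked, ann$mask[1] + 1L, ann$mask[2]),
                           "")[[1]] == "N"))
  # the embedded reference copy equals the extracted element
  emb <- substr(as.character(g$genome[[ann$ref_contig]]),
                ann$ref_start + 1L, ann$ref_start + ann$te_length)
  expect_identical(emb, as.character(g$te))
})

test_that("identical seeds give byte-identical sequences, reads and reports", {
  a <- simulate_sample(toy_config())
  b <- simulate_sample(toy_config())
  expect_identical(as.character(a$reference$genome), as.character(b$reference$genome))
  expect_identical(as.character(a$mutated), as.character(b$mutated))
  expect_identical(a$reads$genome_aln, b$reads$genome_aln)
  expect_identical(a$reads$te_aln, b$reads$te_aln)
  expect_identical(a$report_genome, b$report_genome)
})

test_that("contig too short for the element is rejected", {
  cfg <- toy_config()
  cfg$contig_lengths <- c(chr1 = 20000L)
  expect_error(simulate_genome(cfg), "10x")
})

test_that("planting zero insertions leaves the genome unchanged", {
  cfg <- toy_config(n_insertions = 0L)
  g <- simulate_genome(cfg)
  p <- plant_insertions(g$genome, g$annotation, cfg)
  expect_identical(as.character(p$genome), as.character(g$genome))
  expect_equal(nrow(p$truth$insertions), 0L)
})

test_that("each insertion duplicates the target site on both sides", {
  s <- toy_sim()
  orig <- s$reference$genome
  ins <- s$truth$insertions[is.na(s$truth$insertions$parent), ]
  for (i in seq_len(nrow(ins))) {
    tsd_seq <- substr(as.character(orig[[ins$contig[i]]]),
                      ins$site[i] + 1L, ins$site[i] + ins$tsd[i])
    mut <- as.character(s$mutated[[ins$contig[i]]])
    left <- substr(mut, ins$block_start[i] - ins$tsd[i] + 1L, ins$block_start[i])
    right <- substr(mut, ins$block_end[i] + 1L, ins$block_end[i] + ins$tsd[i])
    expect_identical(left, tsd_seq)
    expect_identical(right, tsd_seq)
  }
})

test_that("removing each element and one TSD copy restores the original genome", {
  s <- toy_sim()
  for (ctg in names(s$mutated)) {
    mut <- as.character(s$mutated[[ctg]])
    ins <- s$truth$insertions
    ins <- ins[ins$contig == ctg & is.na(ins$parent), ]
    if (nrow(ins)) {
      ins <- ins[order(-ins$block_start), ]
      for (i in seq_len(nrow(ins)))  # excise element + left TSD copy
        mut <- paste0(substr(mut, 1L, ins$block_start[i] - ins$tsd[i]),
                      substr(mut, ins$block_end[i] + 1L, nchar(mut)))
    }
    expect_identical(mut, as.character(s$reference$genome[[ctg]]))
  }
})

test_that("nested configuration records the antisense child at the configured spacings", {
  cfg <- toy_config(seed = 11L, n_insertions = 1L, nested = TRUE)
  g <- simulate_genome(cfg)
  p <- plant_insertions(g$genome, g$annotation, cfg)
  ins <- p$truth$insertions
  child <- ins[!is.na(ins$parent), ]
  parent <- ins[is.na(ins$parent), ]
  expect_equal(nrow(child), 1L)
  expect_equal(child$gap5, 2562L)
  expect_equal(child$gap3, 1942L)
  expect_true(child$strand != parent$strand)
  # geometry on the mutated contig: distance from the end of the parent
  # 5' LTR to the child block, and from the child block to the parent 3' LTR
  ann <- g$annotation
  if (parent$strand == "+") {
    parent_5ltr_end <- parent$block_start + ann$ltr5[2]
    parent_3ltr_start <- parent$block_end - ann$ltr_length
    expect_equal(child$block_start - parent_5ltr_end, child$gap5 + child$tsd)
    expect_equal(parent_3ltr_start - child$block_end, child$gap3)
  }
})

test_that("impossible placement requests fail with a sizing error", {
  cfg <- toy_config(n_insertions = 100L)
  g <- simulate_genome(cfg)
  expect_error(plant_insertions(g$genome, g$annotation, cfg), "crowded")
})

test_that("insert sizes stay within the configured range and depth matches coverage", {
  s <- std_sim()
  fr <- s$reads$fragments
  expect_true(all(fr$insert >= 300 & fr$insert <= 700))
  # realized mean depth on a nuclear contig within 10% of nominal coverage
  lens <- vapply(names(s$reference$genome),
                 function(n) length(s$reference$genome[[n]]), 1L)
  mut_len <- length(s$mutated[["chr2"]])
  cov_ctg <- fr[fr$contig == "chr2", ]
  depth <- sum(2 * 150 * nrow(cov_ctg)) / mut_len
  expect_lt(abs(depth - 30) / 30, 0.10)
})

test_that("full conversion with an all-zero methylome reads every cytosine as T", {
  cfg <- toy_config(seed = 21L, n_insertions = 0L, conversion_failure = 0,
                    methylation_profile = list(
                      background = c(CG = 0, CHG = 0, CHH = 0),
                      pericentromere = c(CG = 0, CHG = 0, CHH = 0),
                      te = c(CG = 0, CHG = 0, CHH = 0),
                      chloroplast = c(CG = 0, CHG = 0, CHH = 0)))
  s <- simulate_sample(cfg)
  expect_true(all(!s$reads$calls$meth))
  expect_true(all(s$report_genome$count_meth == 0))
})

test_that("zero requested coverage is an error, zero reads give an all-zero report", {
  cfg <- toy_config(coverage = 0)
  g <- simulate_genome(cfg)
  p <- plant_insertions(g$genome, g$annotation, cfg)
  expect_error(simulate_emseq_reads(p$genome, p$truth, cfg), "zero fragments")
  empty <- data.table::data.table(qname = character(), mate = integer(),
                                  contig = character(), pos = integer(),
                                  strand = character(), meth = logical())
  rep0 <- emit_cytosine_report(empty, g$genome)
  expect_true(all(rep0$count_meth == 0) && all(rep0$count_unmeth == 0))
})

test_that("cytosine report totals match a brute-force tally of read sequences", {
  # independent oracle: write the paired genome alignments as SAM with
  # reconstructed read sequences, then re-count C/T (and G/A) pile-ups per
  # position from the sequences themselves over a 1 kb window
  s <- toy_sim()
  aln <- as.data.frame(s$reads$genome_aln)
  aln <- aln[aln$mode == "paired" & aln$contig == "chrC", ]
  frg <- as.data.frame(s$reads$fragments)
  rownames(frg) <- frg$qname
  chars <- strsplit(as.character(s$mutated[["chrC"]]), "")[[1]]
  calls <- as.data.frame(s$reads$calls)
  win <- c(2000L, 3000L)  # 0-based window
  cm <- integer(5000); cu <- integer(5000)  # indexed by 0-based pos + 1
  for (i in seq_len(nrow(aln))) {
    f <- frg[aln$qname[i], ]
    rs <- if (aln$mate[i] == 1L) f$r1s else f$r2s
    re <- if (aln$mate[i] == 1L) f$r1e else f$r2e
    mp <- calls$pos[calls$qname == aln$qname[i] & calls$mate == aln$mate[i] &
                      calls$meth]
    v <- chars[(rs + 1L):re]
    base <- if (f$template == "+") "C" else "G"
    idx <- which(v == base) + rs - 1L        # 0-based positions of base
    conv <- setdiff(idx, mp)                  # read as T (or A)
    # overlap bases belong to mate 1
    if (aln$mate[i] == 2L) {
      idx <- idx[idx >= max(rs, f$r1e)]
      conv <- conv[conv >= max(rs, f$r1e)]
    }
    keep <- idx >= win[1] & idx < win[2]
    for (p in idx[keep])
      if (p %in% conv) cu[p + 1L] <- cu[p + 1L] + 1L
      else cm[p + 1L] <- cm[p + 1L] + 1L
  }
  rep <- s$report_genome
  rep <- rep[rep$contig == "chrC" & rep$pos > win[1] & rep$pos <= win[2], ]
  expect_identical(cm[rep$pos], rep$count_meth)
  expect_identical(cu[rep$pos], rep$count_unmeth)
})

test_that("chloroplast weighted methylation reflects only conversion failure", {
  s <- toy_sim()
  cf <- s$config$conversion_failure
  rep <- s$report_genome
  d <- rep[rep$contig == "chrC", ]
  m <- sum(d$count_meth); tot <- m + sum(d$count_unmeth)
  # binomial interval around the conversion-failure rate at realized depth
  ci <- wilson_interval(m, tot, 0.999)
  expect_true(cf >= ci[1, "lower"] && cf <= ci[1, "upper"])
})
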