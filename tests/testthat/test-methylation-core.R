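test_that("context classification follows the CG/CHG/CHH definition", {
  expect_equal(classify_context("CGA", 1, "+"), "CG")
  expect_equal(classify_context("CAG", 1, "+"), "CHG")
  expect_equal(classify_context("CAT", 1, "+"), "CHH")
  expect_equal(classify_context("TCG", 3, "-"), "CG")
  expect_error(classify_context("ACG", 1, "+"), "cytosine")
})

test_that("minus-strand contexts agree with a reverse-complement oracle", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  gpos <- which(strsplit(seq, "")[[1]] == "G")
  gpos <- gpos[gpos >= 3 & gpos <= 298]
  got <- classify_context(seq, gpos, "-")
  # oracle: the same cytosine on the reverse complement, plus strand
  oracle <- classify_context(rc, nchar(seq) - gpos + 1L, "+")
  expect_identical(got, oracle)
})

test_that("weighted methylation is coverage-weighted, not a mean of per-site fractions", {
  rec <- data.frame(contig = "c", pos = c(1, 2), strand = "+",
                    count_meth = c(9L, 0L), count_unmeth = c(1L, 30L),
                    context = "CG", trinuc = "CGA")
  w <- weighted_methylation(rec)
  expect_equal(w$weighted_pct[w$context == "CG"], 100 * 9 / 40)  # 22.5, not 45
  # symmetric case and the all-methylated extreme
  rec2 <- data.frame(contig = "c", pos = 1:2, strand = "+",
                     count_meth = c(3L, 1L), count_unmeth = c(1L, 3L),
                     context = "CG", trinuc = "CGA")
  expect_equal(weighted_methylation(rec2)$weighted_pct[1], 50)
  rec3 <- transform(rec2, count_unmeth = 0L)
  expect_equal(weighted_methylation(rec3)$weighted_pct[1], 100)
})

test_that("zero coverage yields a flagged-undefined summary, not zero", {
  rec <- data.frame(contig = "c", pos = 1, strand = "+",
                    count_meth = 0L, count_unmeth = 0L,
                    context = "CHH", trinuc = "CTT")
  w <- weighted_methylation(rec)
  expect_true(all(is.na(w$weighted_pct)))
  expect_true(all(w$n_cytosines == 0))
})

test_that("weighted methylation is invariant to partitioning into batches", {
  set.seed(1)
  rec <- data.frame(contig = "c", pos = 1:50, strand = "+",
                    count_meth = rpois(50, 5), count_unmeth = rpois(50, 5),
                    context = sample(c("CG", "CHG", "CHH"), 50, TRUE),
                    trinuc = "NNN")
  whole <- weighted_methylation(rec)
  parts <- split(rec, rep(1:5, each = 10))
  pooled <- lapply(c("CG", "CHG", "CHH"), function(cx) {
    ms <- vapply(parts, function(p)
      weighted_methylation(p)$meth_count[weighted_methylation(p)$context == cx], 1)
    ts <- vapply(parts, function(p)
      weighted_methylation(p)$total_count[weighted_methylation(p)$context == cx], 1)
    100 * sum(ms) / sum(ts)
  })
  expect_equal(unlist(pooled), whole$weighted_pct, tolerance = 1e-12)
})

test_that("conversion rate arithmetic and error cases", {
  rec <- data.frame(contig = "chrC", pos = 1:2, strand = "+",
                    count_meth = c(1L, 0L), count_unmeth = c(499L, 500L),
                    context = "CG", trinuc = "CGA")
  expect_equal(conversion_rate(rec, "chrC"), 99.9)
  rec$count_meth <- 0L
  expect_equal(conversion_rate(rec, "chrC"), 100)
  expect_error(conversion_rate(rec, "chrM"), "absent")
})

test_that("group comparison: identical groups are not significant; BH family is the invocation", {
  set.seed(2)
  g <- data.frame(context = rep(c("CG", "CHG", "CHH"), each = 30),
                  value = runif(90))
  res <- compare_methylation(g, g)
  expect_true(all(res$p_adj >= 0.05))
  expect_false(any(res$signif))
  # a single comparison's adjusted p equals its raw p
  res1 <- compare_methylation(g, g, contexts = "CG")
  expect_equal(res1$p_adj, res1$p)
  # step-up: adjusted values equal the hand-computed BH transform
  ga <- data.frame(context = rep(c("CG", "CHG", "CHH"), each = 20),
                   value = c(runif(20, 0, 1), runif(20, 0.1, 1.1),
                             runif(20, 0.4, 1.4)))
  gb <- data.frame(context = rep(c("CG", "CHG", "CHH"), each = 20),
                   value = runif(60))
  res2 <- compare_methylation(ga, gb)
  p <- res2$p
  hand <- pmin(1, cummin((p[order(-p)] * 3 / (3:1))))[order(order(-p))]
  expect_equal(res2$p_adj, hand, tolerance = 1e-12)
})

test_that("groups with fewer than two values are flagged NA", {
  a <- data.frame(context = "CG", value = 0.5)
  b <- data.frame(context = rep("CG", 5), value = runif(5))
  res <- compare_methylation(a, b, contexts = "CG")
  expect_true(is.na(res$p))
})

test_that("Wilson interval matches the closed form and its mirror symmetry", {
  w0 <- wilson_interval(0, 10)
  expect_equal(unname(w0[1, "lower"]), 0)
  expect_equal(unname(w0[1, "upper"]), 0.2775, tolerance = 1e-3)
  w10 <- wilson_interval(10, 10)
  expect_equal(unname(w10[1, "lower"]), 0.7225, tolerance = 1e-3)
  expect_equal(unname(w10[1, "upper"]), 1)
  w5 <- wilson_interval(5, 10)
  expect_equal(unname(w5[1, "lower"] + w5[1, "upper"]), 1, tolerance = 1e-12)
  # mirror property across a sweep
  for (n in c(7, 20, 113)) {
    k <- 0:n
    a <- wilson_interval(k, n)
    b <- wilson_interval(n - k, n)
    expect_equal(a[, "lower"], 1 - b[, "upper"], tolerance = 1e-12)
  }
  expect_error(wilson_interval(1, 0), "positive")
  expect_error(wilson_interval(5, 3), "within")
})

test_that("simulated weighted methylation converges to the planted level", {
  # deep coverage on a small genome: estimates must fall inside a binomial
  # interval around the planted probabilities
  cfg <- toy_config(seed = 31L, n_insertions = 0L, coverage = 100)
  s <- simulate_sample(cfg)
  rep <- s$report_genome
  ann <- s$reference$annotation
  # background region away from the element and pericentromere
  bg <- rep[rep$contig == "chr1" & rep$pos > 16000 & rep$pos <= 28000, ]
  w <- weighted_methylation(bg)
  cf <- cfg$conversion_failure
  for (cx in c("CG", "CHG", "CHH")) {
    planted <- cfg$methylation_profile$background[[cx]] / 100
    planted <- planted + (1 - planted) * cf  # apparent level incl. failures
    row <- w[w$context == cx, ]
    ci <- wilson_interval(row$meth_count, row$total_count, 0.9999)
    expect_true(planted >= ci[1, "lower"] && planted <= ci[1, "upper"],
                label = sprintf("%s planted %.3f in [%.3f, %.3f]", cx,
                                planted, ci[1, "lower"], ci[1, "upper"]))
  }
})

test_that("cytosine report round-trips through TSV without loss", {
  s <- toy_sim()
  rep <- s$report_te
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(rep, path)
  back <- read_cytosine_report(path)
  expect_equal(back, rep)
})
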