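make_aln <- function(qname, mate, contig = "chr1", start, end, strand,
                     clip_left = 0L, clip_right = 0L, mode = "single") {
  data.table::data.table(qname = qname, mate = mate, contig = contig,
                         start = as.integer(start), end = as.integer(end),
                         strand = strand, clip_left = as.integer(clip_left),
                         clip_right = as.integer(clip_right), mode = mode)
}
make_te <- function(qname, mate, start, end, strand, clip_left = 0L,
                    clip_right = 0L) {
  data.table::data.table(qname = qname, mate = mate, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         clip_left = as.integer(clip_left),
                         clip_right = as.integer(clip_right),
                         rescued = FALSE, true_ltr = NA_character_,
                         ins_id = NA_integer_)
}

test_that("discordant pairing keeps genome/element pairs and drops dual-reference reads", {
  g <- rbind(make_aln("a", 1L, start = 100, end = 250, strand = "+"),
             make_aln("b", 1L, start = 300, end = 450, strand = "+"),
             make_aln("b", 2L, start = 700, end = 850, strand = "-"),
             make_aln("c", 1L, start = 900, end = 1050, strand = "+"))
  t <- rbind(make_te("a", 2L, 10, 160, "-"),
             make_te("c", 1L, 10, 160, "-"))  # read c mate1 on both references
  pairs <- find_discordant(g, t)
  expect_equal(pairs$qname, "a")
  lg <- attr(pairs, "log")
  expect_equal(lg$n_discarded_both_refs, 1L)  # whole pair c discarded
  expect_gte(lg$n_skipped_unpaired, 1L)       # b: both mates on genome
})

test_that("clustering groups by proximity and never across contigs", {
  p <- data.table::data.table(
    qname = sprintf("r%d", 1:9),
    contig = c(rep("chr1", 8), "chr2"),
    g_start = c(0, 100, 200, 300, 400, 500, 2000, 2100, 2100),
    g_end = c(0, 100, 200, 300, 400, 500, 2000, 2100, 2100) + 150,
    g_strand = "+", g_mate = 1L, clip_left = 0L, clip_right = 0L,
    te_start = 0L, te_end = 150L, te_strand = "-")
  cl <- cluster_reads(p, max_gap = 700)
  expect_equal(cl[cl$contig == "chr1" & cl$g_start <= 500, ]$cluster,
               rep(1L, 6))
  expect_equal(unique(cl[cl$g_start >= 2000 & cl$contig == "chr1", ]$cluster), 2L)
  expect_equal(unique(cl[cl$contig == "chr2", ]$cluster), 3L)
})

test_that("cluster validation enforces the m>=3 / n>=3 single-switch rule", {
  v <- validate_cluster(make_cluster(1:6 * 100, c("+", "+", "+", "-", "-", "-")))
  expect_true(v$valid); expect_equal(c(v$m, v$n), c(3L, 3L))
  expect_false(validate_cluster(
    make_cluster(1:7 * 100, c("+", "+", rep("-", 5))))$valid)  # (2,5)
  expect_false(validate_cluster(
    make_cluster(1:6 * 100, c("+", "-", "+", "-", "+", "-")))$valid)
  expect_false(validate_cluster(  # reversed directionality
    make_cluster(1:6 * 100, c("-", "-", "-", "+", "+", "+")))$valid)
})

test_that("cluster validity agrees with a brute-force split enumeration", {
  oracle <- function(dir, min_m = 3, min_n = 3) {
    n <- length(dir)
    any(vapply(min_m:(n - min_n), function(k)
      all(dir[1:k]) && all(!dir[(k + 1):n]), TRUE))
  }
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(6:12, 1)
    dir <- sample(c(TRUE, FALSE), n, replace = TRUE)
    cl <- make_cluster(seq_len(n) * 100, ifelse(dir, "+", "-"))
    expect_equal(validate_cluster(cl)$valid, oracle(dir),
                 label = paste(dir, collapse = ""))
  }
})

test_that("site inference interval arithmetic, including overlapping boundaries", {
  cl <- make_cluster(c(100, 200, 850, 1005, 1100, 1200),
                     c("+", "+", "+", "-", "-", "-"))
  cl$g_end <- cl$g_start + 150L
  cl$g_end[3] <- 1000L
  s <- infer_site(cl)
  expect_equal(s$end_mth, 1000L); expect_equal(s$start_m1, 1005L)
  expect_equal(s$overlap, 0L)
  cl$g_start[4] <- 995L
  s2 <- infer_site(cl)
  expect_equal(s2$overlap, 5L)
  expect_equal(c(s2$site_lo, s2$site_hi), c(995L, 1000L))
})

test_that("TSD detection requires the boundary soft-clip pattern", {
  cl <- make_cluster(c(100, 200, 870, 995, 1100, 1200),
                     c("+", "+", "+", "-", "-", "-"))
  cl$g_end <- cl$g_start + 150L
  cl$g_end[3] <- 1000L
  # no soft clips on the boundary reads -> no TSD even with overlap
  expect_true(is.na(detect_tsd(cl)))
  cl$clip_right[3] <- 20L
  cl$clip_left[4] <- 20L
  expect_equal(detect_tsd(cl), 5L)
  # an 8 bp overlap gives an 8 bp TSD
  cl$g_start[4] <- 992L
  expect_equal(detect_tsd(cl), 8L)
})

test_that("strand and LTR-of-origin follow mate orientation in all four cases", {
  up <- c("+", "+", "+"); down <- c("-", "-", "-")
  # sense insertion: upstream mates on element minus strand (5' LTR)
  sense <- make_cluster(1:6 * 100, c(up, down),
                        te_strands = c("-", "-", "-", "+", "+", "+"))
  r <- infer_strand_and_ltr(sense)
  expect_equal(r$strand, "+")
  expect_equal(r$labels$ltr, c("5p", "5p", "5p", "3p", "3p", "3p"))
  # antisense: element strands swapped
  anti <- make_cluster(1:6 * 100, c(up, down),
                       te_strands = c("+", "+", "+", "-", "-", "-"))
  r2 <- infer_strand_and_ltr(anti)
  expect_equal(r2$strand, "-")
  expect_equal(r2$labels$ltr, c("3p", "3p", "3p", "5p", "5p", "5p"))
  # mixed orientations within a border are ambiguous
  mix <- make_cluster(1:6 * 100, c(up, down),
                      te_strands = c("-", "+", "-", "+", "+", "+"))
  r3 <- infer_strand_and_ltr(mix)
  expect_equal(r3$strand, "ambiguous")
  expect_true(all(is.na(r3$labels$ltr)))
})

test_that("calls on simulated data match planted truth against relabeled strands and LTRs", {
  s <- std_sim()
  res <- std_calls()
  truth <- s$truth$insertions[is.na(s$truth$insertions$parent), ]
  for (i in seq_len(nrow(res$calls))) {
    tm <- truth[truth$contig == res$calls$contig[i] &
                  abs(truth$site - res$calls$site[i]) < 500, ]
    expect_equal(nrow(tm), 1L)
    expect_equal(res$calls$strand[i], tm$strand)
  }
  # inferred site interval contains the planted site for every call
  hits <- vapply(seq_len(nrow(res$calls)), function(i) {
    tm <- truth[truth$contig == res$calls$contig[i] &
                  abs(truth$site - res$calls$site[i]) < 500, ]
    res$calls$site_lo[i] <= tm$site && tm$site <= res$calls$site_hi[i]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("location classification uses the pericentromere intervals", {
  peri <- data.frame(contig = "chr1", start = 0L, end = 1000L)
  calls <- data.frame(contig = c("chr1", "chr1", "chr5"),
                      site = c(500L, 1500L, 500L))
  expect_equal(classify_location(calls, peri),
               c("pericentromeric", "arm", "arm"))
  # 3 arm calls of 4 -> 75% arm
  calls4 <- data.frame(contig = "chr1", site = c(100L, 2000L, 3000L, 4000L))
  loc <- classify_location(calls4, peri)
  expect_equal(mean(loc == "arm"), 0.75)
})

test_that("per-border support filter sits exactly at the documented threshold", {
  calls <- data.frame(call_id = 1:4, m = c(3L, 2L, 4L, 5L),
                      n = c(3L, 4L, 2L, 7L))
  kept <- filter_calls(calls)
  expect_equal(kept$call_id, c(1L, 4L))
  expect_equal(nrow(filter_calls(calls[0, ])), 0L)
})

test_that("nested screen thresholds: N / y / Y", {
  ann <- std_sim()$reference$annotation
  l5 <- ann$ltr5; l3 <- ann$ltr3
  # two same-strand pairs at each LTR -> Y
  t_y <- rbind(
    make_te("p1", 1L, l5[1] + 10, l5[1] + 160, "+"),
    make_te("p1", 2L, l5[2] + 200, l5[2] + 350, "+"),
    make_te("p2", 1L, l5[1] + 30, l5[1] + 180, "+"),
    make_te("p2", 2L, l5[2] + 260, l5[2] + 410, "+"),
    make_te("p3", 1L, l3[1] + 10, l3[1] + 160, "-"),
    make_te("p3", 2L, l3[1] - 300, l3[1] - 150, "-"),
    make_te("p4", 1L, l3[1] + 40, l3[1] + 190, "-"),
    make_te("p4", 2L, l3[1] - 350, l3[1] - 200, "-"))
  expect_equal(find_nested(t_y, ann)$status, "Y")
  # a single qualifying mate at one LTR -> y
  t_1 <- rbind(make_te("p1", 1L, l5[1] + 10, l5[1] + 160, "+"),
               make_te("p1", 2L, l5[2] + 200, l5[2] + 350, "+"))
  expect_equal(find_nested(t_1, ann)$status, "y")
  # opposite-orientation (concordant) pairs are not evidence
  t_0 <- rbind(make_te("p1", 1L, l5[1] + 10, l5[1] + 160, "+"),
               make_te("p1", 2L, l5[2] + 200, l5[2] + 350, "-"))
  expect_equal(find_nested(t_0, ann)$status, "N")
})

test_that("a planted nested insertion is detected and controls stay clean", {
  s <- std_sim()
  ann <- s$reference$annotation
  cfg <- sim_config(seed = 11L, n_insertions = 2L, nested = TRUE)
  sn <- simulate_sample(cfg, genome = s$reference)
  expect_equal(find_nested(sn$reads$te_aln, ann)$status, "Y")
  expect_equal(find_nested(s$reads$te_aln, ann)$status, "N")
})

test_that("hairpin screen requires same-orientation LTR mates within the insert size", {
  ann <- std_sim()$reference$annotation
  l5 <- ann$ltr5
  near <- rbind(make_te("h1", 1L, l5[1] + 10, l5[1] + 160, "+"),
                make_te("h1", 2L, l5[1] + 260, l5[1] + 410, "+"))
  expect_equal(unique(find_hairpins(near, ann)$qname), "h1")
  # same orientation but 2 kb apart: beyond the library insert size
  far <- rbind(make_te("h2", 1L, 10, 160, "+"),
               make_te("h2", 2L, ann$ltr3[1] + 60, ann$ltr3[1] + 210, "+"))
  expect_equal(nrow(find_hairpins(far, ann)), 0L)
  # opposite orientation mates are concordant, not hairpin evidence
  conc <- rbind(make_te("h3", 1L, l5[1] + 10, l5[1] + 160, "+"),
                make_te("h3", 2L, l5[1] + 260, l5[1] + 410, "-"))
  expect_equal(nrow(find_hairpins(conc, ann)), 0L)
})

test_that("a two-insertion cluster is split at the direction switch", {
  cl <- make_cluster(c(1:6 * 100, 1:6 * 100 + 900),
                     rep(c("+", "+", "+", "-", "-", "-"), 2))
  cl$qname <- sprintf("r%02d", 1:12)
  g <- cl[, c("qname", "contig", "g_start", "g_end", "g_strand", "clip_left",
              "clip_right")]
  data.table::setnames(g, c("g_start", "g_end", "g_strand"),
                       c("start", "end", "strand"))
  g$mate <- 1L; g$mode <- "single"
  t <- make_te(cl$qname, 2L, 10, 160, ifelse(cl$g_strand == "+", "-", "+"))
  res <- call_insertions(g, t, split_ambiguous = TRUE)
  expect_equal(nrow(res$calls), 2L)
  res0 <- call_insertions(g, t, split_ambiguous = FALSE)
  expect_equal(nrow(res0$calls), 0L)
})
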