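#' Identify polymorphic insertion sites informative for landing-site state
#'
#' The methylation state of a landing site before transposition can only be
#' read from individuals of the same genotype that do not carry the
#' insertion. Calls from all samples are therefore grouped into sites (calls
#' within `tol` bp on the same contig are considered the same insertion);
#' sites present in every sequenced sample (fixed) are discarded, and for
#' each remaining site the same-genotype non-carriers form the informative
#' set. A site whose genotype offers no non-carrier (e.g. a genotype with a
#' single sample) is non-informative and dropped with a log count.
#'
#' @param calls_by_sample data.frame of calls across samples: columns
#'   `sample_id`, `contig`, `site` (0-based midpoint).
#' @param sample_info data.frame: `sample_id`, `genotype`, and optionally
#'   `status` (e.g. element activity), covering every sequenced sample.
#' @param tol maximum distance (bp) between calls treated as one site.
#' @return data.table with one row per informative site: `site_id`,
#'   `contig`, `site` (median midpoint), `carriers` and `informative`
#'   (list columns of sample ids), `genotype`; attribute `log` carries the
#'   number of fixed and non-informative sites dropped.
#' @export
polymorphic_sites <- function(calls_by_sample, sample_info, tol = 100L) {
  dt <- as.data.table(calls_by_sample)
  info <- as.data.table(sample_info)
  stopifnot(all(dt$sample_id %in% info$sample_id))
  all_samples <- info$sample_id
  setorder(dt, contig, site)
  newg <- c(TRUE, dt$contig[-1] != dt$contig[-nrow(dt)] |
              diff(dt$site) > tol)
  dt[, site_id := cumsum(newg)]
  n_fixed <- 0L; n_noninf <- 0L
  out <- list()
  for (g in split(dt, by = "site_id")) {
    carriers <- unique(g$sample_id)
    if (length(carriers) == length(all_samples)) {  # fixed insertion
      n_fixed <- n_fixed + 1L
      next
    }
    genos <- unique(info[sample_id %in% carriers, genotype])
    informative <- info[genotype %in% genos & !sample_id %in% carriers,
                        sample_id]
    if (!length(informative)) {
      n_noninf <- n_noninf + 1L
      next
    }
    out[[length(out) + 1L]] <- data.table(
      site_id = g$site_id[1], contig = g$contig[1],
      site = as.integer(stats::median(g$site)),
      carriers = list(carriers), informative = list(informative),
      genotype = paste(sort(genos), collapse = ","))
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(site_id = integer(), contig = character(), site = integer(),
               carriers = list(), informative = list(), genotype = character())
  setattr(res, "log", list(n_fixed = n_fixed, n_noninformative = n_noninf))
  res[]
}

#' Pre-insertion methylation of a landing site
#'
#' Pools cytosine counts from the informative (non-carrier) samples over a
#' window centered on the site and returns the weighted methylation per
#' context. Pooling sums counts first (so two samples pooled equal their
#' summed reports), never averages per-sample percentages.
#'
#' @param contig,site site location (0-based position on the reference
#'   genome).
#' @param reports named list of cytosine report data.frames, one per
#'   informative sample.
#' @param window half-window (bp); the site interval is
#'   `[site - window, site + window]`.
#' @return data.frame per context with `weighted_pct` (`NA` and flagged when
#'   the window has zero coverage), counts and `n_cytosines`.
#' @export
preinsertion_methylation <- function(contig, site, reports, window = 200L) {
  stopifnot(window > 0L, length(reports) >= 1L)
  pooled <- rbindlist(lapply(reports, as.data.table))
  ctg <- contig
  pooled <- pooled[pooled$contig == ctg &
                     pos >= site + 1L - window & pos <= site + 1L + window]
  weighted_methylation(pooled)
}

#' Classify a landing site's methylation state
#'
#' Applies the 10% rules: unmethylated when all three contexts are below
#' 10%, mCG-only when CG exceeds 10% with CHG and CHH below, and non-CG
#' methylated when CHG or CHH exceeds 10%. Values exactly at the threshold
#' fall to the less-methylated side and are flagged borderline. Every
#' percentage triple maps to exactly one class.
#'
#' @param cg,chg,chh methylation percentages (vectorized).
#' @param threshold class boundary in percent (default 10).
#' @return data.frame with `class` (`"unmethylated"`, `"mCG_only"`,
#'   `"nonCG"`) and logical `borderline`.
#' @export
classify_site <- function(cg, chg, chh, threshold = 10) {
  if (any(is.na(c(cg, chg, chh))))
    stop("percentages must be defined; unclassifiable sites should be ",
         "flagged upstream")
  high_cg <- cg > threshold
  high_chg <- chg > threshold
  high_chh <- chh > threshold
  cls <- ifelse(high_chg | high_chh, "nonCG",
                ifelse(high_cg, "mCG_only", "unmethylated"))
  data.frame(class = cls,
             borderline = cg == threshold | chg == threshold |
               chh == threshold)
}

#' Assign a silencing-pathway label to non-CG methylated sites
#'
#' Overlaps the site window with an external pathway annotation (intervals
#' labelled `RdDM` or `CMT2`, e.g. derived from mutant methylome panels) and
#' labels the site by the first matching pathway, `RdDM` taking precedence
#' when the window overlaps both; sites overlapping neither are
#' `"independent"`.
#'
#' @param contig,site site location (0-based).
#' @param pathway_bed data.frame: `contig`, `start`, `end` (0-based
#'   half-open), `name` (`"RdDM"`/`"CMT2"`).
#' @param window half-window used for the overlap rule (any overlap counts).
#' @return `"RdDM"`, `"CMT2"` or `"independent"`.
#' @export
classify_pathway <- function(contig, site, pathway_bed, window = 200L) {
  if (is.null(pathway_bed) || nrow(pathway_bed) == 0L) return("independent")
  bed <- as.data.frame(pathway_bed)
  lo <- site - window; hi <- site + window
  hit <- bed$contig == contig & bed$start < hi & lo < bed$end
  labs <- unique(bed$name[hit])
  if ("RdDM" %in% labs) "RdDM"
  else if ("CMT2" %in% labs) "CMT2"
  else "independent"
}

#' Classify all informative landing sites of a cohort
#'
#' Combines [polymorphic_sites()], [preinsertion_methylation()],
#' [classify_site()] and [classify_pathway()] into the landing-site record
#' table, and tabulates class counts (the pie-chart table).
#'
#' @param calls_by_sample,sample_info see [polymorphic_sites()].
#' @param reports named list of genome cytosine reports for every sample.
#' @param pathway_bed optional pathway annotation (see [classify_pathway()]).
#' @param window half-window (bp) for the pre-insertion state.
#' @param threshold class boundary in percent.
#' @return list with `records` (one row per site: location, carriers,
#'   per-context pre-insertion percentages, `class`, `borderline`,
#'   `pathway`) and `class_counts`.
#' @export
landing_site_classify <- function(calls_by_sample, sample_info, reports,
                                  pathway_bed = NULL, window = 200L,
                                  threshold = 10) {
  sites <- polymorphic_sites(calls_by_sample, sample_info)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    inf_samples <- sites$informative[[i]]
    m <- preinsertion_methylation(sites$contig[i], sites$site[i],
                                  reports[inf_samples], window = window)
    pct <- setNames(m$weighted_pct, m$context)
    if (any(is.na(pct))) {
      rows[[i]] <- data.table(sites[i, .(site_id, contig, site, genotype)],
                              CG = pct[["CG"]], CHG = pct[["CHG"]],
                              CHH = pct[["CHH"]], class = NA_character_,
                              borderline = NA, pathway = NA_character_)
      next
    }
    cl <- classify_site(pct[["CG"]], pct[["CHG"]], pct[["CHH"]], threshold)
    pw <- if (cl$class == "nonCG")
      classify_pathway(sites$contig[i], sites$site[i], pathway_bed, window)
      else NA_character_
    rows[[i]] <- data.table(sites[i, .(site_id, contig, site, genotype)],
                            CG = pct[["CG"]], CHG = pct[["CHG"]],
                            CHH = pct[["CHH"]], class = cl$class,
                            borderline = cl$borderline, pathway = pw)
  }
  records <- if (length(rows)) rbindlist(rows) else
    data.table(site_id = integer(), contig = character(), site = integer(),
               genotype = character(), CG = numeric(), CHG = numeric(),
               CHH = numeric(), class = character(), borderline = logical(),
               pathway = character())
  records[, `:=`(carriers = sites$carriers, informative = sites$informative)]
  counts <- records[!is.na(class), .N, by = class]
  list(records = records[], class_counts = counts[])
}

#' Metaplot of the methylation shift around insertion sites
#'
#' For each informative site, the difference in weighted methylation
#' (carriers minus non-carriers, pooled counts on each side) is computed per
#' distance bin and context over a window around the insertion point, on the
#' insertion-free (reference) coordinate system — element-internal bases do
#' not exist on this frame, so only flanking sequence contributes. Bin
#' shifts are then averaged over sites within each sample group.
#'
#' @param sites output of [polymorphic_sites()] (or the `records` of
#'   [landing_site_classify()], which carries the same columns).
#' @param reports named list of genome cytosine reports for every sample.
#' @param sample_info data.frame `sample_id`, `genotype`, `status`; the
#'   group label of a site is the genotype x status of its carriers.
#' @param window half-window (bp).
#' @param bin bin width (bp).
#' @return data.table: `bin_mid` (signed distance from the site), `context`,
#'   `group`, `mean_shift` (percentage points), `n_sites` (sites
#'   contributing; bins with no coverage on either side are `NA` and
#'   excluded from the mean).
#' @export
methylation_shift_metaplot <- function(sites, reports, sample_info,
                                       window = 2000L, bin = 50L) {
  stopifnot(nrow(sites) >= 1L, bin >= 1L)
  info <- as.data.table(sample_info)
  edges <- seq(-window, window, by = bin)
  out <- list()
  for (i in seq_len(nrow(sites))) {
    carriers <- sites$carriers[[i]]
    noncarr <- sites$informative[[i]]
    grp <- paste(sort(unique(info[sample_id %in% carriers,
                                  paste(genotype, status, sep = ":")])),
                 collapse = ";")
    pool <- function(samples) {
      dt <- rbindlist(lapply(reports[samples], as.data.table))
      ctg <- sites$contig[i]
      dt <- dt[dt$contig == ctg]
      dt[, rel := pos - 1L - sites$site[i]]
      dt[rel >= -window & rel < window]
    }
    shift_one <- function(ca, nc) {
      ca[, b := findInterval(rel, edges)]
      nc[, b := findInterval(rel, edges)]
      a <- ca[, .(m = sum(count_meth), t = sum(count_meth + count_unmeth)),
              by = .(b, context)]
      b2 <- nc[, .(m = sum(count_meth), t = sum(count_meth + count_unmeth)),
               by = .(b, context)]
      mm <- merge(a, b2, by = c("b", "context"), all = TRUE,
                  suffixes = c("_ca", "_nc"))
      mm[, shift := ifelse(!is.na(t_ca) & t_ca > 0 & !is.na(t_nc) & t_nc > 0,
                           100 * m_ca / t_ca - 100 * m_nc / t_nc, NA_real_)]
      mm
    }
    mm <- shift_one(pool(carriers), pool(noncarr))
    mm[, `:=`(site_id = sites$site_id[i], group = grp)]
    out[[i]] <- mm
  }
  all <- rbindlist(out)
  res <- all[!is.na(shift),
             .(mean_shift = mean(shift), sd_shift = stats::sd(shift),
               n_sites = .N),
             by = .(b, context, group)]
  res[, bin_mid := edges[b] + bin / 2]
  setorder(res, group, context, bin_mid)
  res[, b := NULL]
  res[]
}
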