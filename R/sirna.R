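# 24-nt siRNA cluster calling, 150-bp merging, RPM normalisation,
# differential clusters, and TE-overlap summaries.

#' Call 24-nt siRNA clusters from read placements
#'
#' Builds maximal chains of 24-bp reads in which consecutive reads are
#' separated by at most `link_gap` bp (gap = next start - previous end, in
#' 0-based half-open coordinates); chains with at least `min_reads` reads
#' are reported, spanning the union of their member reads. Reads that are
#' not exactly 24 bp are rejected with a message.
#'
#' @param reads BED-like data.table: chrom, start, end (0-based
#'   half-open).
#' @param min_reads Minimum reads per cluster (default 10).
#' @param link_gap Maximum gap linking consecutive reads into a chain
#'   (default 75).
#' @return data.table: chrom, start, end, read_count.
#' @export
call_clusters <- function(reads, min_reads = 10L, link_gap = 75L) {
  dt <- data.table::as.data.table(reads)
  bad <- dt$end - dt$start != 24L
  if (any(bad)) {
    message(sum(bad), " non-24-nt read(s) rejected")
    dt <- dt[!bad]
  }
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), read_count = integer()))
  data.table::setorder(dt, chrom, start)
  out <- dt[, {
    gap_break <- c(FALSE, start[-1L] - cummax(end[-.N]) > link_gap)
    cid <- cumsum(gap_break)
    data.table::data.table(start = start, end = end, cid = cid)[
      , .(start = min(start), end = max(end), read_count = .N), by = cid]
  }, by = chrom]
  out <- out[read_count >= min_reads]
  out[, cid := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Merge nearby siRNA clusters into loci
#'
#' Clusters separated by a gap of at most `merge_distance` bp (inclusive)
#' are merged; read counts are summed. The result is pairwise disjoint
#' with all gaps > `merge_distance`; merging is idempotent.
#'
#' @param clusters Output of [call_clusters()] (needs chrom, start, end,
#'   read_count).
#' @param merge_distance Maximum gap merged (default 150).
#' @return data.table of siRNA loci: chrom, start, end, read_count.
#' @export
merge_clusters <- function(clusters, merge_distance = 150L) {
  dt <- data.table::as.data.table(clusters)
  if (nrow(dt) == 0L) return(dt)
  data.table::setorder(dt, chrom, start)
  out <- dt[, {
    gap_break <- c(FALSE, start[-1L] - cummax(end[-.N]) > merge_distance)
    cid <- cumsum(gap_break)
    data.table::data.table(start, end, read_count, cid)[
      , .(start = min(start), end = max(end),
          read_count = sum(read_count)), by = cid]
  }, by = chrom]
  out[, cid := NULL]
  data.table::setorder(out, chrom, start)
  out[]
}

#' Reads-per-million normalisation
#'
#' @param count Read count(s) in a locus.
#' @param library_total Total mapped reads of the library (> 0).
#' @return `count * 1e6 / library_total`.
#' @export
rpm <- function(count, library_total) {
  stopifnot(all(library_total > 0))
  count * 1e6 / library_total
}

#' Differential siRNA locus between two libraries
#'
#' Fold change is computed on RPM with a 1-RPM pseudocount,
#' `log2((rpm_treat + c) / (rpm_ctrl + c))`, so fully silenced loci remain
#' representable; the p-value is a two-sided Fisher exact test of the
#' locus count against the rest of each library. Significant loci satisfy
#' `|log2fc| >= lfc_min` and `p < alpha`.
#'
#' @param count_ctrl,count_treat Locus read counts per group.
#' @param total_ctrl,total_treat Library totals.
#' @param pseudo_rpm Pseudocount in RPM units (default 1).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param alpha Significance threshold (default 0.05).
#' @return data.table: rpm_ctrl, rpm_treat, log2fc, p_diff, significant.
#' @export
differential_cluster <- function(count_ctrl, count_treat, total_ctrl,
                                 total_treat, pseudo_rpm = 1, lfc_min = 1,
                                 alpha = 0.05) {
  r_c <- rpm(count_ctrl, total_ctrl)
  r_t <- rpm(count_treat, total_treat)
  lfc <- log2((r_t + pseudo_rpm) / (r_c + pseudo_rpm))
  p <- .fisher2x2(count_ctrl, total_ctrl - count_ctrl,
                  count_treat, total_treat - count_treat)
  data.table::data.table(rpm_ctrl = r_c, rpm_treat = r_t, log2fc = lfc,
                         p_diff = p,
                         significant = abs(lfc) >= lfc_min & p < alpha)
}

#' Transposable-element overlap of siRNA loci
#'
#' Flags each locus that intersects a TE interval by at least 1 bp
#' (half-open coordinates) and, when genic intervals are supplied,
#' summarises the TE-overlap fraction within genic vs intergenic strata
#' (a locus is genic if it overlaps any gene).
#'
#' @param loci,te_intervals,genic_intervals BED-like data.tables (chrom,
#'   start, end, 0-based half-open); `genic_intervals` optional.
#' @return List with `loci` (input + `te_overlap` and, when available,
#'   `genic` flags) and `summary` (stratum, n, fraction_te).
#' @export
te_overlap <- function(loci, te_intervals, genic_intervals = NULL) {
  l <- data.table::as.data.table(loci)
  overlaps_any <- function(a, b) {
    if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
    ga <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1L, a$end))
    gb <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
    GenomicRanges::countOverlaps(ga, gb) > 0L
  }
  l[, te_overlap := overlaps_any(l, data.table::as.data.table(te_intervals))]
  if (!is.null(genic_intervals)) {
    l[, genic := overlaps_any(l,
                              data.table::as.data.table(genic_intervals))]
    summ <- l[, .(n = .N, fraction_te = mean(te_overlap)),
              by = .(stratum = ifelse(genic, "genic", "intergenic"))]
  } else {
    summ <- l[, .(stratum = "all", n = .N, fraction_te = mean(te_overlap))]
  }
  list(loci = l[], summary = summ[])
}
utils::globalVariables(c("cid", "read_count", "te_overlap", "genic"))
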