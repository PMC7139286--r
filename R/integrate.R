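# Interval arithmetic over DMRs and genomic elements, and meta-feature
# methylation profiles.

#' All overlapping pairs between two interval sets
#'
#' Returns every pair of intervals from `a` and `b` with at least 1 bp
#' intersection under 0-based half-open coordinates, with the overlap
#' length.
#'
#' @param a,b data.tables with chrom, start, end (0-based half-open);
#'   additional columns are preserved with `a.`/`b.` prefixes on index.
#' @return data.table: a_idx, b_idx, overlap_bp.
#' @export
intersect_intervals <- function(a, b) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.table::data.table(a_idx = integer(), b_idx = integer(),
                                  overlap_bp = integer()))
  ga <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$start + 1L, a$end))
  gb <- GenomicRanges::GRanges(b$chrom,
                               IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  out <- data.table::data.table(a_idx = qi, b_idx = si, overlap_bp = ov)
  data.table::setorder(out, a_idx, b_idx)
  out[]
}

#' Annotate DMRs with overlapping genomic elements
#'
#' A feature lies "within" a DMR when they intersect by at least 1 bp
#' (partial overlap counts). Each DMR is classified by the kinds of
#' gene/lncRNA/siRNA elements it touches: `single_gene`, `single_lncRNA`,
#' `single_siRNA` (exactly one such element), `gene_plus_siRNA`,
#' `lncRNA_plus_siRNA`, `other_multi`, or `none`. TE overlaps are recorded
#' but do not enter the class.
#'
#' @param dmrs data.table with chrom, start, end (0-based half-open).
#' @param features data.table with feature_id, kind (`gene`, `lncRNA`,
#'   `siRNA_locus`, `TE`), chrom, start, end.
#' @return List with `overlaps` (dmr_idx, feature_id, kind, overlap_bp)
#'   and `annotations` (per DMR: counts by kind and element_class).
#' @export
annotate_dmrs <- function(dmrs, features) {
  dmrs <- data.table::as.data.table(dmrs)
  features <- data.table::as.data.table(features)
  pairs <- intersect_intervals(dmrs, features)
  overlaps <- data.table::data.table(
    dmr_idx = pairs$a_idx,
    feature_id = features$feature_id[pairs$b_idx],
    kind = features$kind[pairs$b_idx],
    overlap_bp = pairs$overlap_bp
  )
  counts <- data.table::dcast(
    overlaps[, .N, by = .(dmr_idx, kind)],
    dmr_idx ~ factor(kind, levels = c("gene", "lncRNA", "siRNA_locus",
                                      "TE")),
    value.var = "N", fill = 0L, drop = FALSE)
  ann <- data.table::data.table(dmr_idx = seq_len(nrow(dmrs)))
  ann <- merge(ann, counts, by = "dmr_idx", all.x = TRUE)
  for (cl in c("gene", "lncRNA", "siRNA_locus", "TE")) {
    if (!cl %in% names(ann)) ann[, (cl) := 0L]
    data.table::set(ann, which(is.na(ann[[cl]])), cl, 0L)
  }
  ann[, element_class := {
    ng <- gene; nl <- lncRNA; ns <- siRNA_locus
    tot <- ng + nl + ns
    data.table::fcase(
      tot == 0L, "none",
      tot == 1L & ng == 1L, "single_gene",
      tot == 1L & nl == 1L, "single_lncRNA",
      tot == 1L & ns == 1L, "single_siRNA",
      ng >= 1L & ns >= 1L & nl == 0L, "gene_plus_siRNA",
      nl >= 1L & ns >= 1L & ng == 0L, "lncRNA_plus_siRNA",
      default = "other_multi"
    )
  }]
  list(overlaps = overlaps, annotations = ann[])
}

#' Meta-feature methylation profile
#'
#' Averages methylation levels over strand-oriented bins spanning an
#' upstream flank, the feature body, and a downstream flank. Bin means are
#' coverage-weighted (pooled mC over pooled coverage).
#'
#' @param features data.table: chrom, start, end (0-based half-open),
#'   strand.
#' @param records Cytosine records (chrom, pos, mC, umC); samples pooled.
#' @param flank_bp Flank size in bp (default 2000).
#' @param body_bins Number of body bins (default 20).
#' @param flank_bins Number of bins per flank (default 10).
#' @return data.table: region (`upstream`, `body`, `downstream`),
#'   bin (1-based within region, 5' to 3'), mean_ML, coverage.
#' @export
methylation_profile <- function(features, records, flank_bp = 2000L,
                                body_bins = 20L, flank_bins = 10L) {
  feats <- data.table::as.data.table(features)
  recs <- data.table::as.data.table(records)[
    , .(mC = sum(mC), umC = sum(umC)), by = .(chrom, pos)]
  acc <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i]
    lo <- f$start - flank_bp; hi <- f$end + flank_bp
    r <- recs[chrom == f$chrom & pos > lo & pos <= hi]
    if (nrow(r) == 0L) next
    q <- r$pos - 1L  # 0-based
    upstream <- q < f$start; downstream <- q >= f$end
    body <- !upstream & !downstream
    region <- ifelse(upstream, "upstream", ifelse(body, "body",
                                                  "downstream"))
    bin <- integer(nrow(r))
    bin[upstream] <- pmin(flank_bins, 1L + as.integer(
      (q[upstream] - lo) * flank_bins / flank_bp))
    bin[body] <- pmin(body_bins, 1L + as.integer(
      (q[body] - f$start) * body_bins / (f$end - f$start)))
    bin[downstream] <- pmin(flank_bins, 1L + as.integer(
      (q[downstream] - f$end) * flank_bins / flank_bp))
    if (f$strand == "-") {  # mirror to 5'->3'
      region <- c(upstream = "downstream", body = "body",
                  downstream = "upstream")[region]
      bin <- ifelse(region == "body", body_bins + 1L - bin,
                    flank_bins + 1L - bin)
    }
    acc[[length(acc) + 1L]] <- data.table::data.table(
      region = region, bin = bin, mC = r$mC, umC = r$umC)
  }
  if (length(acc) == 0L)
    return(data.table::data.table(region = character(), bin = integer(),
                                  mean_ML = numeric(),
                                  coverage = integer()))
  dt <- data.table::rbindlist(acc)
  out <- dt[, .(mean_ML = sum(mC) / sum(mC + umC),
                coverage = sum(mC + umC)), by = .(region, bin)]
  out[, region := factor(region, levels = c("upstream", "body",
                                            "downstream"))]
  data.table::setorder(out, region, bin)
  out[]
}
utils::globalVariables(c("dmr_idx", "kind", "element_class", "gene",
                         "lncRNA", "siRNA_locus", "TE", "region"))
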