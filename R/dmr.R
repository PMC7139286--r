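# DMR calling: 1-kb sliding windows at 100-bp steps, group-pooled Fisher
# exact test per window, merging of significant windows into regions, and a
# per-region ANOVA confirmation on per-site methylation levels.

# Exact two-sided Fisher p for many 2x2 tables [[a,b],[c,d]], using the
# minimum-likelihood rule (sum of hypergeometric probabilities not
# exceeding the observed one, with the same 1e-7 relative tolerance as
# stats::fisher.test). Dramatically faster than per-table fisher.test for
# thousands of tables with large margins.
.fisher2x2 <- function(a, b, c, d) {
  n_tab <- length(a)
  p <- numeric(n_tab)
  for (i in seq_len(n_tab)) {
    m <- a[i] + b[i]; nn <- c[i] + d[i]; k <- a[i] + c[i]
    if (m + nn == 0L || k == 0L || k == m + nn) { p[i] <- 1; next }
    lo <- max(0L, k - nn); hi <- min(k, m)
    dens <- stats::dhyper(lo:hi, m, nn, k)
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)]))
  }
  p
}

# Pool two-group cytosine records per site; a site is eligible when BOTH
# groups reach min_cov pooled coverage (eligibility must agree across
# groups for the per-site ANOVA downstream).
.pool_sites <- function(records, min_cov = 5L) {
  dt <- data.table::as.data.table(records)
  pooled <- dt[, .(mC = sum(mC), umC = sum(umC)), by = .(chrom, pos, group)]
  wide <- data.table::dcast(pooled, chrom + pos ~ group,
                            value.var = c("mC", "umC"), fill = 0L)
  for (cl in c("mC_ctrl", "umC_ctrl", "mC_treat", "umC_treat"))
    if (!cl %in% names(wide)) wide[, (cl) := 0L]
  wide[, eligible := (mC_ctrl + umC_ctrl) >= min_cov &
         (mC_treat + umC_treat) >= min_cov]
  data.table::setorder(wide, chrom, pos)
  wide
}

#' Enumerate sliding windows with group-pooled methylation counts
#'
#' Scans each chromosome in fixed-size windows advanced by a fixed step and
#' pools methylated/unmethylated counts per group over eligible sites
#' (pooled coverage >= `min_cov` in both groups). Only windows containing
#' at least one eligible site are returned.
#'
#' @param records Two-group cytosine records (chrom, pos, strand, mC, umC,
#'   sample_id, group with levels `ctrl`/`treat`), sorted by (chrom, pos).
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default 100); must divide `window`.
#' @param min_cov Per-group pooled coverage floor per site (default 5).
#' @return data.table: chrom, start, end (0-based half-open), n_sites, and
#'   pooled `mC_ctrl`, `umC_ctrl`, `mC_treat`, `umC_treat`.
#' @export
enumerate_windows <- function(records, window = 1000L, step = 100L,
                              min_cov = 5L) {
  if (window %% step != 0L)
    stop("`step` must divide `window`", call. = FALSE)
  dt <- data.table::as.data.table(records)
  sorted <- if ("sample_id" %in% names(dt)) {
    all(dt[, .(ok = !is.unsorted(order(chrom, pos)) &&
                 identical(order(chrom, pos), seq_len(.N))),
           by = sample_id]$ok)
  } else {
    identical(order(dt$chrom, dt$pos), seq_len(nrow(dt)))
  }
  if (!sorted)
    stop("records must be sorted by (chrom, pos) within each sample",
         call. = FALSE)
  sites <- .pool_sites(dt, min_cov)[eligible == TRUE]
  if (nrow(sites) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_sites = integer(),
                                  mC_ctrl = integer(), umC_ctrl = integer(),
                                  mC_treat = integer(),
                                  umC_treat = integer()))
  k <- as.integer(window %/% step)
  sites[, bin := (pos - 1L) %/% step]
  per_bin <- sites[, .(n_sites = .N, mC_ctrl = sum(mC_ctrl),
                       umC_ctrl = sum(umC_ctrl), mC_treat = sum(mC_treat),
                       umC_treat = sum(umC_treat)), by = .(chrom, bin)]
  out <- per_bin[, {
    full <- data.table::data.table(bin = 0:max(bin))
    dat <- merge(full, .SD, by = "bin", all.x = TRUE)
    for (cl in c("n_sites", "mC_ctrl", "umC_ctrl", "mC_treat", "umC_treat"))
      data.table::set(dat, which(is.na(dat[[cl]])), cl, 0L)
    # rolling sum of k consecutive bins = window starting at bin*step
    roll <- function(x) {
      cs <- cumsum(c(x, rep(0L, k - 1L)))
      cs[seq_along(x) + k - 1L] - c(0L, head(cs, length(x) - 1L))
    }
    data.table::data.table(
      start = dat$bin * step,
      n_sites = roll(dat$n_sites),
      mC_ctrl = roll(dat$mC_ctrl), umC_ctrl = roll(dat$umC_ctrl),
      mC_treat = roll(dat$mC_treat), umC_treat = roll(dat$umC_treat)
    )
  }, by = chrom]
  out <- out[n_sites > 0L]
  out[, end := start + as.integer(window)]
  data.table::setcolorder(out, c("chrom", "start", "end", "n_sites"))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Two-sided Fisher exact test on pooled window counts
#'
#' Tests the 2x2 table `[[mC_ctrl, umC_ctrl], [mC_treat, umC_treat]]` per
#' window. Windows with an empty margin get p = 1 with a warning.
#'
#' @param windows data.table from [enumerate_windows()].
#' @return The input with a `p_fisher` column added.
#' @export
window_test <- function(windows) {
  w <- data.table::as.data.table(windows)
  empty <- (w$mC_ctrl + w$umC_ctrl == 0L) | (w$mC_treat + w$umC_treat == 0L) |
    (w$mC_ctrl + w$mC_treat == 0L) | (w$umC_ctrl + w$umC_treat == 0L)
  p <- .fisher2x2(w$mC_ctrl, w$umC_ctrl, w$mC_treat, w$umC_treat)
  p[empty] <- 1
  if (any(empty))
    warning(sum(empty), " window(s) with an empty margin set to p = 1")
  w[, p_fisher := p]
  w[]
}

#' Merge significant windows into candidate regions
#'
#' Windows with `p_fisher < p_threshold` are merged when they overlap or
#' abut (gap 0); the resulting regions are pairwise disjoint and span the
#' union of their member windows.
#'
#' @param windows Output of [window_test()].
#' @param p_threshold Window significance threshold (default 0.05).
#' @return data.table: chrom, start, end, n_windows.
#' @export
merge_significant <- function(windows, p_threshold = 0.05) {
  w <- data.table::as.data.table(windows)[p_fisher < p_threshold]
  if (nrow(w) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_windows = integer()))
  gr <- GenomicRanges::GRanges(w$chrom,
                               IRanges::IRanges(w$start + 1L, w$end))
  red <- GenomicRanges::reduce(gr)  # merges overlapping or adjacent
  hits <- GenomicRanges::countOverlaps(red, gr)
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_windows = hits
  )
  data.table::setorder(out, chrom, start)
  out[]
}

# one-way two-group ANOVA on per-site methylation levels, by sums of
# squares (robust to zero within-group variance, and checkable against the
# squared two-sample t statistic)
.anova_two_group <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  grand <- mean(c(x, y))
  ssb <- n1 * (mean(x) - grand)^2 + n2 * (mean(y) - grand)^2
  ssw <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  df1 <- 1L; df2 <- n1 + n2 - 2L
  if (ssw == 0) {
    p <- if (ssb > 0) 0 else 1
    return(list(F = if (ssb > 0) Inf else 0, p = p))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' ANOVA confirmation of a candidate region
#'
#' One-way ANOVA across the two groups on per-site corrected methylation
#' levels inside the region; the region is retained as a DMR iff
#' `p < alpha`. Direction is `hyper` when the pooled treated level exceeds
#' the pooled control level.
#'
#' @param region One-row list/data.table with chrom, start, end.
#' @param sites Pooled per-site table (as from the internal pooling of
#'   [call_dmrs()]): chrom, pos, mC_ctrl, umC_ctrl, mC_treat, umC_treat.
#' @param r Non-conversion error rate used for corrected levels.
#' @param alpha Region-level significance threshold (default 0.05).
#' @return One-row data.table DMR (with `p_region`, `ML_ctrl`, `ML_treat`,
#'   `direction`, `length_bp`), or NULL with attribute-free rejection when
#'   the test fails or a group has < 2 eligible sites.
#' @export
region_filter <- function(region, sites, r = 0, alpha = 0.05) {
  s <- data.table::as.data.table(sites)[
    chrom == region$chrom & pos > region$start & pos <= region$end]
  if (nrow(s) < 2L) return(NULL)
  ml_ctrl <- corrected_level(
    methylation_level(s$mC_ctrl, s$umC_ctrl), r)
  ml_treat <- corrected_level(
    methylation_level(s$mC_treat, s$umC_treat), r)
  ok <- !is.na(ml_ctrl) & !is.na(ml_treat)
  if (sum(ok) < 2L) return(NULL)
  test <- .anova_two_group(ml_ctrl[ok], ml_treat[ok])
  if (!(test$p < alpha)) return(NULL)
  pooled_ctrl <- corrected_level(
    sum(s$mC_ctrl[ok]) / sum(s$mC_ctrl[ok] + s$umC_ctrl[ok]), r)
  pooled_treat <- corrected_level(
    sum(s$mC_treat[ok]) / sum(s$mC_treat[ok] + s$umC_treat[ok]), r)
  data.table::data.table(
    chrom = region$chrom, start = region$start, end = region$end,
    p_region = test$p, ML_ctrl = pooled_ctrl, ML_treat = pooled_treat,
    direction = if (pooled_treat > pooled_ctrl) "hyper" else "hypo",
    length_bp = region$end - region$start, n_sites = sum(ok)
  )
}

#' Call differentially methylated regions
#'
#' The full sliding-window pipeline: enumerate windows, Fisher-test each,
#' merge significant windows into regions, and confirm each region by
#' per-site ANOVA.
#'
#' @inheritParams enumerate_windows
#' @param r Non-conversion error rate (`1 - conversion_rate`).
#' @param p_window Window-level Fisher threshold (default 0.05).
#' @param p_region Region-level ANOVA threshold (default 0.05).
#' @return data.table of DMRs sorted by genomic position (possibly empty).
#' @export
call_dmrs <- function(records, window = 1000L, step = 100L, min_cov = 5L,
                      r = 0, p_window = 0.05, p_region = 0.05) {
  wins <- enumerate_windows(records, window, step, min_cov)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    p_region = numeric(), ML_ctrl = numeric(), ML_treat = numeric(),
    direction = character(), length_bp = integer(), n_sites = integer())
  if (nrow(wins) == 0L) return(empty)
  wins <- suppressWarnings(window_test(wins))
  regions <- merge_significant(wins, p_window)
  if (nrow(regions) == 0L) return(empty)
  sites <- .pool_sites(records, min_cov)[eligible == TRUE]
  dmrs <- lapply(seq_len(nrow(regions)), function(i)
    region_filter(regions[i], sites, r = r, alpha = p_region))
  dmrs <- data.table::rbindlist(dmrs[!vapply(dmrs, is.null, logical(1))])
  if (nrow(dmrs) == 0L) return(empty)
  data.table::setorder(dmrs, chrom, start)
  dmrs[]
}
utils::globalVariables(c("eligible", "p_fisher", "mC_ctrl", "umC_ctrl",
                         "mC_treat", "umC_treat", "n_sites"))
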