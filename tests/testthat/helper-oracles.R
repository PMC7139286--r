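# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's own code paths.

# quadratic interval intersection (0-based half-open)
bf_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1) out[[length(out) + 1L]] <-
        data.frame(a_idx = i, b_idx = j, overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(a_idx = integer(), b_idx = integer(),
                      overlap_bp = integer()))
  do.call(rbind, out)
}

# brute-force SNP-cluster flags: any run of n consecutive SNPs spanning
# <= w bases (inclusive span) marks all members
bf_cluster_flags <- function(pos, n = 3L, w = 35L) {
  pos <- sort(pos)
  flag <- logical(length(pos))
  if (length(pos) >= n) {
    for (i in seq_len(length(pos) - n + 1L)) {
      j <- i + n - 1L
      if (pos[j] - pos[i] + 1L <= w) flag[i:j] <- TRUE
    }
  }
  flag
}

# brute-force sliding-window pooled counts on one chromosome: every
# start = k*step window, pooling sites (1-based pos) with
# start < pos <= start + window
bf_windows <- function(sites, window = 1000L, step = 100L) {
  if (nrow(sites) == 0L) return(NULL)
  ks <- 0:((max(sites$pos) - 1L) %/% step)
  out <- list()
  for (k in ks) {
    s <- k * step
    sel <- sites$pos > s & sites$pos <= s + window
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      start = s, end = s + window, n_sites = sum(sel),
      mC_ctrl = sum(sites$mC_ctrl[sel]),
      umC_ctrl = sum(sites$umC_ctrl[sel]),
      mC_treat = sum(sites$mC_treat[sel]),
      umC_treat = sum(sites$umC_treat[sel]))
  }
  do.call(rbind, out)
}

# transitive-closure clustering of reads: link any two reads with gap
# <= link_gap, then keep components with >= min_reads members
bf_sirna_clusters <- function(reads, min_reads = 10L, link_gap = 75L) {
  reads <- reads[order(reads$start), ]
  n <- nrow(reads)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(reads$start[i], reads$start[j]) -
        min(reads$end[i], reads$end[j])
      if (gap <= link_gap && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  parts <- split(seq_len(n), comp)
  res <- lapply(parts, function(ix) {
    data.frame(start = min(reads$start[ix]), end = max(reads$end[ix]),
               read_count = length(ix))
  })
  res <- do.call(rbind, res)
  res <- res[res$read_count >= min_reads, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# union of possibly-overlapping-or-adjacent intervals by pairwise merging
bf_merge <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

# build a two-group single-replicate cytosine record table from per-site
# pooled counts (1-based positions on one chromosome)
make_records <- function(pos, mC_ctrl, umC_ctrl, mC_treat, umC_treat,
                         chrom = "chr1") {
  rbind(
    data.frame(chrom = chrom, pos = pos, strand = "+", context = "CG",
               mC = mC_ctrl, umC = umC_ctrl, sample_id = "ctrl_1",
               group = "ctrl"),
    data.frame(chrom = chrom, pos = pos, strand = "+", context = "CG",
               mC = mC_treat, umC = umC_treat, sample_id = "treat_1",
               group = "treat"))
}
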