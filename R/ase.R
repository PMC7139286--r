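# Allele-specific expression: variant filtering, genotype-transition
# classes, allele-fraction quantification, gene-level candidate loci, and
# differential ASE between conditions.

#' Filter variants by quality and SNP-cluster membership
#'
#' Retains biallelic SNVs with phred quality >= `min_qual` that do not
#' belong to any run of `cluster_n` consecutive SNPs spanning at most
#' `cluster_window` bases (span = last - first + 1, inclusive). Cluster
#' membership removes every member of the run; runs are evaluated on all
#' input SNVs per chromosome.
#'
#' @param loci data.table with chrom, pos (1-based), ref, alt, qual.
#' @param min_qual Minimum variant quality (default 20).
#' @param cluster_n Run length defining a cluster (default 3).
#' @param cluster_window Maximum span in bases of a cluster run
#'   (default 35).
#' @return The retained rows, position-sorted.
#' @export
filter_variants <- function(loci, min_qual = 20, cluster_n = 3L,
                            cluster_window = 35L) {
  dt <- data.table::as.data.table(loci)
  bad_allele <- !(nchar(dt$ref) == 1L & nchar(dt$alt) == 1L &
                    dt$ref %in% c("A", "C", "G", "T") &
                    dt$alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    message(sum(bad_allele), " non-SNV record(s) skipped")
  dt <- dt[!bad_allele]
  data.table::setorder(dt, chrom, pos)
  dt[, clustered := {
    p <- pos
    n <- length(p)
    cl <- logical(n)
    if (n >= cluster_n) {
      for (i in seq_len(n - cluster_n + 1L)) {
        j <- i + cluster_n - 1L
        if (p[j] - p[i] + 1L <= cluster_window) cl[i:j] <- TRUE
      }
    }
    cl
  }, by = chrom]
  out <- dt[qual >= min_qual & clustered == FALSE]
  out[, clustered := NULL]
  out[]
}

#' Depth filter for allelic loci
#'
#' A locus is kept only if the total allelic depth (REF + ALT, replicates
#' summed) is strictly greater than `min_total - 1` in **both** conditions.
#'
#' @param ref_ctrl,alt_ctrl,ref_treat,alt_treat Condition-level allelic
#'   read counts (replicates already summed).
#' @param min_total Minimum total depth per condition (default 6, i.e.
#'   "greater than 5").
#' @return Logical keep flag(s).
#' @export
depth_filter <- function(ref_ctrl, alt_ctrl, ref_treat, alt_treat,
                         min_total = 6L) {
  (ref_ctrl + alt_ctrl) >= min_total & (ref_treat + alt_treat) >= min_total
}

# genotype call from allelic counts: heterozygous iff the minor allele has
# >= min_reads supporting reads and frequency >= min_frac
.call_genotype <- function(ref, alt, min_frac = 0.1, min_reads = 2L) {
  total <- ref + alt
  minor <- pmin(ref, alt)
  ifelse(total == 0, NA_character_,
         ifelse(minor >= min_reads & minor / total >= min_frac,
                "het", "hom"))
}

#' Classify the genotype transition of a locus between conditions
#'
#' Loci are heterozygous when the minor allele has at least `min_reads`
#' supporting reads and a frequency of at least `min_frac`; the transition
#' class is one of `het_het`, `het_hom`, `hom_het`, `other` (homozygous in
#' both conditions: no allelic variation).
#'
#' @inheritParams depth_filter
#' @param min_frac Minor-allele frequency threshold for a het call
#'   (default 0.1).
#' @param min_reads Minimum minor-allele reads for a het call (default 2).
#' @return Character vector of transition classes.
#' @export
classify_transition <- function(ref_ctrl, alt_ctrl, ref_treat, alt_treat,
                                min_frac = 0.1, min_reads = 2L) {
  g1 <- .call_genotype(ref_ctrl, alt_ctrl, min_frac, min_reads)
  g2 <- .call_genotype(ref_treat, alt_treat, min_frac, min_reads)
  ifelse(is.na(g1) | is.na(g2), NA_character_,
    ifelse(g1 == "het" & g2 == "het", "het_het",
    ifelse(g1 == "het" & g2 == "hom", "het_hom",
    ifelse(g1 == "hom" & g2 == "het", "hom_het", "other"))))
}

#' Allele fraction (ASE level)
#'
#' `ALT / (ALT + REF)`: the fraction of reads carrying the alternative
#' allele.
#'
#' @param ref_count,alt_count Allelic read counts.
#' @return Fraction(s) in `[0, 1]`; `NA` where total is 0.
#' @export
ase_level <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  ifelse(total > 0, alt_count / total, NA_real_)
}

#' Select the representative ASE locus of a gene
#'
#' Among loci lying within the gene's 3' UTR or within `utr_window` bp
#' beyond its outer boundary (strand-aware, half-open window
#' `(utr_end, utr_end + w]` on + / `[utr_start - w, utr_start)` on -),
#' returns the locus with the maximum total supporting reads (both
#' conditions summed); ties break to the smallest genomic coordinate.
#'
#' @param gene List/row with `chrom`, `utr_start`, `utr_end` (1-based
#'   inclusive 3' UTR), `strand`.
#' @param loci data.table with chrom, pos, ref_ctrl, alt_ctrl, ref_treat,
#'   alt_treat.
#' @param utr_window Downstream window size in bp (default 500).
#' @return The selected one-row data.table, or NULL when no locus is
#'   eligible.
#' @export
select_gene_locus <- function(gene, loci, utr_window = 500L) {
  dt <- data.table::as.data.table(loci)[chrom == gene$chrom]
  in_utr <- dt$pos >= gene$utr_start & dt$pos <= gene$utr_end
  beyond <- if (gene$strand == "+") {
    dt$pos > gene$utr_end & dt$pos <= gene$utr_end + utr_window
  } else {
    dt$pos < gene$utr_start & dt$pos >= gene$utr_start - utr_window
  }
  dt <- dt[in_utr | beyond]
  if (nrow(dt) == 0L) return(NULL)
  dt[, total_reads := ref_ctrl + alt_ctrl + ref_treat + alt_treat]
  data.table::setorder(dt, -total_reads, pos)
  dt[1L]
}

#' Differential allele-specific expression between conditions
#'
#' Two-sided Fisher exact test on the 2x2 table of condition-level REF/ALT
#' counts (replicates summed); `delta` is the treated minus control allele
#' fraction; significant at `p < alpha`.
#'
#' @inheritParams depth_filter
#' @param alpha Significance threshold (default 0.05).
#' @return data.table with ase_ctrl, ase_treat, a_over_r per condition,
#'   delta, p_diff, significant.
#' @export
differential_ase <- function(ref_ctrl, alt_ctrl, ref_treat, alt_treat,
                             alpha = 0.05) {
  p <- .fisher2x2(ref_ctrl, alt_ctrl, ref_treat, alt_treat)
  f_c <- ase_level(ref_ctrl, alt_ctrl)
  f_t <- ase_level(ref_treat, alt_treat)
  data.table::data.table(
    ase_ctrl = f_c, ase_treat = f_t,
    a_over_r_ctrl = ifelse(ref_ctrl > 0, alt_ctrl / ref_ctrl, NA_real_),
    a_over_r_treat = ifelse(ref_treat > 0, alt_treat / ref_treat,
                            NA_real_),
    delta = f_t - f_c, p_diff = p, significant = p < alpha
  )
}

#' A/R shift summary for gene sets
#'
#' For each gene set (e.g. up- and downregulated genes) summarises the
#' per-condition A/R (ALT/REF) distribution of the genes' candidate loci
#' and tests for a location shift between conditions (two-sample Wilcoxon).
#'
#' @param gene_sets Named list of character vectors of gene ids.
#' @param ase_results data.table with gene_id, a_over_r_ctrl,
#'   a_over_r_treat.
#' @return data.table: set, n, median_ctrl, median_treat, p_shift (rows
#'   with empty sets are returned with NA statistics).
#' @export
group_ase_shift <- function(gene_sets, ase_results) {
  res <- data.table::as.data.table(ase_results)
  out <- lapply(names(gene_sets), function(nm) {
    sub <- res[gene_id %in% gene_sets[[nm]] &
                 !is.na(a_over_r_ctrl) & !is.na(a_over_r_treat)]
    if (nrow(sub) == 0L)
      return(data.table::data.table(set = nm, n = 0L,
                                    median_ctrl = NA_real_,
                                    median_treat = NA_real_,
                                    p_shift = NA_real_))
    p <- if (nrow(sub) >= 2L)
      suppressWarnings(wilcox.test(sub$a_over_r_ctrl,
                                   sub$a_over_r_treat)$p.value)
    else NA_real_
    data.table::data.table(set = nm, n = nrow(sub),
                           median_ctrl = median(sub$a_over_r_ctrl),
                           median_treat = median(sub$a_over_r_treat),
                           p_shift = p)
  })
  data.table::rbindlist(out)
}
utils::globalVariables(c("clustered", "qual", "total_reads", "gene_id",
                         "a_over_r_ctrl", "a_over_r_treat", "ref_ctrl",
                         "alt_ctrl", "ref_treat", "alt_treat"))
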