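# Tally operations over stage result tables: totals, up/down splits, and
# percentage shares, as reported in differential-expression, siRNA, and
# association summaries.

#' Summarise differential-expression calls
#'
#' @param results data.table with logical `is_de` and `log2fc`.
#' @return data.table: n_total (DE features), n_up, n_down.
#' @export
summarize_de <- function(results) {
  dt <- data.table::as.data.table(results)
  de <- dt[is_de %in% TRUE]
  data.table::data.table(n_total = nrow(de),
                         n_up = sum(de$log2fc > 0),
                         n_down = sum(de$log2fc < 0))
}

#' Summarise differential siRNA loci
#'
#' @param results data.table with logical `significant` and `log2fc` (one
#'   row per locus).
#' @return data.table: n_loci, n_significant, pct_significant (of all
#'   loci), n_up, n_down, pct_up, pct_down (of significant loci).
#' @export
summarize_sirna_diff <- function(results) {
  dt <- data.table::as.data.table(results)
  sig <- dt[significant %in% TRUE]
  data.table::data.table(
    n_loci = nrow(dt), n_significant = nrow(sig),
    pct_significant = 100 * nrow(sig) / nrow(dt),
    n_up = sum(sig$log2fc > 0), n_down = sum(sig$log2fc < 0),
    pct_up = 100 * sum(sig$log2fc > 0) / nrow(sig),
    pct_down = 100 * sum(sig$log2fc < 0) / nrow(sig))
}

#' Summarise significant SNP-trait associations per trait
#'
#' @param results data.table with `trait` and logical `significant` (as
#'   from [assoc_scan()], possibly stacked over traits).
#' @return List with `per_trait` (trait, n_significant) and `n_total`.
#' @export
summarize_associations <- function(results) {
  dt <- data.table::as.data.table(results)
  per_trait <- dt[significant %in% TRUE, .(n_significant = .N),
                  by = trait]
  list(per_trait = per_trait[], n_total = sum(per_trait$n_significant))
}

#' Fraction of CpG loci with changed allelic methylation
#'
#' @param genotypes Output of [classify_allelic_change()].
#' @return Percentage of loci flagged `changed`.
#' @export
pct_changed_cpg <- function(genotypes) {
  dt <- data.table::as.data.table(genotypes)
  100 * mean(dt$changed, na.rm = TRUE)
}
utils::globalVariables(c("is_de", "significant", "trait"))
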