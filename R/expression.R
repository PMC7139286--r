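# FPKM quantification and differential-expression criteria.

#' Fragments per kilobase per million mapped fragments
#'
#' @param fragments Fragment count(s) assigned to the feature.
#' @param feature_length_bp Feature length in bp (> 0).
#' @param total_mapped_fragments Library total (> 0).
#' @return `fragments * 1e9 / (feature_length_bp * total_mapped_fragments)`.
#' @export
fpkm <- function(fragments, feature_length_bp, total_mapped_fragments) {
  stopifnot(all(feature_length_bp > 0), all(total_mapped_fragments > 0))
  fragments * 1e9 / (feature_length_bp * total_mapped_fragments)
}

#' Differential-expression call for one feature
#'
#' A feature is differentially expressed when all three criteria hold:
#' `|log2(fold change)| >= lfc_min` on group-mean FPKM, Fisher exact
#' `p < alpha` on pooled fragment counts against library remainders, and
#' FPKM strictly above `min_fpkm` in **every** sample.
#'
#' @param fragments Integer vector of per-sample fragment counts.
#' @param totals Per-sample total mapped fragments.
#' @param groups Factor/character of `ctrl`/`treat` per sample.
#' @param length_bp Feature length.
#' @param min_fpkm Per-sample FPKM floor (default 5, strict).
#' @param lfc_min Absolute log2 fold-change threshold (default 1, i.e.
#'   fold change 2).
#' @param alpha P-value threshold (default 0.05).
#' @return One-row data.table: fpkm_ctrl, fpkm_treat (group means),
#'   log2fc, p_value, min_sample_fpkm, is_de.
#' @export
call_deg <- function(fragments, totals, groups, length_bp, min_fpkm = 5,
                     lfc_min = 1, alpha = 0.05) {
  stopifnot(length(fragments) == length(totals),
            length(fragments) == length(groups))
  f <- fpkm(fragments, length_bp, totals)
  is_t <- groups == "treat"
  m_c <- mean(f[!is_t]); m_t <- mean(f[is_t])
  lfc <- log2(m_t / m_c)
  p <- .fisher2x2(sum(fragments[!is_t]),
                  sum(totals[!is_t] - fragments[!is_t]),
                  sum(fragments[is_t]),
                  sum(totals[is_t] - fragments[is_t]))
  data.table::data.table(
    fpkm_ctrl = m_c, fpkm_treat = m_t, log2fc = lfc, p_value = p,
    min_sample_fpkm = min(f),
    is_de = is.finite(lfc) && abs(lfc) >= lfc_min && p < alpha &&
      all(f > min_fpkm)
  )
}

#' Differential-expression table for a count matrix
#'
#' Applies [call_deg()] to every row of a feature x sample fragment-count
#' matrix.
#'
#' @param counts Matrix of fragment counts (features x samples).
#' @param lengths_bp Per-feature lengths.
#' @param totals,groups Per-sample library totals and group labels.
#' @inheritParams call_deg
#' @return data.table with one row per feature (feature_id column first).
#' @export
deg_table <- function(counts, lengths_bp, totals, groups, min_fpkm = 5,
                      lfc_min = 1, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(counts)), function(i)
    call_deg(counts[i, ], totals, groups, lengths_bp[i], min_fpkm,
             lfc_min, alpha))
  out <- data.table::rbindlist(rows)
  out[, feature_id := rownames(counts) %||% paste0("f", .I)]
  data.table::setcolorder(out, "feature_id")
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable-expression filter for lncRNAs
#'
#' Keeps a transcript when its group-level FPKM exceeds 1 in at least one
#' group and is above 0 in the other.
#'
#' @param fpkm_ctrl,fpkm_treat Group-level FPKM values.
#' @return Logical keep flag(s).
#' @export
lncrna_stable_filter <- function(fpkm_ctrl, fpkm_treat) {
  (fpkm_ctrl > 1 | fpkm_treat > 1) & pmin(fpkm_ctrl, fpkm_treat) > 0
}
utils::globalVariables(c("feature_id", ".I"))
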