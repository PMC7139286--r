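#' Per-site methylation level
#'
#' Methylation level at a cytosine is the fraction of bisulfite reads
#' supporting methylation, `ML = mC / (mC + umC)`, where `mC` and `umC` are
#' the methylated and unmethylated read counts.
#'
#' @param mC Non-negative integer vector of methylated read counts.
#' @param umC Non-negative integer vector of unmethylated read counts.
#' @return Numeric vector of levels in `[0, 1]`; `NA` where total coverage is
#'   zero (undefined, deliberately not 0).
#' @examples
#' methylation_level(2, 8)   # 0.2
#' methylation_level(0, 17)  # 0
#' @export
methylation_level <- function(mC, umC) {
  stopifnot(all(mC >= 0, na.rm = TRUE), all(umC >= 0, na.rm = TRUE))
  total <- mC + umC
  out <- ifelse(total > 0, mC / total, NA_real_)
  out
}

#' Conversion-corrected methylation level
#'
#' Incomplete bisulfite conversion makes a fraction `r` of truly unmethylated
#' cytosines read as methylated; the observed level is corrected as
#' `(ML - r) / (1 - r)` and clamped to `[0, 1]`. Here `r` is the
#' non-conversion (error) rate; if your pipeline reports a conversion rate
#' `c` (e.g. 0.995), pass `r = 1 - c`.
#'
#' @param ML Observed methylation level(s) in `[0, 1]`.
#' @param r Non-conversion error rate, `0 <= r < 1`.
#' @return Corrected level(s), clamped to `[0, 1]`.
#' @examples
#' corrected_level(0.505, 0.01)  # 0.5
#' @export
corrected_level <- function(ML, r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r >= 1)
    stop("`r` must be a single value in [0, 1)", call. = FALSE)
  pmin(1, pmax(0, (ML - r) / (1 - r)))
}

#' Binomial test for genuine methylation at a site
#'
#' Tests whether the methylated read count at a site exceeds what
#' non-conversion noise alone would produce: a one-sided upper-tail binomial
#' test of `mC` successes in `mC + umC` trials with null success probability
#' `r` (the non-conversion rate). Sites below the coverage floor are excluded
#' (`NA` call), not called unmethylated.
#'
#' @param mC,umC Methylated / unmethylated read counts (vectors).
#' @param r Non-conversion error rate (null methylation probability).
#' @param alpha Significance level for the call (default 0.05).
#' @param min_coverage Minimum total reads for a site to be testable
#'   (default 5).
#' @return A `data.table` with columns `mC`, `umC`, `ML`, `ML_corrected`,
#'   `p_binomial`, `is_methylated` (NA where coverage is below the floor).
#' @export
call_methylated_site <- function(mC, umC, r, alpha = 0.05, min_coverage = 5L) {
  stopifnot(length(mC) == length(umC))
  if (r < 0 || r >= 1) stop("`r` must be in [0, 1)", call. = FALSE)
  n <- mC + umC
  # P(X >= mC) under Binomial(n, r); mC = 0 gives p = 1
  p <- pbinom(mC - 1L, n, r, lower.tail = FALSE)
  eligible <- n >= min_coverage
  ML <- methylation_level(mC, umC)
  data.table::data.table(
    mC = mC, umC = umC,
    ML = ML,
    ML_corrected = corrected_level(ML, r),
    p_binomial = ifelse(eligible, p, NA_real_),
    is_methylated = ifelse(eligible, p < alpha, NA)
  )
}

#' Methylation support rate of a CpG locus
#'
#' The support rate `S = mC_reads / (mC_reads + C_reads)` ranges from 0 (no
#' methylation on either allele) to 1 (complete methylation of both
#' alleles); intermediate values indicate allelic (hemi-)methylation.
#'
#' @param mC_reads Reads supporting methylation at the locus.
#' @param c_reads Reads supporting the unmethylated state.
#' @return Support rate(s) in `[0, 1]`; `NA` where total is zero.
#' @examples
#' methylation_support(7, 7)  # 0.5: one allele methylated
#' @export
methylation_support <- function(mC_reads, c_reads) {
  methylation_level(mC_reads, c_reads)
}

#' Classify change in allelic methylation between conditions
#'
#' A CpG locus is called "changed" when the relative shift of its
#' methylation support rate between treatment and control exceeds a
#' threshold: `|S_treat - S_ctrl| / S_ctrl > threshold` (strict). A locus
#' with `S_ctrl = 0` and `S_treat > 0` is changed with an infinite ratio
#' (any gain from zero is an obvious change); `S_ctrl = S_treat = 0` is
#' unchanged.
#'
#' @param S_treat,S_ctrl Support rates in the treated and control condition.
#' @param threshold Relative-change threshold (default 0.5).
#' @return `data.table` with `S_ctrl`, `S_treat`, `change_ratio`, `changed`.
#' @export
classify_allelic_change <- function(S_treat, S_ctrl, threshold = 0.5) {
  stopifnot(length(S_treat) == length(S_ctrl))
  ratio <- ifelse(S_ctrl > 0, abs(S_treat - S_ctrl) / S_ctrl,
                  ifelse(S_treat > 0, Inf, 0))
  data.table::data.table(
    S_ctrl = S_ctrl, S_treat = S_treat,
    change_ratio = ratio,
    changed = ratio > threshold
  )
}

#' Sequence context of a cytosine (CG / CHG / CHH)
#'
#' Classifies cytosines by their trinucleotide context on the given strand:
#' CG if the next base is G; CHG if the next base is H (A, C or T) and the
#' base after is G; CHH otherwise. Minus-strand positions are evaluated on
#' the reverse complement. Sites whose context window runs past the
#' chromosome end are returned as `NA` with a warning (no sequence is
#' fabricated).
#'
#' @param genome A named [Biostrings::DNAStringSet] (or object coercible to
#'   one) holding the reference sequences.
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s) of the cytosine.
#' @param strand `"+"` or `"-"` per position.
#' @return Character vector in `c("CG", "CHG", "CHH")` (or `NA`).
#' @export
classify_context <- function(genome, chrom, pos, strand) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  lens <- setNames(Biostrings::width(genome), names(genome))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    seq_ch <- as.character(genome[[ch]])
    L <- lens[[ch]]
    base_at <- function(p) {
      ok <- p >= 1 & p <= L
      b <- rep(NA_character_, length(p))
      if (any(ok)) b[ok] <- substring(seq_ch, p[ok], p[ok])
      b
    }
    plus <- idx[strand[idx] == "+"]
    minus <- idx[strand[idx] == "-"]
    if (length(plus)) {
      p <- pos[plus]
      if (any(base_at(p) != "C", na.rm = TRUE))
        stop("position is not a cytosine on the + strand", call. = FALSE)
      b1 <- base_at(p + 1L); b2 <- base_at(p + 2L)
      out[plus] <- .context_from_bases(b1, b2)
    }
    if (length(minus)) {
      p <- pos[minus]
      if (any(base_at(p) != "G", na.rm = TRUE))
        stop("position is not a cytosine on the - strand", call. = FALSE)
      # reverse complement: next base downstream on - strand is complement
      # of the base at pos - 1 on the + strand
      b1 <- .complement(base_at(p - 1L))
      b2 <- .complement(base_at(p - 2L))
      out[minus] <- .context_from_bases(b1, b2)
    }
  }
  if (anyNA(out))
    warning(sum(is.na(out)),
            " site(s) within 2 bp of a chromosome end excluded (context NA)")
  out
}

.complement <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

.context_from_bases <- function(b1, b2) {
  ctx <- rep(NA_character_, length(b1))
  cg <- !is.na(b1) & b1 == "G"
  ctx[cg] <- "CG"
  chg <- !is.na(b1) & !is.na(b2) & b1 != "G" & b2 == "G"
  ctx[chg] <- "CHG"
  chh <- !is.na(b1) & !is.na(b2) & b1 != "G" & b2 != "G"
  ctx[chh] <- "CHH"
  ctx
}

#' Fraction of methylated cytosines per context
#'
#' @param calls A data.frame/data.table with columns `context` and
#'   `is_methylated` (as from [call_methylated_site()] joined to records).
#' @return Named numeric vector `c(CG=, CHG=, CHH=)` of fractions of all
#'   methylated sites, summing to 1.
#' @export
summarize_contexts <- function(calls) {
  calls <- data.table::as.data.table(calls)
  m <- calls[is_methylated %in% TRUE]
  if (nrow(m) == 0L) stop("no methylated calls to summarize", call. = FALSE)
  tab <- table(factor(m$context, levels = c("CG", "CHG", "CHH")))
  as.vector(tab / sum(tab)) |> setNames(c("CG", "CHG", "CHH"))
}
utils::globalVariables("is_methylated")
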