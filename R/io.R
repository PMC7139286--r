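# Plain-text readers/writers for the pipeline's interchange formats.

#' Write / read a cytosine report
#'
#' Tab-separated per-cytosine counts (Bismark-style dialect): chrom,
#' pos (1-based), strand, context, count_methylated, count_unmethylated,
#' sample_id.
#'
#' @param records data.table with chrom, pos, strand, context, mC, umC,
#'   sample_id (and optionally group).
#' @param path Output file.
#' @return `path`, invisibly (writer); a data.table (reader).
#' @export
write_cytosine_report <- function(records, path) {
  dt <- data.table::as.data.table(records)
  out <- dt[, .(chrom, pos, strand, context,
                count_methylated = mC, count_unmethylated = umC,
                sample_id)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_cytosine_report
#' @export
read_cytosine_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  data.table::setnames(dt, old = c("count_methylated",
                                   "count_unmethylated"),
                       new = c("mC", "umC"), skip_absent = TRUE)
  dt[]
}

#' Write / read BED intervals
#'
#' BED6 (chrom, start, end, name, score, strand), 0-based half-open.
#'
#' @param intervals data.table with chrom, start, end (name/score/strand
#'   optional).
#' @param path File path.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table::as.data.table(intervals)
  if (!"name" %in% names(dt)) dt[, name := paste0("iv", .I)]
  if (!"score" %in% names(dt)) dt[, score := 0L]
  if (!"strand" %in% names(dt)) dt[, strand := "."]
  data.table::fwrite(dt[, .(chrom, start, end, name, score, strand)],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  data.table::setnames(dt, seq_len(min(6L, ncol(dt))),
                       c("chrom", "start", "end", "name", "score",
                         "strand")[seq_len(min(6L, ncol(dt)))])
  dt[]
}

#' Write allelic counts as VCF 4.2 with AD, and read them back
#'
#' One sample column per condition x replicate; genotype fields carry
#' `GT:AD` with allelic depths `ref,alt`. Reading uses `vcfR`.
#'
#' @param counts data.table from [simulate_allelic_counts()] (chrom, pos,
#'   ref, alt, condition, replicate, ref_count, alt_count, qual).
#' @param path File path.
#' @export
write_allelic_vcf <- function(counts, path) {
  dt <- data.table::as.data.table(counts)
  dt[, sample := paste0(condition, "_", replicate)]
  samples <- sort(unique(dt$sample))
  loci <- unique(dt[, .(chrom, pos, ref, alt, qual)])
  data.table::setorder(loci, chrom, pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i]
    cells <- vapply(samples, function(s) {
      row <- dt[chrom == l$chrom & pos == l$pos & sample == s]
      if (nrow(row) == 0L) return("./.:0,0")
      gt <- if (row$ref_count > 0 && row$alt_count > 0) "0/1"
      else if (row$alt_count > 0) "1/1" else "0/0"
      paste0(gt, ":", row$ref_count, ",", row$alt_count)
    }, character(1))
    paste(c(l$chrom, l$pos, ".", l$ref, l$alt, l$qual, "PASS", ".",
            "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_allelic_vcf
#' @export
read_allelic_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- data.table::as.data.table(vcfR::getFIX(v))
  rows <- lapply(colnames(ad), function(s) {
    parts <- data.table::tstrsplit(ad[, s], ",", type.convert = TRUE)
    cond_rep <- data.table::tstrsplit(s, "_")
    data.table::data.table(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      condition = cond_rep[[1]], replicate = as.integer(cond_rep[[2]]),
      ref_count = parts[[1]], alt_count = parts[[2]],
      qual = as.numeric(fix$QUAL))
  })
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, chrom, pos, condition, replicate)
  out[]
}

#' Write / read a 0/1/2 genotype matrix as TSV
#'
#' First column `individual`, one column per SNP; missing genotypes are
#' empty cells.
#'
#' @param genotypes Individuals x SNPs matrix.
#' @param path File path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  dt <- data.table::as.data.table(as.data.frame(genotypes),
                                  keep.rownames = "individual")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
utils::globalVariables(c("condition", "replicate", "ref", "alt", "name",
                         "score", "ref_count", "alt_count"))
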