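# End-to-end orchestration over the synthetic inputs, plus light-weight
# input validation for the interchange formats.

#' Simulate gene fragment counts
#'
#' Poisson fragment counts per sample for a set of features with known
#' group-level FPKM, so the expression stage has a truth-backed input.
#'
#' @param specs data.frame: feature_id, length_bp, fpkm_ctrl, fpkm_treat.
#' @param config A [sim_config()] (replicate count and seed).
#' @param library_size Total mapped fragments per sample (default 1e6).
#' @return List with `counts` (matrix features x samples), `lengths_bp`,
#'   `totals`, `groups`, `truth`.
#' @export
simulate_expression_counts <- function(specs, config,
                                       library_size = 1e6) {
  specs <- data.table::as.data.table(specs)
  .sim_seed(config, 6L)
  nrep <- config$n_replicates_per_group
  groups <- rep(c("ctrl", "treat"), each = nrep)
  mu <- function(fpkm) fpkm * specs$length_bp * library_size / 1e9
  counts <- vapply(seq_along(groups), function(k) {
    f <- if (groups[k] == "ctrl") specs$fpkm_ctrl else specs$fpkm_treat
    rpois(nrow(specs), mu(f))
  }, integer(nrow(specs)))
  rownames(counts) <- specs$feature_id
  colnames(counts) <- paste0(groups, "_", rep(seq_len(nrep), 2))
  list(counts = counts, lengths_bp = specs$length_bp,
       totals = rep(library_size, length(groups)), groups = groups,
       truth = specs)
}

#' Run the integrated pipeline on synthetic data
#'
#' Generates every input from `config`, writes the interchange files under
#' `out_dir`, runs the requested stages in dependency order
#' (simulate -> methylome/expression/ase/sirna -> dmr -> integrate ->
#' assoc), and writes a manifest with parameters and MD5 checksums of all
#' outputs. Re-running with the same config and seed reproduces identical
#' checksums.
#'
#' @param config A [sim_config()]; stages whose specs are absent are
#'   skipped.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (default "all").
#' @param expression_specs Optional specs for
#'   [simulate_expression_counts()].
#' @return Invisibly, a list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir, stages = "all",
                         expression_specs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  all_stages <- c("simulate", "methylome", "dmr", "ase", "sirna", "expr",
                  "integrate", "assoc")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  need <- function(stage, obj, upstream) {
    if (is.null(obj))
      stop("stage '", stage, "' needs output of stage '", upstream,
           "'; run it first or include it in `stages`", call. = FALSE)
    obj
  }

  r_err <- 1 - config$conversion_rate
  genome <- meth <- NULL
  if ("simulate" %in% stages) {
    genome <- simulate_genome(config)
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    meth <- simulate_methylome(genome, config)
    write_cytosine_report(meth$records,
                          file.path(out_dir, "cytosine_report.tsv"))
    data.table::fwrite(meth$truth, file.path(out_dir, "truth_dmrs.tsv"),
                       sep = "\t")
    res$simulate <- list(genome = genome, methylome = meth)
  }

  if ("methylome" %in% stages) {
    m <- need("methylome", meth, "simulate")
    pooled <- m$records[, .(mC = sum(mC), umC = sum(umC)),
                        by = .(chrom, pos, strand, context)]
    calls <- call_methylated_site(pooled$mC, pooled$umC, r = r_err)
    res$methylome <- cbind(pooled[, .(chrom, pos, strand, context)],
                           calls[, .(ML, ML_corrected, p_binomial,
                                     is_methylated)])
    data.table::fwrite(res$methylome,
                       file.path(out_dir, "methylation_calls.tsv"),
                       sep = "\t")
  }

  if ("dmr" %in% stages) {
    m <- need("dmr", meth, "simulate")
    res$dmr <- call_dmrs(m$records, r = r_err)
    if (nrow(res$dmr))
      write_bed(res$dmr[, .(chrom, start, end, name = direction,
                            score = round(-10 * log10(pmax(p_region,
                                                           1e-30))))],
                file.path(out_dir, "dmrs.bed"))
    data.table::fwrite(res$dmr, file.path(out_dir, "dmrs.tsv"),
                       sep = "\t")
  }

  if ("ase" %in% stages && !is.null(config$ase_specs)) {
    sim <- simulate_allelic_counts(config)
    write_allelic_vcf(sim$counts, file.path(out_dir, "allelic.vcf"))
    wide <- sim$counts[, .(ref_count = sum(ref_count),
                           alt_count = sum(alt_count)),
                       by = .(chrom, pos, condition)]
    wide <- data.table::dcast(wide, chrom + pos ~ condition,
                              value.var = c("ref_count", "alt_count"))
    keep <- depth_filter(wide$ref_count_ctrl, wide$alt_count_ctrl,
                         wide$ref_count_treat, wide$alt_count_treat)
    wide <- wide[keep]
    diffs <- differential_ase(wide$ref_count_ctrl, wide$alt_count_ctrl,
                              wide$ref_count_treat,
                              wide$alt_count_treat)
    res$ase <- cbind(wide, diffs)
    data.table::fwrite(res$ase, file.path(out_dir, "ase_results.tsv"),
                       sep = "\t")
    res$ase_truth <- sim$truth
  }

  if ("sirna" %in% stages && !is.null(config$sirna_specs)) {
    if (is.null(genome) && "simulate" %in% stages)
      genome <- simulate_genome(config)
    g <- need("sirna", genome, "simulate")
    sim <- simulate_sirna_reads(g, config)
    for (lib in sim$libraries$library_id)
      write_bed(sim$reads[library_id == lib],
                file.path(out_dir, paste0("sirna_", lib, ".bed")))
    per_lib <- lapply(sim$libraries$library_id, function(lib)
      merge_clusters(call_clusters(sim$reads[library_id == lib])))
    names(per_lib) <- sim$libraries$library_id
    res$sirna <- list(loci = per_lib, libraries = sim$libraries,
                      truth = sim$truth)
  }

  if ("expr" %in% stages && !is.null(expression_specs)) {
    sim <- simulate_expression_counts(expression_specs, config)
    tab <- deg_table(sim$counts, sim$lengths_bp, sim$totals, sim$groups)
    data.table::fwrite(tab, file.path(out_dir, "deg_results.tsv"),
                       sep = "\t")
    res$expr <- list(table = tab, truth = sim$truth)
  }

  if ("integrate" %in% stages && !is.null(res$dmr) &&
        nrow(res$dmr) > 0L) {
    feats <- list()
    if (!is.null(res$sirna)) {
      loci <- res$sirna$loci[[1]]
      if (nrow(loci))
        feats$sirna <- data.table::data.table(
          feature_id = paste0("sirna_", seq_len(nrow(loci))),
          kind = "siRNA_locus", loci[, .(chrom, start, end)])
    }
    if (length(feats)) {
      ann <- annotate_dmrs(res$dmr, data.table::rbindlist(feats))
      res$integrate <- ann
      data.table::fwrite(ann$annotations,
                         file.path(out_dir, "dmr_annotation.tsv"),
                         sep = "\t")
    }
  }

  if ("assoc" %in% stages && !is.null(config$population$causal)) {
    pop <- simulate_population(config)
    write_genotypes_tsv(pop$genotypes,
                        file.path(out_dir, "genotypes.tsv"))
    data.table::fwrite(pop$phenotypes,
                       file.path(out_dir, "phenotypes.tsv"), sep = "\t")
    G <- filter_snps(pop$genotypes)
    K <- grm(G)
    res$assoc <- assoc_scan(pop$phenotypes$trait, G, K = K)
    data.table::fwrite(res$assoc,
                       file.path(out_dir, "association_results.tsv"),
                       sep = "\t")
    res$assoc_truth <- pop$truth
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "methlink",
    seed = config$seed,
    stages = stages,
    parameters = list(conversion_rate = config$conversion_rate,
                      coverage_mean = config$coverage_mean,
                      n_replicates = config$n_replicates_per_group),
    outputs = as.list(tools::md5sum(sort(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Validate pipeline input files
#'
#' Light-weight per-file structural checks: VCF header and AD availability,
#' BED column count and coordinate sanity, cytosine-report columns. The
#' first offending line is reported per file.
#'
#' @param paths Character vector of file paths.
#' @param formats Matching vector of formats: `"vcf"`, `"bed"`,
#'   `"cytosine_report"`, or `"tsv"`.
#' @return data.table: file, format, ok, message.
#' @export
validate_inputs <- function(paths, formats) {
  stopifnot(length(paths) == length(formats))
  rows <- lapply(seq_along(paths), function(i) {
    path <- paths[i]; fmt <- formats[i]
    msg <- ""; ok <- TRUE
    if (!file.exists(path)) {
      ok <- FALSE; msg <- "file not found"
    } else if (fmt == "vcf") {
      lines <- readLines(path, n = 200)
      if (!grepl("^##fileformat=VCF", lines[1])) {
        ok <- FALSE; msg <- "line 1: missing ##fileformat header"
      } else if (!any(grepl("^##FORMAT=<ID=AD", lines))) {
        ok <- FALSE; msg <- "no AD FORMAT definition (required for ASE)"
      }
    } else if (fmt == "bed") {
      dt <- data.table::fread(path, header = FALSE, nrows = 1000)
      if (ncol(dt) < 3L) {
        ok <- FALSE; msg <- "fewer than 3 columns"
      } else if (any(dt[[2]] >= dt[[3]])) {
        ok <- FALSE
        msg <- paste0("line ", which(dt[[2]] >= dt[[3]])[1],
                      ": start >= end (1-based intervals?)")
      }
    } else if (fmt == "cytosine_report") {
      dt <- data.table::fread(path, nrows = 5)
      needed <- c("chrom", "pos", "strand", "context",
                  "count_methylated", "count_unmethylated")
      missing_cols <- setdiff(needed, names(dt))
      if (length(missing_cols)) {
        ok <- FALSE
        msg <- paste("missing column(s):",
                     paste(missing_cols, collapse = ", "))
      }
    }
    data.table::data.table(file = path, format = fmt, ok = ok,
                           message = msg)
  })
  data.table::rbindlist(rows)
}
utils::globalVariables(c("direction", "p_region", "ML", "ML_corrected",
                         "p_binomial", "ref_count_ctrl", "alt_count_ctrl",
                         "ref_count_treat", "alt_count_treat"))
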