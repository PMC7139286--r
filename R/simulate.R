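#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: a small
#' reference genome, a two-group bisulfite methylome with planted
#' differentially methylated regions (DMRs), allelic read counts at SNP
#' loci, 24-nt siRNA read placements, and a structured population with
#' phenotypes carrying known additive/dominance effects.
#'
#' Defaults emulate the study conditions of a short-term cytokinin
#' treatment experiment in poplar: three biological replicates per group,
#' ~30x cytosine coverage, bisulfite conversion rate 0.995, and baseline
#' methylation levels of 0.40 / 0.20 / 0.10 in the CG / CHG / CHH contexts
#' (typical plant leaf methylome orderings).
#'
#' @param seed Integer seed; all generators are deterministic given it.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (>= 1000).
#' @param gc_fraction GC content of the simulated genome.
#' @param baseline_ml Named vector of per-context true methylation levels
#'   (`CG`, `CHG`, `CHH`).
#' @param conversion_rate Bisulfite conversion rate `c`; unmethylated
#'   cytosines escape conversion (read methylated) with probability `1 - c`.
#' @param coverage_mean Mean per-site read coverage (Poisson).
#' @param n_replicates_per_group Biological replicates per group.
#' @param dmr_specs `data.frame(chrom, start, end, delta_ML)` of planted
#'   DMRs (0-based half-open; `delta_ML` signed, applied to the treated
#'   group).
#' @param ase_specs `data.frame(chrom, pos, f_ctrl, f_treat, depth)` of
#'   allelic loci with true ALT fractions per condition.
#' @param sirna_specs `data.frame(chrom, start, end, reads_ctrl,
#'   reads_treat)` of planted 24-nt siRNA clusters.
#' @param sirna_background_reads Uniformly scattered background 24-nt reads
#'   per library.
#' @param population List with `n_individuals`, `n_snps`, `maf_range`,
#'   `missing_rate`, `causal` (`data.frame(snp, a, d)` in trait units),
#'   `polygenic_var`, `residual_var`.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 1L,
                       chrom_length_bp = 100000L,
                       gc_fraction = 0.34,
                       baseline_ml = c(CG = 0.40, CHG = 0.20, CHH = 0.10),
                       conversion_rate = 0.995,
                       coverage_mean = 30,
                       n_replicates_per_group = 3L,
                       dmr_specs = NULL,
                       ase_specs = NULL,
                       sirna_specs = NULL,
                       sirna_background_reads = 0L,
                       population = list(n_individuals = 300L, n_snps = 100L,
                                         maf_range = c(0.1, 0.5),
                                         missing_rate = 0.05,
                                         causal = NULL,
                                         polygenic_var = 0.5,
                                         residual_var = 1)) {
  stopifnot(n_chrom >= 1L, chrom_length_bp >= 1000L)
  props <- c(gc_fraction, baseline_ml, conversion_rate)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  if (!all(c("CG", "CHG", "CHH") %in% names(baseline_ml)))
    stop("baseline_ml needs CG, CHG and CHH entries", call. = FALSE)
  if (!is.null(dmr_specs)) {
    dmr_specs <- data.table::as.data.table(dmr_specs)
    stopifnot(all(c("chrom", "start", "end", "delta_ML") %in%
                    names(dmr_specs)))
    if (any(dmr_specs$start < 0 | dmr_specs$end > chrom_length_bp |
              dmr_specs$start >= dmr_specs$end))
      stop("dmr_specs intervals outside chromosome bounds", call. = FALSE)
  }
  if (!is.null(ase_specs)) ase_specs <- data.table::as.data.table(ase_specs)
  if (!is.null(sirna_specs)) {
    sirna_specs <- data.table::as.data.table(sirna_specs)
    if (any(sirna_specs$end - sirna_specs$start < 24))
      stop("sirna cluster intervals must be >= 24 bp", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length_bp = as.integer(chrom_length_bp),
    gc_fraction = gc_fraction, baseline_ml = baseline_ml,
    conversion_rate = conversion_rate, coverage_mean = coverage_mean,
    n_replicates_per_group = as.integer(n_replicates_per_group),
    dmr_specs = dmr_specs, ase_specs = ase_specs,
    sirna_specs = sirna_specs,
    sirna_background_reads = as.integer(sirna_background_reads),
    population = population
  ), class = "sim_config")
}

# Distinct RNG streams per generator so each is reproducible regardless of
# the order generators are called in.
.sim_seed <- function(config, offset) {
  set.seed((config$seed * 101L + offset) %% .Machine$integer.max)
}

#' Simulate a reference genome
#'
#' Draws i.i.d. bases at the configured GC fraction; chromosomes are named
#' `chr1 ... chrN`.
#'
#' @param config A [sim_config()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 1L)
  gc <- config$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(config$n_chrom), function(i) {
    paste(sample(names(p), config$chrom_length_bp, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(config$n_chrom))
  out
}

# locate every cytosine (both strands) and its context, as a data.table
.genome_cytosines <- function(genome) {
  res <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    plus <- Biostrings::start(Biostrings::matchPattern("C", s))
    minus <- Biostrings::start(Biostrings::matchPattern("G", s))
    data.table::data.table(
      chrom = ch,
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus)))
    )
  })
  dt <- data.table::rbindlist(res)
  data.table::setorder(dt, chrom, pos, strand)
  dt
}

#' Simulate a two-group bisulfite methylome
#'
#' Emits per-sample cytosine-report-style counts for every cytosine in the
#' genome. True methylation level at a site is the per-context baseline;
#' inside a planted DMR the treated-group level is baseline + `delta_ML`.
#' Methylated cytosines always read methylated (bisulfite does not convert
#' 5mC); unmethylated cytosines escape conversion and read methylated with
#' probability `1 - conversion_rate`, so the observed methylated count is
#' `Binomial(coverage, pi + (1 - pi) * (1 - c))`. Coverage is
#' `Poisson(coverage_mean)`; low-coverage sites are still emitted (filtering
#' is the caller's job).
#'
#' @param genome A [Biostrings::DNAStringSet] from [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `records` (data.table: chrom, pos, strand, context, mC,
#'   umC, sample_id, group) and `truth` (planted DMR table with direction).
#' @export
simulate_methylome <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, 2L)
  sites <- .genome_cytosines(genome)
  suppressWarnings(
    sites[, context := classify_context(genome, chrom, pos, strand)]
  )
  sites <- sites[!is.na(context)]
  pi_base <- config$baseline_ml[sites$context]
  err <- 1 - config$conversion_rate

  dmrs <- config$dmr_specs
  pi_treat <- pi_base
  if (!is.null(dmrs)) {
    for (i in seq_len(nrow(dmrs))) {
      in_dmr <- sites$chrom == dmrs$chrom[i] &
        sites$pos > dmrs$start[i] & sites$pos <= dmrs$end[i]
      newpi <- pi_base[in_dmr] + dmrs$delta_ML[i]
      if (any(newpi < 0 | newpi > 1))
        stop("delta_ML pushes true methylation outside [0, 1]",
             call. = FALSE)
      pi_treat[in_dmr] <- newpi
    }
  }

  nrep <- config$n_replicates_per_group
  samples <- data.table::CJ(group = c("ctrl", "treat"), rep = seq_len(nrep))
  recs <- lapply(seq_len(nrow(samples)), function(k) {
    grp <- samples$group[k]
    pi <- if (grp == "treat") pi_treat else pi_base
    p_obs <- pi + (1 - pi) * err
    cov <- rpois(nrow(sites), config$coverage_mean)
    mC <- rbinom(nrow(sites), cov, p_obs)
    data.table::data.table(
      sites[, .(chrom, pos, strand, context)],
      mC = mC, umC = cov - mC,
      sample_id = paste0(grp, "_", samples$rep[k]), group = grp
    )
  })
  records <- data.table::rbindlist(recs)
  truth <- if (is.null(dmrs)) {
    data.table::data.table(chrom = character(), start = integer(),
                           end = integer(), delta_ML = numeric(),
                           direction = character())
  } else {
    data.table::data.table(dmrs,
                           direction = ifelse(dmrs$delta_ML > 0,
                                              "hyper", "hypo"))
  }
  list(records = records, truth = truth)
}

#' Simulate allelic read counts at SNP loci
#'
#' Each locus has a true ALT-allele fraction per condition; per replicate,
#' the ALT count is `Binomial(depth, f_condition)` and REF is the
#' remainder.
#'
#' @param config A [sim_config()] with `ase_specs`.
#' @return List with `counts` (data.table: chrom, pos, ref, alt, condition,
#'   replicate, ref_count, alt_count, qual) and `truth` (the spec table).
#' @export
simulate_allelic_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  specs <- config$ase_specs
  if (is.null(specs)) stop("config has no ase_specs", call. = FALSE)
  stopifnot(all(specs$depth >= 1))
  .sim_seed(config, 3L)
  nrep <- config$n_replicates_per_group
  grid <- data.table::CJ(locus = seq_len(nrow(specs)),
                         condition = c("ctrl", "treat"),
                         replicate = seq_len(nrep))
  f <- ifelse(grid$condition == "ctrl",
              specs$f_ctrl[grid$locus], specs$f_treat[grid$locus])
  depth <- specs$depth[grid$locus]
  alt <- rbinom(nrow(grid), depth, f)
  counts <- data.table::data.table(
    chrom = specs$chrom[grid$locus], pos = specs$pos[grid$locus],
    ref = "A", alt = "G",
    condition = grid$condition, replicate = grid$replicate,
    ref_count = depth - alt, alt_count = alt, qual = 60
  )
  data.table::setorder(counts, chrom, pos, condition, replicate)
  list(counts = counts, truth = data.table::copy(specs))
}

#' Simulate 24-nt siRNA read placements
#'
#' Reads are exactly 24 bp, placed uniformly within their planted cluster
#' interval; optional background reads are scattered uniformly over the
#' genome. One control and one treated library are emitted.
#'
#' @param genome Reference from [simulate_genome()].
#' @param config A [sim_config()] with `sirna_specs`.
#' @return List with `reads` (BED-like data.table: chrom, start, end, name,
#'   score, strand, library_id), `libraries` (library_id, group,
#'   total_mapped_reads) and `truth`.
#' @export
simulate_sirna_reads <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  specs <- config$sirna_specs
  if (is.null(specs)) stop("config has no sirna_specs", call. = FALSE)
  .sim_seed(config, 4L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  one_lib <- function(lib, col) {
    parts <- lapply(seq_len(nrow(specs)), function(i) {
      n <- specs[[col]][i]
      if (n == 0) return(NULL)
      start <- sample.int(specs$end[i] - specs$start[i] - 23L, n,
                          replace = TRUE) + specs$start[i] - 1L
      data.table::data.table(chrom = specs$chrom[i], start = start)
    })
    nbg <- config$sirna_background_reads
    if (nbg > 0) {
      ch <- sample(names(lens), nbg, replace = TRUE)
      parts <- c(parts, list(data.table::data.table(
        chrom = ch,
        start = vapply(ch, function(c2)
          sample.int(lens[[c2]] - 24L, 1L), integer(1)) - 1L
      )))
    }
    dt <- data.table::rbindlist(parts)
    dt[, `:=`(end = start + 24L,
              name = paste0(lib, "_r", seq_len(.N)),
              score = 0L, strand = "+", library_id = lib)]
    data.table::setorder(dt, chrom, start)
    dt
  }
  reads <- data.table::rbindlist(list(one_lib("ctrl_1", "reads_ctrl"),
                                      one_lib("treat_1", "reads_treat")))
  libraries <- data.table::data.table(
    library_id = c("ctrl_1", "treat_1"), group = c("ctrl", "treat"),
    total_mapped_reads = c(sum(reads$library_id == "ctrl_1"),
                           sum(reads$library_id == "treat_1"))
  )
  list(reads = reads, libraries = libraries,
       truth = data.table::copy(specs))
}

#' Simulate a structured population with phenotypes
#'
#' Genotypes are drawn in Hardy-Weinberg proportions at per-SNP minor
#' allele frequencies uniform in `maf_range`; missing genotypes are
#' missing-completely-at-random. Phenotypes follow
#' `y = mu + sum(x * a + het * d) + u + e`, where `x` is the 0/1/2 additive
#' coding, `het` the heterozygote indicator, `u` a polygenic term with
#' covariance proportional to the VanRaden genomic relationship matrix
#' built from the simulated genotypes themselves, and `e` Gaussian noise.
#'
#' @param config A [sim_config()] whose `population` block is set.
#' @return List with `genotypes` (individuals x SNPs matrix, 0/1/2/NA),
#'   `phenotypes` (data.table individual, trait), `truth` (causal SNPs with
#'   a and d), `maf` (true per-SNP MAF).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  popc <- config$population
  n <- popc$n_individuals; m <- popc$n_snps
  if (n < 50L) stop("need >= 50 individuals for association tests",
                    call. = FALSE)
  .sim_seed(config, 5L)
  maf <- runif(m, popc$maf_range[1], popc$maf_range[2])
  G <- vapply(seq_len(m), function(j) rbinom(n, 2L, maf[j]), integer(n))
  colnames(G) <- paste0("snp", seq_len(m))
  rownames(G) <- paste0("ind", seq_len(n))

  causal <- popc$causal
  y <- rep(0, n)
  if (!is.null(causal)) {
    causal <- data.table::as.data.table(causal)
    for (i in seq_len(nrow(causal))) {
      g <- G[, causal$snp[i]]
      y <- y + g * causal$a[i] + (g == 1L) * causal$d[i]
    }
  }
  if (isTRUE(popc$polygenic_var > 0)) {
    Z <- scale(G)
    Z[is.na(Z)] <- 0  # monomorphic columns
    u <- as.vector(Z %*% rnorm(m)) / sqrt(m) * sqrt(popc$polygenic_var)
    y <- y + u
  }
  if (isTRUE(popc$residual_var > 0))
    y <- y + rnorm(n, sd = sqrt(popc$residual_var))

  miss <- popc$missing_rate
  if (isTRUE(miss > 0)) {
    drop <- matrix(runif(n * m) < miss, n, m)
    G[drop] <- NA_integer_
  }
  truth <- if (is.null(causal)) {
    data.table::data.table(snp = character(), a = numeric(), d = numeric())
  } else causal
  list(genotypes = G,
       phenotypes = data.table::data.table(individual = rownames(G),
                                           trait = y),
       truth = truth, maf = maf)
}
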