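test_that("genome generator is deterministic with the right composition", {
  cfg <- sim_config(seed = 1, chrom_length_bp = 100000, gc_fraction = 0.5)
  g1 <- simulate_genome(cfg)
  expect_equal(length(g1), 1L)
  expect_equal(Biostrings::width(g1), 100000L)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  cfg2 <- sim_config(seed = 5, chrom_length_bp = 200000,
                     gc_fraction = 0.34)
  gc <- as.numeric(Biostrings::letterFrequency(
    simulate_genome(cfg2)[[1]], "GC", as.prob = TRUE))
  expect_gt(gc, 0.32); expect_lt(gc, 0.36)
  expect_error(sim_config(chrom_length_bp = 10), "chrom_length_bp")
})

test_that("methylome counts track the planted truth", {
  cfg <- sim_config(seed = 2, chrom_length_bp = 10000, coverage_mean = 30,
                    dmr_specs = data.frame(chrom = "chr1", start = 2000,
                                           end = 4000, delta_ML = 0.4),
                    baseline_ml = c(CG = 0.2, CHG = 0.2, CHH = 0.2))
  g <- simulate_genome(cfg)
  m <- simulate_methylome(g, cfg)
  expect_equal(nrow(m$truth), 1L)
  expect_equal(m$truth$direction, "hyper")
  rec <- m$records
  in_dmr <- rec$pos > 2000 & rec$pos <= 4000
  pooled <- function(x) sum(x$mC) / sum(x$mC + x$umC)
  diff_in <- pooled(rec[in_dmr & rec$group == "treat"]) -
    pooled(rec[in_dmr & rec$group == "ctrl"])
  expect_equal(diff_in, 0.4, tolerance = 0.05)
  # outside the DMR the groups agree
  diff_out <- pooled(rec[!in_dmr & rec$group == "treat"]) -
    pooled(rec[!in_dmr & rec$group == "ctrl"])
  expect_lt(abs(diff_out), 0.02)
})

test_that("perfect conversion and zero methylation emit no methylated reads", {
  cfg <- sim_config(seed = 3, chrom_length_bp = 5000,
                    conversion_rate = 1,
                    baseline_ml = c(CG = 0, CHG = 0, CHH = 0))
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  expect_equal(sum(m$records$mC), 0L)
})

test_that("delta pushing true methylation out of range errors", {
  cfg <- sim_config(seed = 4, chrom_length_bp = 5000,
                    dmr_specs = data.frame(chrom = "chr1", start = 0,
                                           end = 1000, delta_ML = 0.9),
                    baseline_ml = c(CG = 0.4, CHG = 0.2, CHH = 0.1))
  expect_error(simulate_methylome(simulate_genome(cfg), cfg), "\\[0, 1\\]")
})

test_that("allelic counts are binomial around the planted fractions", {
  cfg <- sim_config(seed = 5, n_replicates_per_group = 1,
                    ase_specs = data.frame(chrom = "chr1",
                                           pos = c(100, 200),
                                           f_ctrl = c(0.5, 1.0),
                                           f_treat = c(0.5, 1.0),
                                           depth = c(10000, 500)))
  a <- simulate_allelic_counts(cfg)
  bal <- a$counts[pos == 100 & condition == "ctrl"]
  expect_gt(bal$alt_count / (bal$alt_count + bal$ref_count), 0.48)
  expect_lt(bal$alt_count / (bal$alt_count + bal$ref_count), 0.52)
  expect_equal(a$counts[pos == 200]$ref_count, c(0, 0))  # f = 1
  expect_equal(nrow(a$truth), 2L)
})

test_that("planted differential ASE is detected downstream", {
  cfg <- sim_config(seed = 6, n_replicates_per_group = 1,
                    ase_specs = data.frame(chrom = "chr1", pos = 100,
                                           f_ctrl = 0.5, f_treat = 0.9,
                                           depth = 500))
  a <- simulate_allelic_counts(cfg)$counts
  res <- differential_ase(a[condition == "ctrl"]$ref_count,
                          a[condition == "ctrl"]$alt_count,
                          a[condition == "treat"]$ref_count,
                          a[condition == "treat"]$alt_count)
  expect_lt(res$p_diff, 0.05)
})

test_that("siRNA reads are 24 bp, conserved in number, inside clusters", {
  cfg <- sim_config(seed = 7, chrom_length_bp = 50000,
                    sirna_specs = data.frame(chrom = "chr1",
                                             start = c(1000, 30000),
                                             end = c(1300, 30100),
                                             reads_ctrl = c(50, 5),
                                             reads_treat = c(20, 5)))
  s <- simulate_sirna_reads(simulate_genome(cfg), cfg)
  ctrl <- s$reads[s$reads$library_id == "ctrl_1"]
  expect_equal(nrow(ctrl), 55L)
  expect_true(all(s$reads$end - s$reads$start == 24L))
  in1 <- ctrl[ctrl$start >= 1000 & ctrl$end <= 1300]
  expect_equal(nrow(in1), 50L)
  # the 5-read cluster stays below the downstream 10-read minimum
  called <- call_clusters(ctrl)
  expect_true(all(called$start < 2000))
})

test_that("population genotypes are Hardy-Weinberg and effects noiseless", {
  cfg <- sim_config(seed = 8, population = list(
    n_individuals = 10000, n_snps = 2, maf_range = c(0.3, 0.3),
    missing_rate = 0, causal = NULL, polygenic_var = 0,
    residual_var = 0))
  pop <- simulate_population(cfg)
  freq <- table(pop$genotypes[, 1]) / 10000
  expect_lt(max(abs(as.numeric(freq) - c(0.49, 0.42, 0.09))), 0.02)
  # noiseless construction: class means exactly mu + g*a + het*d
  cfg2 <- sim_config(seed = 9, population = list(
    n_individuals = 500, n_snps = 3, maf_range = c(0.3, 0.5),
    missing_rate = 0, causal = data.frame(snp = "snp2", a = 2, d = 0),
    polygenic_var = 0, residual_var = 0))
  pop2 <- simulate_population(cfg2)
  m <- tapply(pop2$phenotypes$trait, pop2$genotypes[, "snp2"], mean)
  expect_equal(unname(m["2"] - m["0"]), 4)
  expect_equal(unname(m["1"]), unname((m["0"] + m["2"]) / 2))
  expect_equal(nrow(pop2$truth), 1L)
})

test_that("every generator is byte-identical under a repeated seed", {
  cfg <- sim_config(seed = 42, chrom_length_bp = 5000,
                    ase_specs = data.frame(chrom = "chr1", pos = 10,
                                           f_ctrl = 0.5, f_treat = 0.7,
                                           depth = 100),
                    sirna_specs = data.frame(chrom = "chr1", start = 100,
                                             end = 400, reads_ctrl = 20,
                                             reads_treat = 10))
  expect_identical(simulate_methylome(simulate_genome(cfg), cfg),
                   simulate_methylome(simulate_genome(cfg), cfg))
  expect_identical(simulate_allelic_counts(cfg),
                   simulate_allelic_counts(cfg))
  g <- simulate_genome(cfg)
  expect_identical(simulate_sirna_reads(g, cfg),
                   simulate_sirna_reads(g, cfg))
  expect_identical(simulate_population(cfg), simulate_population(cfg))
})
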