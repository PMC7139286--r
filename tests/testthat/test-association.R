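make_geno <- function(n, mafs, seed = 1) {
  set.seed(seed)
  G <- vapply(mafs, function(p) rbinom(n, 2L, p), integer(n))
  colnames(G) <- paste0("snp", seq_along(mafs))
  rownames(G) <- paste0("ind", seq_len(n))
  G
}

test_that("SNP filtering applies MAF, missingness, and class-size rules", {
  set.seed(101)
  n <- 400L
  G <- make_geno(n, c(0.04, 0.05, 0.3, 0.3, 0.0), seed = 101)
  G[sample(n, 120), 4] <- NA  # 30% missing
  out <- filter_snps(G)
  st <- attr(out, "stats")
  expect_false(st$kept[st$snp == "snp1"])  # MAF < 0.05
  expect_true(st$kept[st$snp == "snp3"])
  expect_false(st$kept[st$snp == "snp4"])  # missing > 0.25
  expect_false(st$kept[st$snp == "snp5"])  # monomorphic
  # a SNP whose minor-homozygote class has < 3 carriers is dropped
  g_rare <- c(rep(0L, 380L), rep(1L, 18L), rep(2L, 2L))
  G2 <- cbind(G, snp6 = sample(g_rare))
  st2 <- attr(filter_snps(G2), "stats")
  expect_false(st2$kept[st2$snp == "snp6"])
})

test_that("the genomic relationship matrix is symmetric PSD", {
  G <- make_geno(100, runif(500, 0.1, 0.5), seed = 102)
  K <- grm(G)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # independent individuals: off-diagonal mean near zero
  off <- K[upper.tri(K)]
  expect_lt(abs(mean(off)), 0.02)
  # duplicated individuals show maximal pairwise relationship
  G2 <- rbind(G, G[1, , drop = FALSE])
  K2 <- grm(G2)
  expect_equal(K2[1, 101], K2[1, 1])
  expect_equal(max(K2[upper.tri(K2)]), K2[1, 101])
})

test_that("the mixed model reduces to OLS when kinship is identity", {
  set.seed(103)
  n <- 150L
  g <- rbinom(n, 2L, 0.3)
  y <- 0.3 * g + rnorm(n)
  res <- mlm_assoc(y, g, K = diag(n))
  fit1 <- lm(y ~ g + I(g == 1))
  fit0 <- lm(y ~ 1)
  f_ols <- anova(fit0, fit1)
  expect_equal(res$p_value, f_ols$`Pr(>F)`[2], tolerance = 1e-6)
  res_null <- mlm_assoc(y, g)  # K = NULL is the same limit
  expect_equal(res_null$p_value, res$p_value, tolerance = 1e-6)
  expect_error(mlm_assoc(y, rep(1L, n)), "genotype classes")
})

test_that("mixed-model p-values are uniform under a polygenic null", {
  cfg <- sim_config(seed = 104, population = list(
    n_individuals = 200, n_snps = 200, maf_range = c(0.1, 0.5),
    missing_rate = 0, causal = NULL, polygenic_var = 1,
    residual_var = 1))
  pop <- simulate_population(cfg)
  K <- grm(pop$genotypes)
  res <- assoc_scan(pop$phenotypes$trait, pop$genotypes, K = K)
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
})

test_that("a planted effect is detected with high power", {
  cfg <- sim_config(seed = 105, population = list(
    n_individuals = 300, n_snps = 50, maf_range = c(0.3, 0.3),
    missing_rate = 0,
    causal = data.frame(snp = "snp1", a = 1, d = 0),
    polygenic_var = 0.25, residual_var = 1))
  pop <- simulate_population(cfg)
  K <- grm(pop$genotypes)
  res <- mlm_assoc(pop$phenotypes$trait, pop$genotypes[, "snp1"], K = K)
  expect_lt(res$p_value, 0.001)
  expect_true(res$r_squared > 0 && res$r_squared < 1)
})

test_that("effect decomposition matches the stated class-mean formulas", {
  y <- c(rep(10, 30), rep(14, 30), rep(6, 30))
  g <- rep(c(2L, 1L, 0L), each = 30)  # AA=10, Aa=14, aa=6
  dec <- effect_decomposition(y, g)
  expect_equal(dec$a, 2)
  expect_equal(dec$d, 6)
  expect_equal(dec$d_over_a, 3)
  expect_true(dec$prominent_dominant)
  # pure additivity
  dec2 <- effect_decomposition(c(rep(10, 5), rep(8, 5), rep(6, 5)),
                               rep(c(2L, 1L, 0L), each = 5))
  expect_equal(dec2$d, 0)
  expect_false(dec2$prominent_dominant)
  # d/a exactly 2 is NOT prominent (strict inequality)
  dec3 <- effect_decomposition(c(rep(8, 5), rep(10, 5), rep(4, 5)),
                               rep(c(2L, 1L, 0L), each = 5))
  expect_equal(dec3$d_over_a, 2)
  expect_false(dec3$prominent_dominant)
  # a = 0 gives an infinite sentinel, prominent iff |d| > 0
  dec4 <- effect_decomposition(c(rep(5, 5), rep(9, 5), rep(5, 5)),
                               rep(c(2L, 1L, 0L), each = 5))
  expect_equal(dec4$d_over_a, Inf)
  expect_true(dec4$prominent_dominant)
  # class with < 3 individuals: NA decomposition
  dec5 <- effect_decomposition(1:10, c(rep(0L, 5), rep(1L, 3), 2L, 2L))
  expect_true(is.na(dec5$a))
})

test_that("q-values follow BH step-up with joint significance flags", {
  q <- qvalues(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(q$q_value, rep(0.04, 4))
  expect_equal(qvalues(rep(1, 5))$q_value, rep(1, 5))
  set.seed(106)
  p <- runif(50)
  qq <- qvalues(p)$q_value
  expect_true(all(diff(qq[order(p)]) >= -1e-12))  # monotone in sorted p
  # significance needs both p < 0.001 and q < 0.10
  q2 <- qvalues(c(1e-5, 0.005, rep(0.5, 8)))
  expect_equal(q2$significant, c(TRUE, rep(FALSE, 9)))
})

test_that("parameter recovery and additive-null dominance control", {
  # replicated recovery of planted a and d at n = 500, residual SD 1
  err_a <- err_d <- numeric(30)
  for (s in seq_len(30)) {
    cfg <- sim_config(seed = 106 + s, population = list(
      n_individuals = 500, n_snps = 20, maf_range = c(0.3, 0.5),
      missing_rate = 0,
      causal = data.frame(snp = "snp1", a = 1.0, d = 0.8),
      polygenic_var = 0, residual_var = 1))
    pop <- simulate_population(cfg)
    dec <- effect_decomposition(pop$phenotypes$trait,
                                pop$genotypes[, "snp1"])
    err_a[s] <- dec$a - 1.0
    err_d[s] <- dec$d - 0.8
  }
  expect_lt(abs(mean(err_a)), 0.15)  # unbiased recovery
  expect_lt(abs(mean(err_d)), 0.15)
  expect_gte(mean(abs(err_a) <= 0.15 & abs(err_d) <= 0.15), 0.8)
  # pure-additive loci (d = 0) rarely look prominent-dominant
  flags <- logical(0)
  for (s in seq_len(5)) {
    cfg2 <- sim_config(seed = 200 + s, population = list(
      n_individuals = 500, n_snps = 20, maf_range = c(0.25, 0.5),
      missing_rate = 0,
      causal = data.frame(snp = paste0("snp", 1:20), a = 0.75, d = 0),
      polygenic_var = 0, residual_var = 1))
    pop2 <- simulate_population(cfg2)
    flags <- c(flags, vapply(seq_len(20), function(j)
      isTRUE(effect_decomposition(pop2$phenotypes$trait,
                                  pop2$genotypes[, j])$prominent_dominant),
      logical(1)))
  }
  expect_lte(mean(flags), 0.05)
})
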