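test_that("window geometry pools sites into every covering window", {
  rec <- make_records(pos = c(50, 950), mC_ctrl = c(5, 5),
                      umC_ctrl = c(5, 5), mC_treat = c(5, 5),
                      umC_treat = c(5, 5))
  w <- enumerate_windows(rec)
  w0 <- w[w$start == 0]
  expect_equal(w0$n_sites, 2L)
  w100 <- w[w$start == 100]
  expect_equal(w100$n_sites, 1L)  # only pos 950 remains
  expect_true(all(w$end - w$start == 1000L))
  # empty input yields zero windows
  expect_equal(nrow(enumerate_windows(rec[0, ])), 0L)
})

test_that("streaming window enumeration equals brute force", {
  set.seed(21)
  for (rep in 1:5) {
    pos <- sort(sample(10000L, 150))
    sites <- data.frame(pos = pos,
                        mC_ctrl = rpois(150, 5), umC_ctrl = rpois(150, 8),
                        mC_treat = rpois(150, 5), umC_treat = rpois(150, 8))
    # keep only sites eligible in both groups, as the enumerator requires
    elig <- (sites$mC_ctrl + sites$umC_ctrl) >= 5 &
      (sites$mC_treat + sites$umC_treat) >= 5
    sites <- sites[elig, ]
    rec <- make_records(sites$pos, sites$mC_ctrl, sites$umC_ctrl,
                        sites$mC_treat, sites$umC_treat)
    got <- enumerate_windows(rec)
    want <- bf_windows(sites)
    expect_equal(got$start, want$start)
    expect_equal(got$n_sites, want$n_sites)
    expect_equal(got$mC_ctrl, want$mC_ctrl)
    expect_equal(got$umC_treat, want$umC_treat)
  }
})

test_that("unsorted records are rejected rather than silently re-sorted", {
  rec <- make_records(pos = c(950, 50), mC_ctrl = c(5, 5),
                      umC_ctrl = c(5, 5), mC_treat = c(5, 5),
                      umC_treat = c(5, 5))
  expect_error(enumerate_windows(rec), "sorted")
})

test_that("window Fisher test matches the exact test", {
  w <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                              n_sites = 1L,
                              mC_ctrl = c(10L, 10L, 0L),
                              umC_ctrl = c(90L, 90L, 5L),
                              mC_treat = c(10L, 30L, 5L),
                              umC_treat = c(90L, 70L, 0L))
  p <- window_test(w)$p_fisher
  expect_equal(p[1], 1)
  expect_equal(p[2], fisher.test(matrix(c(10, 90, 30, 70), 2,
                                        byrow = TRUE))$p.value)
  expect_equal(p[2], 5.6e-4, tolerance = 0.02)
  expect_equal(p[3], 1 / 126, tolerance = 1e-10)
  # empty margin gives p = 1 with a warning
  w0 <- data.table::data.table(chrom = "chr1", start = 0L, end = 1000L,
                               n_sites = 1L, mC_ctrl = 0L, umC_ctrl = 0L,
                               mC_treat = 3L, umC_treat = 4L)
  expect_warning(p0 <- window_test(w0)$p_fisher, "margin")
  expect_equal(p0, 1)
})

test_that("significant-window merging equals a union oracle", {
  mkw <- function(start, p) data.table::data.table(
    chrom = "chr1", start = start, end = start + 1000L, p_fisher = p)
  m <- merge_significant(mkw(c(0L, 100L), c(0.01, 0.01)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 1100L))
  m2 <- merge_significant(mkw(c(0L, 5000L), c(0.01, 0.01)))
  expect_equal(nrow(m2), 2L)
  # random significance patterns against pairwise-merge oracle
  set.seed(31)
  for (rep in 1:5) {
    starts <- sort(sample(seq(0L, 20000L, by = 100L), 200))
    p <- runif(200)
    got <- merge_significant(mkw(starts, p))
    sig <- data.frame(start = starts[p < 0.05],
                      end = starts[p < 0.05] + 1000L)
    want <- bf_merge(sig)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # merged regions are pairwise disjoint
    expect_true(all(diff(got$start) > (got$end - got$start)[-nrow(got)] |
                      diff(got$start) >= 0))
    expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("region ANOVA separates groups and equals the squared t test", {
  sites <- data.table::data.table(
    chrom = "chr1", pos = c(100, 200, 300),
    mC_ctrl = c(1L, 1L, 1L), umC_ctrl = c(9L, 9L, 9L),
    mC_treat = c(9L, 9L, 9L), umC_treat = c(1L, 1L, 1L))
  region <- list(chrom = "chr1", start = 0L, end = 1000L)
  dmr <- region_filter(region, sites)
  expect_false(is.null(dmr))
  expect_equal(dmr$direction, "hyper")
  # identical group levels: zero between-group variance, rejected
  sites_null <- data.table::copy(sites)[, `:=`(mC_treat = mC_ctrl,
                                               umC_treat = umC_ctrl)]
  expect_null(region_filter(region, sites_null))
  # F equals the squared two-sample t statistic
  set.seed(41)
  x <- runif(8, 0.1, 0.3); y <- runif(8, 0.4, 0.9)
  f <- methlink:::.anova_two_group(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(f$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(f$p, tt$p.value, tolerance = 1e-10)
})

test_that("planted DMRs are recovered with correct direction", {
  cfg <- sim_config(
    seed = 51, chrom_length_bp = 60000, coverage_mean = 30,
    baseline_ml = c(CG = 0.3, CHG = 0.3, CHH = 0.3),
    dmr_specs = data.frame(chrom = "chr1",
                           start = c(10000, 40000),
                           end = c(12000, 42000),
                           delta_ML = c(0.4, -0.25)))
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  dmrs <- call_dmrs(m$records, r = 1 - cfg$conversion_rate)
  hit1 <- dmrs[dmrs$start < 12000 & dmrs$end > 10000]
  hit2 <- dmrs[dmrs$start < 42000 & dmrs$end > 40000]
  expect_equal(nrow(hit1), 1L)
  expect_equal(hit1$direction, "hyper")
  expect_equal(nrow(hit2), 1L)
  expect_equal(hit2$direction, "hypo")
  expect_true(all(dmrs$length_bp >= 100L))
})

test_that("a null methylome stays near the nominal false-positive rate", {
  cfg <- sim_config(seed = 52, chrom_length_bp = 50000,
                    coverage_mean = 30,
                    baseline_ml = c(CG = 0.3, CHG = 0.3, CHH = 0.3))
  m <- simulate_methylome(simulate_genome(cfg), cfg)
  dmrs <- call_dmrs(m$records, r = 1 - cfg$conversion_rate)
  # ~490 windows at alpha 0.05, merged and ANOVA-filtered: expect few
  expect_lte(nrow(dmrs), 25L)
})
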