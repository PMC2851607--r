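region_from_calls <- function(calls, min_individuals = 1) {
  cover_regions(calls, conf_cutoff = 0, min_individuals = min_individuals,
                state = "combined")
}

test_that("loss regions map copy numbers 0/1/2 onto genotype counts", {
  samples <- sprintf("S%d", 1:10)
  # 2 hom losses, 3 het losses, 5 diploid
  calls <- new_cnv_calls(samples[1:5], "1", 100L, 900L,
                         c(0L, 0L, 1L, 1L, 1L), 10)
  regs <- region_from_calls(calls)
  g <- genotype_region(regs[1, ], calls, samples)
  expect_equal(g$allelicity, "diallelic-loss")
  expect_equal(g$counts, c(n_ref_hom = 5, n_het = 3, n_var_hom = 2))
  expect_equal(g$maf, (2 * 2 + 3) / 20)
})

test_that("gain regions map copy numbers 2/3/4 with 4 as variant homozygote", {
  samples <- sprintf("S%d", 1:6)
  calls <- new_cnv_calls(samples[1:3], "1", 100L, 900L,
                         c(4L, 3L, 3L), 10)
  g <- genotype_region(region_from_calls(calls)[1, ], calls, samples)
  expect_equal(g$allelicity, "diallelic-gain")
  expect_equal(g$counts, c(n_ref_hom = 3, n_het = 2, n_var_hom = 1))
})

test_that("mixed loss and gain forces multiallelic, excluded from testing", {
  samples <- sprintf("S%d", 1:6)
  calls <- new_cnv_calls(samples[1:3], "1", 100L, 900L,
                         c(1L, 2L + 1L, 1L), 10)
  g <- genotype_region(region_from_calls(calls)[1, ], calls, samples)
  expect_equal(g$allelicity, "multiallelic")
  expect_null(g$counts)
  groups <- data.frame(sample_id = samples, group = "G", unrelated = TRUE)
  expect_error(violation_rate(list(g), groups), "no diallelic")
})

test_that("samples without a supporting call are diploid", {
  samples <- sprintf("S%d", 1:4)
  calls <- new_cnv_calls("S9", "1", 100L, 900L, 1L, 10)
  regs <- region_from_calls(calls)
  g <- genotype_region(regs[1, ], calls, samples)
  expect_equal(unname(g$cn), rep(2L, 4))
  expect_equal(g$counts, c(n_ref_hom = 4, n_het = 0, n_var_hom = 0))
  expect_equal(g$maf, 0)
})

test_that("the region copy number follows the largest-overlap call", {
  samples <- "S1"
  calls <- suppressWarnings(new_cnv_calls(
    c("S1", "S1"), "1", c(100L, 100L), c(700L, 280L), c(1L, 0L), c(5, 50)))
  regs <- suppressWarnings(
    cover_regions(calls, probes = new_probe_map(list(`1` = c(100L, 400L,
                                                             700L))),
                  conf_cutoff = 0, min_individuals = 1))
  # region [100,700]: CN-1 call covers 601 bases, CN-0 covers 181
  g <- suppressWarnings(genotype_region(regs[1, ], calls, samples))
  expect_equal(unname(g$cn), 1L)
})

test_that("exact test matches the spot values", {
  expect_equal(hwe_test(counts_vec(25, 50, 25)), 1, tolerance = 1e-6)
  expect_lt(hwe_test(counts_vec(0, 100, 0)), 1e-15)
  expect_equal(hwe_test(counts_vec(89, 10, 1)),
               oracle_hwe_exact(89, 10, 1))
})

test_that("exact p-values equal full enumeration for all n <= 50", {
  set.seed(42)
  for (rep in 1:150) {
    n <- sample(1:50, 1)
    n_var <- sample(0:n, 1)
    n_het <- sample(0:(n - n_var), 1)
    n_ref <- n - n_var - n_het
    got <- hwe_test(counts_vec(n_ref, n_het, n_var))
    want <- oracle_hwe_exact(n_ref, n_het, n_var)
    expect_equal(got, want, tolerance = 1e-10,
                 info = sprintf("(%d,%d,%d)", n_ref, n_het, n_var))
  }
})

test_that("the test is invariant to swapping homozygote labels", {
  set.seed(99)
  for (rep in 1:30) {
    n_ref <- sample(0:40, 1); n_het <- sample(0:40, 1)
    n_var <- sample(0:40, 1)
    if (n_ref + n_het + n_var == 0) next
    expect_equal(hwe_test(counts_vec(n_ref, n_het, n_var)),
                 hwe_test(counts_vec(n_var, n_het, n_ref)))
    expect_equal(hwe_test(counts_vec(n_ref, n_het, n_var), "chisq"),
                 hwe_test(counts_vec(n_var, n_het, n_ref), "chisq"))
  }
})

test_that("monomorphic counts give p = 1 under both methods", {
  expect_equal(hwe_test(counts_vec(30, 0, 0)), 1)
  expect_equal(hwe_test(counts_vec(0, 0, 30)), 1)
  expect_equal(hwe_test(counts_vec(30, 0, 0), "chisq"), 1)
})

test_that("chi-square agrees with the asymptotic regime at large n", {
  # strongly out of HWE: both methods must reject decisively
  expect_lt(hwe_test(counts_vec(500, 0, 500), "chisq"), 1e-10)
  expect_lt(hwe_test(counts_vec(500, 0, 500), "exact"), 1e-10)
})

test_that("violation rate counts regions failing in at least one group", {
  samples <- sprintf("S%d", 1:40)
  groups <- data.frame(sample_id = samples,
                       group = rep(c("G1", "G2"), each = 20),
                       unrelated = TRUE)
  # region violating HWE wildly in G1 only (all G1 carriers heterozygous)
  calls_bad <- new_cnv_calls(samples[1:20], "1", 100L, 900L, 1L, 10)
  # region near HWE everywhere
  calls_ok <- new_cnv_calls(samples[c(1, 21)], "2", 100L, 900L,
                            c(0L, 0L), 10)
  calls <- validate_cnv_calls(rbind(as.data.frame(calls_bad)[1:6],
                                    as.data.frame(calls_ok)[1:6]))
  regs <- region_from_calls(calls)
  gt <- lapply(seq_len(nrow(regs)), function(i) {
    genotype_region(regs[i, ], calls, samples)
  })
  vr <- violation_rate(gt, groups, alpha = 0.01)
  expect_equal(vr$n_diallelic, 2L)
  expect_equal(vr$n_violating, 1L)
  expect_equal(vr$rate, 0.5)
})

test_that("monomorphic regions never violate", {
  samples <- sprintf("S%d", 1:10)
  groups <- data.frame(sample_id = samples, group = "G", unrelated = TRUE)
  calls <- new_cnv_calls("S99", "1", 100L, 900L, 1L, 10)
  g <- genotype_region(region_from_calls(calls)[1, ], calls, samples)
  vr <- violation_rate(list(g, g, g), groups)
  expect_equal(vr$rate, 0)
})

test_that("related samples are excluded from the group counts", {
  samples <- sprintf("S%d", 1:30)
  groups <- data.frame(sample_id = samples, group = "G",
                       unrelated = c(rep(TRUE, 10), rep(FALSE, 20)))
  # all 20 related samples are het carriers: would fail HWE if included
  calls <- new_cnv_calls(samples[11:30], "1", 100L, 900L, 1L, 10)
  g <- genotype_region(region_from_calls(calls)[1, ], calls, samples)
  vr <- violation_rate(list(g), groups)
  expect_equal(vr$rate, 0)  # unrelated subset is all-diploid, p = 1
})

test_that("violation rate is calibrated near alpha on HWE-simulated loci", {
  grid <- make_toy_fixture("hwe_grid", seed = 20260928)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    hwe_test(counts_vec(grid$n_ref_hom[i], grid$n_het[i], grid$n_var_hom[i]))
  }, numeric(1))
  rate <- mean(p < 0.01)
  expect_gte(rate, 0.004)
  expect_lte(rate, 0.02)
})

test_that("tune_thresholds tabulates the grid and flags the steepest drop", {
  loci <- random_locus_spec(6, seed = 3, maf_range = c(0.2, 0.4))
  sim <- simulate_population(loci, c(G1 = 30, G2 = 30), noise_rate = 0.3,
                             seed = 3)
  one <- tune_thresholds(sim$calls, NULL, sim$groups,
                         grid = data.frame(percentile = 20, u = 2),
                         method = "cover")
  expect_equal(nrow(one), 1L)
  expect_false(any(one$steepest_drop))
  expect_gt(one$n_regions, 0L)

  tab <- tune_thresholds(sim$calls, NULL, sim$groups,
                         grid = data.frame(percentile = c(0, 50, 100), u = 2),
                         method = "cover")
  expect_equal(nrow(tab), 3L)
  # percentile 100 keeps only the top-confidence call: no region at u = 2
  expect_true(all(c("n_regions", "violation_rate", "mean_maf",
                    "median_size_kb", "steepest_drop") %in% names(tab)))
  comp <- tune_thresholds(sim$calls, NULL, sim$groups, grid = c(50, 99.9),
                          method = "composite")
  expect_equal(nrow(comp), 2L)
})

test_that("a grid point filtering out all calls reports zero regions", {
  calls <- new_cnv_calls(c("S1", "S2", "S3"), "1", 100L, 900L, 1L,
                         c(5, 5, 5))
  groups <- data.frame(sample_id = c("S1", "S2", "S3"), group = "G",
                       unrelated = TRUE)
  tab <- tune_thresholds(calls, NULL, groups,
                         grid = data.frame(percentile = c(0, 0), u = c(1, 4)),
                         method = "cover")
  expect_equal(tab$n_regions, c(1L, 0L))
  expect_true(is.na(tab$violation_rate[2]))
})
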