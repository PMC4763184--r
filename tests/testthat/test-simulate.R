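test_that("PAF-to-GRR relation reproduces its closed-form anchors", {
  expect_equal(grr_from_paf(0.003, 0.01), 1 + 0.003 / (0.01 * 0.997), tolerance = 1e-12)
  expect_equal(round(grr_from_paf(0.003, 0.01), 1), 1.3)
  expect_equal(round(grr_from_paf(0.005, 0.01), 1), 1.5)
  expect_equal(grr_from_paf(0, 0.01), 1)
  expect_equal(grr_from_paf(0.003, 0.01, protective = TRUE),
               1 / grr_from_paf(0.003, 0.01))
  expect_error(grr_from_paf(1, 0.01), "paf")
  expect_error(grr_from_paf(0.1, 0), "maf")
})

test_that("penetrance is multiplicative across carried causal alleles and capped", {
  h0 <- rep(0L, 5)
  h1 <- c(1L, 0L, 0L, 0L, 0L)
  expect_equal(penetrance(h0, h0, causal_sites = 1, grrs = 1.3, f0 = 0.01), 0.01)
  expect_equal(penetrance(h1, h0, causal_sites = 1, grrs = 1.3, f0 = 0.01), 0.013)
  expect_equal(penetrance(h1, h1, causal_sites = 1, grrs = 1.3, f0 = 0.01),
               0.01 * 1.3^2)
  expect_equal(penetrance(h1, h1, causal_sites = 1, grrs = 50, f0 = 0.01), 1)
})

test_that("haplotype pools round-trip through the plain-text format", {
  H <- rbind(c(1L, 0L, 1L), c(0L, 0L, 1L), c(0L, 1L, 1L), c(0L, 0L, 0L))
  pool <- structure(list(haplotypes = H, positions = c(10L, 250L, 900L),
                         population_mafs = pmin(colMeans(H), 1 - colMeans(H)),
                         region_length = 1000),
                    class = "haplotype_pool")
  path <- tempfile(fileext = ".txt")
  write_haplotypes(pool, path)
  p2 <- read_haplotypes(path)
  expect_equal(p2$haplotypes, unname(H))
  expect_equal(p2$positions, pool$positions)
  # population MAF is plain allele counting (1 carrier in 4 haplotypes)
  expect_equal(p2$population_mafs[1], 0.25)
})

test_that("causal designation follows the rounding-up rule and the rare cutoff", {
  sc <- sim_scenario(causal_fraction = 0.25, r_isk = 0.05)
  pool <- generate_pool(sc, seed = 3)
  n_rare <- sum(pool$population_mafs < sc$rare_cutoff & pool$population_mafs > 0)
  # force exactly 14 causal variants, then r_isk = 0.05 -> ceiling(0.7) = 1
  sc14 <- sim_scenario(causal_fraction = 14 / n_rare, r_isk = 0.05)
  pool14 <- assign_causal(pool, sc14, seed = 4)
  expect_equal(nrow(pool14$causal), 14L)
  expect_equal(sum(pool14$causal$risk), 1L)
  expect_true(all(pool14$causal$maf < 0.01))
  # boundary fractions of risk variants
  pool_all <- assign_causal(pool, sim_scenario(causal_fraction = 0.25, r_isk = 1), seed = 4)
  expect_true(all(pool_all$causal$risk))
  pool_none <- assign_causal(pool, sim_scenario(causal_fraction = 0.25, r_isk = 0), seed = 4)
  expect_false(any(pool_none$causal$risk))
  # protective causal variants get the reciprocal effect size
  expect_true(all(pool_none$causal$grr < 1))
  expect_true(all(pool_all$causal$grr > 1))
})

test_that("generated pools have a rare-heavy folded site frequency spectrum", {
  sc <- sim_scenario()
  counts <- c(rare = 0, low = 0, mid = 0, common = 0)
  for (s in 1:5) {
    pool <- generate_pool(sc, seed = 200 + s)
    f <- pool$population_mafs
    counts <- counts + c(sum(f < 0.001), sum(f >= 0.001 & f < 0.01),
                         sum(f >= 0.01 & f < 0.1), sum(f >= 0.1))
  }
  # per-unit-frequency density must decrease across the folded bins
  dens <- counts / c(0.001, 0.009, 0.09, 0.4)
  expect_true(all(diff(dens) < 0))
})

test_that("case-control sampling: determinism, enrichment, and boundary errors", {
  sc <- sim_scenario(causal_fraction = 0.25, paf = 0.01, r_isk = 1,
                     n_cases = 120, n_controls = 120)
  pool <- generate_pool(sc, seed = 11)
  pool <- assign_causal(pool, sc, seed = 12)
  r1 <- sample_case_control(pool, sc, seed = 13)
  r2 <- sample_case_control(pool, sc, seed = 13)
  expect_identical(r1$region$dosage, r2$region$dosage)
  expect_identical(r1$n_draws, r2$n_draws)
  expect_true(all(r1$risk_ids %in% r1$causal_ids))
  expect_true(all(r1$region$variants$maf_population < sc$analysis_cutoff))
  # cases carry more risk alleles than controls on average (one-sided)
  diffs <- vapply(1:15, function(i) {
    rep_i <- sample_case_control(pool, sc, seed = 100 + i)
    g <- rep_i$region
    risk_cols <- g$variants$id %in% rep_i$risk_ids
    if (!any(risk_cols)) return(NA_real_)
    mean(g$dosage[g$phenotype == 1, risk_cols, drop = FALSE]) -
      mean(g$dosage[g$phenotype == 0, risk_cols, drop = FALSE])
  }, numeric(1))
  expect_gt(mean(diffs > 0, na.rm = TRUE), 0.5)
  expect_gt(mean(diffs, na.rm = TRUE), 0)
  # baseline penetrance 1 leaves no controls to sample
  sc_bad <- sim_scenario(causal_fraction = 0, f0 = 1)
  expect_error(sample_case_control(pool, sc_bad, seed = 1), "control quota")
  # non-null scenarios require causal assignment first
  pool_raw <- generate_pool(sim_scenario(), seed = 44)
  expect_error(sample_case_control(pool_raw, sc, seed = 1), "assign_causal")
})

test_that("an unmutated pool is regenerated and eventually refused", {
  sc <- sim_scenario(pool_size = 20, theta_per_kb = 1e-9)
  expect_error(
    suppressMessages(generate_pool(sc, seed = 5)),
    "failed to generate"
  )
})
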