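test_that("carrier-table reconstruction reproduces published allele counts exactly", {
  g <- angptl4_example()
  expect_equal(n_samples(g), 400L)
  expect_equal(n_variants(g), 17L)
  y <- g$phenotype
  x_case <- as.integer(crossprod(g$dosage, y))
  x_ctrl <- as.integer(colSums(g$dosage)) - x_case
  tbl <- read_carrier_table(
    system.file("extdata", "angptl4_carriers.tsv", package = "rarepinpoint")
  )
  expect_equal(x_case, tbl$carriers_cases)   # all carriers heterozygous
  expect_equal(x_ctrl, tbl$carriers_controls)
  # E40K: 1 of 396 case alleles, 8 of 404 control alleles
  e40k <- which(g$variants$id == "E40K")
  expect_equal(x_case[e40k], 1L)
  expect_equal(x_ctrl[e40k], 8L)
  expect_true(all(g$dosage %in% c(0L, 1L)))
  # disjoint carriers: no sample carries two different variants
  expect_lte(max(rowSums(g$dosage)), 1L)
})

test_that("carrier-table edge cases: all-zero table and pigeonhole infeasibility", {
  empty <- carrier_table(
    data.frame(variant_id = c("a", "b"), position = 1:2,
               carriers_cases = c(0L, 0L), carriers_controls = c(0L, 0L)),
    n_cases = 5, n_controls = 5
  )
  g0 <- from_carrier_table(empty)
  expect_true(all(g0$dosage == 0L))
  over <- carrier_table(
    data.frame(variant_id = c("a", "b"), position = 1:2,
               carriers_cases = c(198L, 1L), carriers_controls = c(0L, 0L)),
    n_cases = 198, n_controls = 202
  )
  expect_error(from_carrier_table(over), "infeasible")
})

test_that("dosage tables round-trip bit-exactly", {
  set.seed(42)
  d <- matrix(sample(c(0L, 1L, 2L, NA), 50, replace = TRUE,
                     prob = c(.55, .25, .1, .1)), 10, 5)
  d[, 1] <- c(rep(1L, 6), rep(0L, 4))   # keep column 1 oriented & polymorphic
  g <- region_genotypes(d, rep(c(1L, 0L), 5))
  path <- tempfile(fileext = ".tsv")
  write_dosage_table(g, path)
  g2 <- read_dosage_table(path)
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$phenotype, g2$phenotype)
  expect_identical(g$variants$maf_pooled, g2$variants$maf_pooled)
  # reconstruction round-trip for the worked example
  ga <- angptl4_example()
  write_dosage_table(ga, path)
  expect_identical(read_dosage_table(path)$dosage, ga$dosage)
  # domain violation: dosage 3
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tphenotype\tv1", "s1\t1\t3", "s2\t0\t1"), bad)
  expect_error(read_dosage_table(bad), "0, 1, 2")
})

test_that("VCF parsing: dosages, minor-allele orientation, multiallelic rejection", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tsiteA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsiteB\tC\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1"
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_vcf(path, phenotype = c(1, 1, 0))
  # siteA: ALT is minor -> dosages 0,1,2
  expect_equal(unname(g$dosage[, "siteA"]), c(0L, 1L, 2L))
  # siteB: ALT frequency 5/6 -> REF is the minor allele, dosage = 2 - alt count
  expect_equal(unname(g$dosage[, "siteB"]), c(0L, 0L, 1L))
  expect_lte(max(g$variants$maf_pooled), 0.5)
  # single het sample at one site
  vcf1 <- c(vcf[1:3], "1\t100\tX\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0")
  writeLines(vcf1, path)
  expect_equal(sum(read_vcf(path, phenotype = c(1, 0, 0))$dosage), 1L)
  # multiallelic dropped with warning; nothing left -> error
  vcfm <- c(vcf[1:3],
            "1\t100\tM\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/2",
            "1\t300\tK\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.\t0/0")
  writeLines(vcfm, path)
  expect_warning(g2 <- read_vcf(path, phenotype = c(1, 1, 0)), "multiallelic")
  expect_equal(n_variants(g2), 1L)
  expect_true(is.na(g2$dosage[2, "K"]))
  expect_error(suppressWarnings(read_vcf(path, phenotype = c(1, 1, 0),
                                         region = c(1000, 2000))),
               "no biallelic variants")
})

test_that("missingness filter drops variants first, then incomplete samples", {
  d <- matrix(0L, 10, 3)
  d[, 1] <- c(1L, rep(0L, 9))
  d[, 2] <- c(0L, 1L, rep(0L, 8))
  d[1:2, 3] <- NA                       # 20% missing
  g <- region_genotypes(d, rep(c(1L, 0L), 5))
  # threshold 0.25: variant kept, the 2 samples with missing entries dropped
  f <- filter_missing(g, 0.25)
  expect_equal(n_variants(f), 3L)
  expect_equal(n_samples(f), 8L)
  # threshold 0.10: variant dropped, all samples kept
  f2 <- filter_missing(g, 0.10)
  expect_equal(n_variants(f2), 2L)
  expect_equal(n_samples(f2), 10L)
  # a variant missing in 14.3% of samples is dropped at the default threshold
  d3 <- matrix(c(rep(0L, 12), 1L, 0L), 14, 1)
  d3[1:2, 1] <- NA                      # 2/14 = 14.3%
  g3 <- region_genotypes(cbind(d3, c(1L, rep(0L, 13))), rep(c(1L, 0L), 7))
  expect_equal(n_variants(filter_missing(g3)), 1L)
  # complete data returned unchanged
  gc <- filter_missing(angptl4_example())
  expect_identical(gc, angptl4_example())
})

test_that("analysis-set filter: strict bounds, monomorphic removal, idempotence", {
  n <- 100
  d <- cbind(
    rep(0L, n),                                  # monomorphic
    c(rep(1L, 10), rep(0L, n - 10)),             # maf exactly 0.05
    c(rep(1L, 4), rep(0L, n - 4)),               # maf 0.02
    c(rep(2L, 30), rep(1L, 20), rep(0L, n - 50)) # common
  )
  g <- region_genotypes(d, rep(c(1L, 0L), n / 2))
  f <- filter_analysis_set(g)
  expect_equal(f$variants$id, "v3")
  expect_identical(filter_analysis_set(f), f)    # idempotent
  # all 17 ANGPTL4 variants pass at the 5% cutoff
  expect_equal(n_variants(filter_analysis_set(angptl4_example())), 17L)
})

test_that("beta weights follow the Beta density and its domain", {
  expect_equal(beta_weights(c(0.1, 0.4, 0.25), a = 1, b = 1), rep(1, 3))
  expect_equal(beta_weights(0.01), 25 * 0.99^24, tolerance = 1e-12)
  grid <- seq(0.001, 0.05, by = 0.001)
  expect_true(all(diff(beta_weights(grid)) < 0))
  expect_error(beta_weights(0), "strictly")
  expect_error(beta_weights(1), "strictly")
})
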