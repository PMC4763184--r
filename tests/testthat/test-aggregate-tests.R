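test_that("score components match hand arithmetic on a 6-sample fixture", {
  d <- matrix(c(2L, 1L, 0L, 1L, 0L, 0L), ncol = 1)
  y <- c(1L, 1L, 1L, 0L, 0L, 0L)
  g <- region_genotypes(d, y)
  comp <- score_components(g, weights = 1)
  # U = sum G_i (y_i - 1/2) = (2 + 1 + 0)*(1/2) + (1 + 0 + 0)*(-1/2) = 1
  expect_equal(comp$U, 1)
  # V = 1/4 * sum (G_i - Gbar)^2, Gbar = 2/3
  expect_equal(comp$V[1, 1], 0.25 * sum((d - mean(d))^2))
})

test_that("scores are centred and their covariance matches permutations", {
  g <- random_region(n = 40, mafs = c(0.2, 0.35), seed = 8)
  comp <- score_components(g)
  set.seed(12)
  B <- 4000
  U <- replicate(B, {
    yp <- sample(g$phenotype)
    as.vector(crossprod(comp$Ac, yp - mean(yp)))
  })
  expect_lt(max(abs(rowMeans(U))), 4 * max(sqrt(diag(comp$V) / B)))
  emp_cov <- tcrossprod(U - rowMeans(U)) / B
  expect_lt(max(abs(emp_cov - comp$V)) / max(abs(comp$V)), 0.15)
})

test_that("asymptotic SKAT and burden tails agree with the permutation oracle", {
  # calibration: applying the asymptotic tail to thousands of permuted
  # datasets must reproduce uniform P-values at the working significance
  # levels (the permutation distribution has atoms of a few percent on a
  # 50-sample fixture, so pointwise central agreement is not attainable;
  # what matters is that the tail transformation is calibrated)
  for (seed in 1:2) {
    g <- random_region(n = 50, mafs = c(0.2, 0.25, 0.3, 0.4), seed = seed)
    comp <- score_components(g, weights = rep(1, 4))
    lam <- eigen(comp$V, symmetric = TRUE, only.values = TRUE)$values
    varT <- sum(comp$V)
    set.seed(seed + 500)
    B <- 3000
    p_skat <- p_burd <- numeric(B)
    for (b in seq_len(B)) {
      yp <- sample(g$phenotype)
      u <- as.vector(crossprod(comp$Ac, yp - mean(yp)))
      p_skat[b] <- liu_tail_cpp(sum(u^2), lam)
      p_burd[b] <- pchisq(sum(u)^2 / varT, 1, lower.tail = FALSE)
    }
    for (alpha in c(0.05, 0.10)) {
      expect_lt(abs(mean(p_skat <= alpha) - alpha), 0.035)
      expect_lt(abs(mean(p_burd <= alpha) - alpha), 0.035)
    }
  }
  # in the tail (an enriched fixture) agreement is much tighter in absolute
  # terms: this is the regime the tests are used in
  set.seed(99)
  d <- sapply(c(0.1, 0.15, 0.2), function(f) rbinom(50, 2, f))
  d[1:10, 1] <- 2L                      # strong case enrichment
  g <- region_genotypes(d, rep(c(1L, 0L), each = 25))
  comp <- score_components(g, weights = rep(1, 3))
  for (m in c("skat", "burden")) {
    fit <- if (m == "skat") skat_test(comp, small_sample = FALSE)
           else burden_test(comp, small_sample = FALSE)
    p_perm <- perm_pvalue(g, B = 20000, method = m, weights = rep(1, 3),
                          seed = 7)
    expect_lt(abs(fit$p_value - p_perm), 0.01)
  }
})

test_that("one-variant regions reduce to the 1-df chi-square closed form", {
  g <- random_region(n = 60, mafs = 0.25, seed = 4)
  comp <- score_components(g)
  s <- skat_test(comp, small_sample = FALSE)
  b <- burden_test(comp, small_sample = FALSE)
  p_closed <- pchisq(comp$U^2 / comp$V[1, 1], df = 1, lower.tail = FALSE)
  expect_equal(s$p_value, p_closed, tolerance = 1e-9)
  expect_equal(b$p_value, p_closed, tolerance = 1e-12)
})

test_that("exactly opposite score contributions annihilate the burden statistic", {
  d1 <- c(rep(1L, 10), rep(0L, 30))
  d <- cbind(d1, rev(d1))              # mirrored carriers across groups
  g <- region_genotypes(d, rep(c(1L, 0L), each = 20))
  comp <- score_components(g, weights = c(1, 1))
  b <- burden_test(comp, small_sample = FALSE)
  expect_equal(b$statistic, 0, tolerance = 1e-20)
  expect_equal(b$p_value, 1)
  # SKAT sees the two opposite signals instead of letting them cancel
  s <- skat_test(comp, small_sample = FALSE)
  expect_lt(s$p_value, 0.05)
})

test_that("mixture-of-chi-square tail matches closed forms and tolerates truncation", {
  # single eigenvalue: exact chi-square
  expect_equal(as.numeric(chisq_mixture_pvalue(7.3, 2)),
               pchisq(7.3 / 2, 1, lower.tail = FALSE), tolerance = 1e-10)
  # equal eigenvalues: lambda * chi2_k
  lam <- rep(1.7, 6)
  q <- 19
  expect_equal(as.numeric(chisq_mixture_pvalue(q, lam)),
               pchisq(q / 1.7, df = 6, lower.tail = FALSE), tolerance = 1e-7)
  # dropping eigenvalues below 1e-10 * max changes nothing detectable
  lam2 <- c(5, 2, 1, 1e-12)
  expect_equal(as.numeric(chisq_mixture_pvalue(10, lam2)),
               as.numeric(chisq_mixture_pvalue(10, lam2[1:3])), tolerance = 1e-8)
  # Liu fallback is a sane approximation of the same tail
  expect_equal(liu_tail_cpp(q, lam),
               pchisq(q / 1.7, df = 6, lower.tail = FALSE), tolerance = 5e-3)
})

test_that("degenerate regions are refused", {
  d <- matrix(0L, 10, 2)
  d[1, 1] <- 1L
  g <- region_genotypes(d, rep(c(1L, 0L), 5))
  comp <- score_components(g, weights = c(0, 0))
  expect_error(skat_test(comp), "degenerate")
  expect_error(burden_test(comp), "degenerate")
})

test_that("the small-sample adjustment is seed-reproducible and tail-coherent", {
  g <- angptl4_example()
  comp <- score_components(g)
  s1 <- skat_test(comp, seed = 5)
  s2 <- skat_test(comp, seed = 5)
  expect_identical(s1$p_value, s2$p_value)
  expect_true(s1$small_sample)          # n = 400 < 2000
  # the adjustment corrects the anti-conservative asymptotic tail downwards
  # for this strongly discrete region
  expect_lt(s1$p_small_sample, s1$p_asymptotic)
  b1 <- burden_test(comp, seed = 5)
  expect_equal(b1$p_value, b1$p_small_sample)
})
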