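# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed by the caller for reproducibility.

# small dense region: dosages drawn binomially at the given MAFs
random_region <- function(n = 50, mafs = c(0.1, 0.2, 0.3), n_cases = n / 2,
                          seed = 1) {
  withr_seed(seed)
  d <- sapply(mafs, function(f) rbinom(n, 2, f))
  # guard against monomorphic draws (would carry zero weight/information)
  for (j in seq_along(mafs)) {
    if (sum(d[, j]) == 0) d[1, j] <- 1L
    if (all(d[, j] == 2L)) d[1, j] <- 1L
  }
  region_genotypes(d, rep(c(1L, 0L), times = c(n_cases, n - n_cases)))
}

withr_seed <- function(seed) set.seed(seed)

# permutation p-value of an aggregate statistic, vectorised over B label
# permutations; the independent oracle for the asymptotic SKAT/burden tails
perm_pvalue <- function(g, B = 4000, method = c("skat", "burden"),
                        weights = NULL, seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  y <- g$phenotype
  n <- length(y)
  ybar <- mean(y)
  if (is.null(weights)) weights <- beta_weights(g$variants$maf_pooled)
  Ac <- sweep(g$dosage, 2, colMeans(g$dosage)) *
    rep(weights, each = n)
  stat <- function(yy) {
    u <- as.vector(crossprod(Ac, yy - mean(yy)))
    if (method == "skat") sum(u^2) else sum(u)^2
  }
  obs <- stat(y)
  perm <- replicate(B, stat(sample(y)))
  (1 + sum(perm >= obs)) / (B + 1)
}

# plain-R re-implementation of the inner region test and greedy elimination,
# independent of the compiled path (Liu approximation written out directly)
r_liu_tail <- function(q, lam) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  if (c2 <= 0) return(if (q > c1) 0 else 1)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2)); delta <- s1 * a^3 - a^2; l <- a^2 - 2 * delta
  } else {
    a <- 1 / sqrt(s2); delta <- 0; l <- 1 / s2
  }
  if (l < 0.05) l <- 0.05
  x <- (q - c1) / sqrt(2 * c2) * sqrt(2) * a + (l + delta)
  if (x <= 0) return(1)
  pchisq(x, df = l, ncp = delta, lower.tail = FALSE)
}

r_subset_p <- function(U, V, idx, method) {
  if (method == "burden") {
    v <- sum(V[idx, idx])
    if (v <= 1e-300) return(1)
    return(pchisq(sum(U[idx])^2 / v, 1, lower.tail = FALSE))
  }
  Vs <- V[idx, idx, drop = FALSE]
  if (sum(diag(Vs)) <= 1e-300) return(1)
  lam <- eigen(Vs, symmetric = TRUE, only.values = TRUE)$values
  r_liu_tail(sum(U[idx]^2), lam)
}

r_greedy <- function(U, V, idx, method) {
  pc <- r_subset_p(U, V, idx, method)
  repeat {
    if (length(idx) <= 1) break
    loo <- vapply(seq_along(idx),
                  function(k) r_subset_p(U, V, idx[-k], method), numeric(1))
    k <- which.min(loo)
    if (loo[k] < pc) {
      pc <- loo[k]
      idx <- idx[-k]
    } else break
  }
  idx
}
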