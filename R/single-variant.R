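#' One-sided Fisher mid-P value for a 2x2 allele table
#'
#' For a variant carried on `m` of `n` alleles overall, with `x_obs` of them
#' falling in an enriched group holding `n1` alleles, the mid-P value is
#'
#'   P(X > x_obs) + 0.5 * P(X = x_obs),   X ~ Hypergeometric(n, n1, m),
#'
#' i.e. the one-sided Fisher exact tail counting only half the probability of
#' the observed table. The half-atom removes the conservativeness the full
#' exact P suffers for very discrete rare-variant tables. By convention the
#' caller passes the group in which the variant is the *more* frequent as the
#' enriched group. A monomorphic variant (`m = 0`) returns 1.
#'
#' All arguments are vectorised.
#'
#' @param x_obs Minor-allele count observed in the enriched group.
#' @param m Total minor-allele count across both groups.
#' @param n1 Number of alleles in the enriched group.
#' @param n Total number of alleles.
#' @return Mid-P values in (0, 1].
#' @export
#' @examples
#' mid_p(1, 1, 200, 400)   # a single minor allele in half the alleles: 0.25
mid_p <- function(x_obs, m, n1, n) {
  len <- max(length(x_obs), length(m), length(n1), length(n))
  x_obs <- rep_len(x_obs, len)
  m <- rep_len(m, len)
  n1 <- rep_len(n1, len)
  n <- rep_len(n, len)
  if (any(x_obs > pmin(m, n1)) || any(m > n) || any(n1 > n) || any(x_obs < 0)) {
    stop("need 0 <= x_obs <= min(m, n1) and m, n1 <= n.", call. = FALSE)
  }
  # X ~ number of the m minor alleles landing among the n1 enriched-group slots
  p <- phyper(x_obs, m, n - m, n1, lower.tail = FALSE) +
    0.5 * dhyper(x_obs, m, n - m, n1)
  p[m == 0] <- 1
  p
}

#' Per-site association scan
#'
#' Computes, for every variant of a complete region, the one-sided Fisher
#' mid-P value in its direction of enrichment, the corresponding two-sided
#' mid-P value (twice the smaller one-sided value, capped at 1), and a
#' direction flag: `deleterious_inclined` when the minor allele is strictly
#' more frequent in cases, `protective_inclined` when strictly more frequent
#' in controls, `balanced` when the two frequencies are exactly equal (such a
#' variant contributes to neither directional ADA score). The 2x2 table is
#' allele-based: entries are minor-allele counts out of `2 x` group sizes.
#'
#' @param g A complete (no missing genotypes) [region_genotypes] object.
#' @return A tibble with one row per variant: `variant_id`, `direction`,
#'   `p_mid`, `p_two`, `x_obs` (minor alleles in the enriched group), `m`,
#'   `n1` (alleles in the enriched group), `n`.
#' @export
per_site_scan <- function(g) {
  stopifnot(inherits(g, "region_genotypes"))
  if (anyNA(g$dosage)) {
    stop("region has missing genotypes; run filter_missing() first.", call. = FALSE)
  }
  y <- g$phenotype
  n1_case <- 2L * sum(y == 1L)
  n <- 2L * length(y)
  x_case <- as.integer(crossprod(g$dosage, y))
  m <- as.integer(colSums(g$dosage))
  scan_from_counts(g$variants$id, x_case, m, n1_case, n)
}

# core of the scan, shared with the vectorised permutation engine
scan_from_counts <- function(ids, x_case, m, n1_case, n) {
  # enrichment by cross-multiplied frequencies: x/n1 vs (m - x)/(n - n1)
  lhs <- as.numeric(x_case) * (n - n1_case)
  rhs <- as.numeric(m - x_case) * n1_case
  p_del <- mid_p(x_case, m, n1_case, n)
  p_pro <- 1 - p_del            # exact complement: both tails + the full atom
  direction <- ifelse(m == 0L, "balanced",
                      ifelse(lhs > rhs, "deleterious_inclined",
                             ifelse(lhs < rhs, "protective_inclined", "balanced")))
  p_enr <- pmin(p_del, p_pro)
  p_enr[direction == "deleterious_inclined"] <- p_del[direction == "deleterious_inclined"]
  p_enr[direction == "protective_inclined"] <- p_pro[direction == "protective_inclined"]
  p_enr[m == 0L] <- 1
  p_two <- pmin(1, 2 * pmin(p_del, p_pro))
  p_two[m == 0L] <- 1
  tibble::tibble(
    variant_id = ids,
    direction = direction,
    p_mid = p_enr,
    p_two = p_two,
    x_obs = ifelse(direction == "protective_inclined", m - x_case, x_case),
    m = m,
    n1 = ifelse(direction == "protective_inclined", n - n1_case, n1_case),
    n = n
  )
}
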