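#' Greedy backward elimination of variants
#'
#' Starting from a variant set, repeatedly recomputes the region test
#' (SKAT or burden) after removing each remaining variant in turn; if the
#' best single removal lowers the P-value it is made permanent, and the
#' procedure repeats until no removal helps (or one variant remains — the
#' set is never emptied). Ties among equally good removals are broken
#' towards the smallest variant index, making the procedure deterministic.
#' The final P-value never exceeds the starting P-value.
#'
#' Inside the elimination loop the SKAT tail is evaluated with the
#' Liu-Tang-Zhang moment approximation: the loop only compares P-values of
#' closely related variant subsets, for which the smooth moment
#' approximation preserves the ordering at a fraction of the cost of full
#' quadrature.
#'
#' @param current_set Character vector of variant ids (or integer indices)
#'   to start from.
#' @param g A complete [region_genotypes] object.
#' @param inner_test `"skat"` or `"burden"`.
#' @param weights Per-variant weights; default Beta(1, 25) density at the
#'   pooled MAF.
#' @param eps_improve Minimum P-value improvement required to remove a
#'   variant (default 0: any strict improvement).
#' @return Character vector of surviving variant ids.
#' @export
greedy_eliminate <- function(current_set, g, inner_test = c("skat", "burden"),
                             weights = NULL, eps_improve = 0) {
  inner_test <- match.arg(inner_test)
  comp <- score_components(g, weights)
  idx <- resolve_variant_ids(current_set, comp$ids)
  if (length(idx) == 0) stop("`current_set` is empty.", call. = FALSE)
  surv <- greedy_eliminate_cpp(comp$U, comp$V, sort(idx),
                               method = if (inner_test == "skat") 0L else 1L,
                               eps_improve = eps_improve)
  comp$ids[surv]
}

resolve_variant_ids <- function(set, ids) {
  if (is.numeric(set)) {
    idx <- as.integer(set)
    if (any(idx < 1L | idx > length(ids))) stop("variant index out of range.", call. = FALSE)
  } else {
    idx <- match(as.character(set), ids)
    if (anyNA(idx)) stop("unknown variant id(s): ",
                         paste(set[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Backward elimination over random variant subsamples (BE-SKAT / BE-BURDEN)
#'
#' The resampling selection procedure built on a region test: draw `r`
#' variants at random, run [greedy_eliminate()] on the subsample, and count,
#' over `B` subsamples, how often each variant survives — its *return
#' count*. A two-component binomial-mixture EM ([partition_counts()]) then
#' splits the variants into an "interesting" (high return count) and a
#' "non-interesting" group; the interesting group is the selected set.
#'
#' @param g A complete [region_genotypes] object with at least 2 variants.
#' @param r Subsample size (default 20, capped at the number of variants).
#' @param B Number of random subsamples (default 1000).
#' @param inner_test `"skat"` or `"burden"`.
#' @param weights Per-variant weights; default Beta(1, 25) density at the
#'   pooled MAF.
#' @param eps_improve Passed to the elimination loop.
#' @param seed Optional seed for the subsample draws; the caller's RNG
#'   stream is restored.
#' @return An object of class `be_fit`: tibble `counts` (`variant_id`,
#'   `return_count`, `interesting`), `selected` (character vector),
#'   `mixture` (fitted EM parameters), plus the configuration.
#' @export
#' @examples
#' g <- angptl4_example()
#' fit <- be_run(g, B = 100, inner_test = "skat", seed = 1)
#' fit$selected
be_run <- function(g, r = 20, B = 1000, inner_test = c("skat", "burden"),
                   weights = NULL, eps_improve = 0, seed = NULL) {
  stopifnot(inherits(g, "region_genotypes"))
  inner_test <- match.arg(inner_test)
  p <- n_variants(g)
  if (p < 2) stop("backward elimination needs at least 2 variants.", call. = FALSE)
  r <- min(r, p)
  comp <- score_components(g, weights)
  subsets <- with_seed(seed, {
    t(replicate(B, sample.int(p, r)))
  })
  counts <- be_counts_cpp(comp$U, comp$V, subsets,
                          method = if (inner_test == "skat") 0L else 1L,
                          eps_improve = eps_improve)
  part <- partition_counts(counts, B)
  tbl <- tibble::tibble(
    variant_id = comp$ids,
    return_count = as.integer(counts),
    interesting = part$interesting
  )
  structure(list(
    counts = tbl,
    selected = tbl$variant_id[tbl$interesting],
    mixture = part$mixture,
    inner_test = inner_test, r = r, B = B
  ), class = "be_fit")
}

#' Partition return counts into interesting / non-interesting variants
#'
#' Fits a two-component binomial mixture to the return counts by EM
#' (components `Binomial(B, q0)` and `Binomial(B, q1)`), initialised from a
#' median split of the counts, at most 200 iterations, log-likelihood
#' tolerance `1e-8`. The component with the higher fitted success
#' probability is labelled *interesting* and variants are assigned by
#' posterior probability. Identical counts for all variants carry no
#' separation signal: everything is labelled non-interesting.
#'
#' @param return_counts Integer vector of per-variant return counts.
#' @param B The number of subsamples the counts were accumulated over.
#' @return List with `interesting` (logical vector) and `mixture` (fitted
#'   `q0`, `q1`, mixing weight `pi1`, iterations, log-likelihood).
#' @export
partition_counts <- function(return_counts, B) {
  k <- as.numeric(return_counts)
  p <- length(k)
  if (p < 2) stop("need at least 2 variants to partition.", call. = FALSE)
  if (max(k) > B) stop("return counts cannot exceed B.", call. = FALSE)
  if (diff(range(k)) == 0) {
    return(list(interesting = rep(FALSE, p),
                mixture = list(q0 = mean(k) / B, q1 = mean(k) / B, pi1 = 0,
                               iterations = 0L, loglik = NA_real_)))
  }
  med <- stats::median(k)
  hi <- k > med
  if (!any(hi)) hi <- k == max(k)
  clamp <- function(q) pmin(pmax(q, 1e-8), 1 - 1e-8)
  q0 <- clamp(mean(k[!hi]) / B)
  q1 <- clamp(mean(k[hi]) / B)
  pi1 <- mean(hi)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    l1 <- log(pi1) + dbinom(k, B, q1, log = TRUE)
    l0 <- log1p(-pi1) + dbinom(k, B, q0, log = TRUE)
    mx <- pmax(l1, l0)
    ll <- sum(mx + log(exp(l1 - mx) + exp(l0 - mx)))
    post1 <- 1 / (1 + exp(l0 - l1))
    pi1 <- mean(post1)
    q1 <- clamp(sum(post1 * k) / (B * max(sum(post1), 1e-12)))
    q0 <- clamp(sum((1 - post1) * k) / (B * max(sum(1 - post1), 1e-12)))
    if (abs(ll - ll_old) < 1e-8 || it >= 200L) break
    ll_old <- ll
  }
  if (q1 < q0) {           # keep component 1 = higher-mean component
    tmp <- q0; q0 <- q1; q1 <- tmp
    post1 <- 1 - post1
    pi1 <- 1 - pi1
  }
  interesting <- if (abs(q1 - q0) < 1e-6) rep(FALSE, p) else post1 > 0.5
  list(interesting = interesting,
       mixture = list(q0 = q0, q1 = q1, pi1 = pi1, iterations = it, loglik = ll))
}

#' @export
print.be_fit <- function(x, ...) {
  cat(sprintf("Backward elimination (inner test: %s), r = %d, B = %d\n",
              toupper(x$inner_test), x$r, x$B))
  cat(sprintf("  interesting variants (%d): %s\n", length(x$selected),
              if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)"))
  invisible(x)
}
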