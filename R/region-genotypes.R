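#' Per-sample genotypes for one gene or region
#'
#' The central container of the package: a samples-by-variants matrix of
#' minor-allele dosages together with a binary phenotype and per-variant
#' metadata. Dosages count copies of the *minor* allele, where minor/major is
#' decided from the pooled (cases + controls) allele frequency; columns whose
#' stated allele is the major one are flipped on construction so that the
#' pooled minor-allele frequency never exceeds 0.5 (ties at 0.5 are left as
#' given).
#'
#' @param dosage Integer matrix, samples x variants, entries in `{0, 1, 2}` or
#'   `NA` for missing genotypes.
#' @param phenotype Binary vector (1 = case, 0 = control), one entry per
#'   sample. At least one case and one control are required.
#' @param variants Optional data frame of per-variant metadata with at least a
#'   `id` column; recognised optional columns are `position` (1-based bp),
#'   `maf_population`, `is_causal` and `is_risk` (simulation truth labels).
#'   Defaults to the matrix column names, or `v1, v2, ...`.
#' @param samples Optional character vector of sample identifiers.
#'
#' @return An object of class `region_genotypes`: a list with elements
#'   `dosage`, `phenotype`, `samples` and `variants` (a tibble that always
#'   carries `id` and the pooled minor-allele frequency `maf_pooled`).
#' @export
region_genotypes <- function(dosage, phenotype, variants = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  p <- ncol(dosage)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n) {
    stop("`phenotype` must have one entry per row of `dosage`.", call. = FALSE)
  }
  if (!all(phenotype %in% c(0L, 1L))) {
    stop("`phenotype` must be binary (1 = case, 0 = control).", call. = FALSE)
  }
  if (sum(phenotype == 1L) == 0L || sum(phenotype == 0L) == 0L) {
    stop("need at least one case and one control.", call. = FALSE)
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) {
    stop("dosages must be 0, 1, 2 or NA.", call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- rownames(dosage)
    if (is.null(samples)) samples <- paste0("s", seq_len(n))
  }
  if (is.null(variants)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- paste0("v", seq_len(p))
    variants <- tibble::tibble(id = ids)
  } else {
    variants <- tibble::as_tibble(variants)
    if (!"id" %in% names(variants)) {
      stop("`variants` must have an `id` column.", call. = FALSE)
    }
    if (nrow(variants) != p) {
      stop("`variants` must have one row per dosage column.", call. = FALSE)
    }
    variants$id <- as.character(variants$id)
  }
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique.", call. = FALSE)
  }
  # orient every column to the pooled minor allele
  freq <- pooled_frequency(dosage)
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
    freq[flip] <- 1 - freq[flip]
  }
  variants$maf_pooled <- freq
  dimnames(dosage) <- list(samples, variants$id)
  structure(
    list(dosage = dosage, phenotype = phenotype,
         samples = as.character(samples), variants = variants),
    class = "region_genotypes"
  )
}

pooled_frequency <- function(dosage) {
  called <- colSums(!is.na(dosage))
  cnt <- colSums(dosage, na.rm = TRUE)
  unname(ifelse(called > 0, cnt / (2 * called), NA_real_))
}

#' @export
print.region_genotypes <- function(x, ...) {
  n <- nrow(x$dosage)
  cat(sprintf(
    "<region_genotypes> %d samples (%d cases / %d controls), %d variants\n",
    n, sum(x$phenotype == 1L), sum(x$phenotype == 0L), ncol(x$dosage)
  ))
  miss <- sum(is.na(x$dosage))
  if (miss > 0) cat(sprintf("  %d missing genotype calls\n", miss))
  print(utils::head(x$variants, 5))
  if (nrow(x$variants) > 5) cat(sprintf("  ... and %d more variants\n", nrow(x$variants) - 5L))
  invisible(x)
}

#' @export
dim.region_genotypes <- function(x) dim(x$dosage)

#' Number of samples / variants in a region
#' @param g A [region_genotypes] object.
#' @return An integer scalar.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_variants <- function(g) ncol(g$dosage)

# internal: subset a region by variant and/or sample index
subset_region <- function(g, variant_idx = NULL, sample_idx = NULL) {
  d <- g$dosage
  v <- g$variants
  s <- g$samples
  ph <- g$phenotype
  if (!is.null(variant_idx)) {
    d <- d[, variant_idx, drop = FALSE]
    v <- v[variant_idx, , drop = FALSE]
  }
  if (!is.null(sample_idx)) {
    d <- d[sample_idx, , drop = FALSE]
    s <- s[sample_idx]
    ph <- ph[sample_idx]
  }
  if (sum(ph == 1L) == 0L || sum(ph == 0L) == 0L) {
    stop("filtering removed all cases or all controls.", call. = FALSE)
  }
  out <- region_genotypes(d, ph, variants = v, samples = s)
  out
}

#' Drop high-missingness variants, then incomplete samples
#'
#' Variants whose missing-call rate exceeds `max_variant_missing_rate` are
#' removed first; any sample still carrying a missing genotype at a retained
#' variant is then removed. The variant-first order is fixed: a failed assay
#' is a property of the site, and dropping it first retains the samples that
#' are complete everywhere else. The result is a complete (no `NA`) region,
#' as required by all association operations in the package.
#'
#' @param g A [region_genotypes] object.
#' @param max_variant_missing_rate Highest tolerated per-variant missing rate
#'   (default 0.10).
#' @return A complete [region_genotypes] object.
#' @export
filter_missing <- function(g, max_variant_missing_rate = 0.10) {
  stopifnot(inherits(g, "region_genotypes"))
  miss_rate <- colMeans(is.na(g$dosage))
  keep_v <- miss_rate <= max_variant_missing_rate
  d <- g$dosage[, keep_v, drop = FALSE]
  keep_s <- rowSums(is.na(d)) == 0L
  if (!any(keep_s)) stop("all samples removed by missingness filtering.", call. = FALSE)
  if (all(keep_v) && all(keep_s)) return(g)
  subset_region(g, variant_idx = which(keep_v), sample_idx = which(keep_s))
}

#' Restrict a region to its rare-variant analysis marker set
#'
#' Keeps variants with `0 < MAF < maf_cutoff` (strict at both ends, so
#' monomorphic variants and variants at exactly the cutoff are excluded). In
#' simulated data carrying a population MAF, that truth frequency is used;
#' otherwise the pooled sample MAF is. The operation is idempotent.
#'
#' @param g A [region_genotypes] object.
#' @param maf_cutoff Upper (strict) MAF bound, default 0.05.
#' @param frequency `"auto"` (population MAF when available for every
#'   variant, else pooled), `"pooled"`, or `"population"`.
#' @return A [region_genotypes] object, possibly with zero variants.
#' @export
filter_analysis_set <- function(g, maf_cutoff = 0.05,
                                frequency = c("auto", "pooled", "population")) {
  stopifnot(inherits(g, "region_genotypes"))
  frequency <- match.arg(frequency)
  have_pop <- "maf_population" %in% names(g$variants) &&
    !anyNA(g$variants$maf_population)
  use_pop <- switch(frequency,
    auto = have_pop,
    pooled = FALSE,
    population = {
      if (!have_pop) stop("population MAF not available for every variant.", call. = FALSE)
      TRUE
    }
  )
  maf <- if (use_pop) g$variants$maf_population else g$variants$maf_pooled
  observed <- g$variants$maf_pooled > 0
  keep <- !is.na(maf) & maf > 0 & maf < maf_cutoff & observed
  if (all(keep)) return(g)
  g$dosage <- g$dosage[, keep, drop = FALSE]
  g$variants <- g$variants[keep, , drop = FALSE]
  g
}

#' Beta-density variant weights
#'
#' The standard rare-variant weighting: variant `j` receives weight
#' `dbeta(maf_j, a, b)`, the Beta(a, b) density evaluated at its minor-allele
#' frequency. With the default shape `(1, 25)` the weight decreases steeply
#' in MAF, up-weighting the rarest variants. The same weight vector is used
#' by the ADA, SKAT and burden procedures so that the three are compared on
#' an equal footing.
#'
#' @param mafs Vector of minor-allele frequencies, all strictly inside (0, 1).
#' @param a,b Beta shape parameters (defaults 1 and 25).
#' @return Numeric vector of non-negative weights.
#' @export
#' @examples
#' beta_weights(c(0.001, 0.01, 0.04))
beta_weights <- function(mafs, a = 1, b = 25) {
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs >= 1)) {
    stop("all MAFs must lie strictly in (0, 1).", call. = FALSE)
  }
  dbeta(mafs, a, b)
}
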