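#' Simulation scenario for case-control rare-variant studies
#'
#' Bundles every free parameter of the simulation design: the region and
#' haplotype pool, which rare variants are causal and how strong they are
#' (through the per-variant population attributable risk fraction, PAF), the
#' split between risk and protective causal variants, the penetrance model
#' and the case-control sampling quotas.
#'
#' @param region_length Region length in bp (typically 5000, 10000, 20000).
#' @param pool_size Number of haplotypes in the population pool (default
#'   10000).
#' @param causal_fraction Fraction of rare (population MAF < `rare_cutoff`)
#'   variants designated causal (e.g. 0.25 or 0.50; 0 for a null region).
#' @param paf Per-variant population attributable risk fraction (e.g. 0.003
#'   or 0.005).
#' @param r_isk Fraction of causal variants that increase risk; the rest are
#'   protective. Non-integer counts are rounded up.
#' @param f0 Baseline penetrance (default 0.01).
#' @param n_cases,n_controls Sampling quotas (defaults 500 / 500).
#' @param rare_cutoff Population-MAF bound defining "rare" for causal
#'   designation (default 0.01, strict).
#' @param analysis_cutoff Population-MAF bound defining the analysis marker
#'   set (default 0.05, strict).
#' @param theta_per_kb Scaled mutation rate per kb of region (per 4N
#'   generations); the default is calibrated so a 5 kb region yields on the
#'   order of 45 analysis-set variants in a 1000-subject sample.
#' @param block_bp Length of the independently coalescing blocks the region
#'   is tiled with (default 1250 bp); see [generate_pool()].
#' @param demography Piecewise-constant population-size history: data frame
#'   with `start` (epoch start, coalescent units of 2N generations, first row
#'   0) and `nu` (population size relative to the reference), most recent
#'   first. The default is a stylised growth-bottleneck history (explosive
#'   recent expansion, severe founding bottleneck, long intermediate epoch,
#'   compact ancestral population) calibrated so that a 5 kb region yields
#'   on the order of 45 analysis-set variants in a 1000-subject sample with
#'   a singleton-heavy rare tail; see the methods vignette.
#' @param max_draws Cap on rejection-sampling subject draws before
#'   [sample_case_control()] gives up.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(region_length = 5000, pool_size = 10000,
                         causal_fraction = 0.25, paf = 0.003, r_isk = 0.5,
                         f0 = 0.01, n_cases = 500, n_controls = 500,
                         rare_cutoff = 0.01, analysis_cutoff = 0.05,
                         theta_per_kb = 0.60, block_bp = 1250,
                         demography = default_demography(),
                         max_draws = 2e6) {
  stopifnot(region_length > 0, pool_size >= 4,
            causal_fraction >= 0, causal_fraction <= 1,
            paf >= 0, paf < 1, r_isk >= 0, r_isk <= 1,
            f0 > 0, f0 <= 1, n_cases > 0, n_controls > 0)
  structure(as.list(environment()), class = "sim_scenario")
}

#' @rdname sim_scenario
#' @export
default_demography <- function() {
  data.frame(
    start = c(0, 0.0012, 0.0044, 3.0),
    nu    = c(400, 0.04, 30, 0.3)
  )
}

# One Kingman coalescent tree under piecewise-constant demography, with
# infinite-sites mutations dropped on the branches. Returns the 0/1 derived
# allele matrix (pool_size x S) and relative positions in (0, 1). Thin
# wrapper over the compiled event loop (which draws from R's RNG stream).
coalescent_block <- function(n, demography, theta) {
  coalescent_block_cpp(n, demography$start, demography$nu, theta)
}

#' Generate a haplotype pool with a coalescent stand-in
#'
#' Simulates `pool_size` haplotypes for the region by tiling it with
#' independently coalescing blocks of `block_bp` base pairs (linkage is
#' complete within a block and free between blocks — a deliberately simple
#' stand-in for recombination) and running, per block, a Kingman coalescent
#' under the scenario's piecewise-constant demography with infinite-sites
#' mutations. The growth-dominated default demography produces the
#' rare-variant-heavy folded site frequency spectrum that makes rare-variant
#' method benchmarking meaningful. Alleles are folded so that 1 encodes the
#' population minor allele. A pool with zero segregating sites is
#' regenerated with a shifted seed (with a message).
#'
#' @param scenario A [sim_scenario].
#' @param seed Optional integer seed.
#' @return An object of class `haplotype_pool`: list with `haplotypes`
#'   (pool_size x sites 0/1 matrix), `positions` (bp), `population_mafs`,
#'   `region_length`.
#' @export
generate_pool <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  for (attempt in 0:9) {
    pool <- with_seed(if (is.null(seed)) NULL else seed + attempt, {
      n_blocks <- max(1L, as.integer(round(scenario$region_length / scenario$block_bp)))
      bp_per_block <- scenario$region_length / n_blocks
      theta_block <- scenario$theta_per_kb * bp_per_block / 1000
      hap <- vector("list", n_blocks)
      pos <- vector("list", n_blocks)
      for (bl in seq_len(n_blocks)) {
        blk <- coalescent_block(scenario$pool_size, scenario$demography, theta_block)
        hap[[bl]] <- blk$haplotypes
        pos[[bl]] <- (bl - 1) * bp_per_block + blk$rel_pos * bp_per_block
      }
      H <- do.call(cbind, hap)
      positions <- pmax(1L, as.integer(ceiling(unlist(pos))))
      ord <- order(positions)
      H <- H[, ord, drop = FALSE]
      positions <- positions[ord]
      freq <- colMeans(H)
      flip <- freq > 0.5
      if (any(flip)) {
        H[, flip] <- 1L - H[, flip, drop = FALSE]
        freq[flip] <- 1 - freq[flip]
      }
      structure(list(haplotypes = H, positions = positions,
                     population_mafs = freq,
                     region_length = scenario$region_length),
                class = "haplotype_pool")
    })
    if (ncol(pool$haplotypes) > 0) return(pool)
    message("pool had zero segregating sites; regenerating with shifted seed.")
  }
  stop("failed to generate a polymorphic haplotype pool.", call. = FALSE)
}

#' Load / save a haplotype pool as plain text
#'
#' Format: a header line of base-pair positions (whitespace-separated),
#' then one haplotype per line as a string of 0/1 characters.
#'
#' @param path File path.
#' @return A `haplotype_pool`.
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  positions <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lapply(lines[-1], function(l) {
    l <- gsub("\\s", "", l)
    as.integer(strsplit(l, "")[[1]])
  })
  H <- do.call(rbind, rows)
  if (ncol(H) != length(positions)) {
    stop("haplotype rows do not match the position header.", call. = FALSE)
  }
  freq <- colMeans(H)
  structure(list(haplotypes = H, positions = positions,
                 population_mafs = pmin(freq, 1 - freq),
                 region_length = max(positions)),
            class = "haplotype_pool")
}

#' @param pool A `haplotype_pool` to write.
#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(pool$positions, collapse = " "), con)
  writeLines(apply(pool$haplotypes, 1, paste, collapse = ""), con)
  invisible(path)
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %d haplotypes, %d segregating sites over %d bp\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$region_length))
  invisible(x)
}

#' Genotype relative risk implied by a population attributable risk fraction
#'
#' Inverting the definition of the per-variant PAF gives the multiplicative
#' genotype relative risk `GRR = 1 + PAF / (MAF (1 - PAF))` for a
#' deleterious variant; a protective variant receives the reciprocal, so at
#' equal MAF protective effects are smaller in magnitude than deleterious
#' ones. `paf = 0` gives `GRR = 1`.
#'
#' @param paf Population attributable risk fraction in \[0, 1).
#' @param maf Population minor-allele frequency in (0, 1).
#' @param protective Protective orientation (default `FALSE`).
#' @return Positive scalar (vectorised over its arguments).
#' @export
#' @examples
#' grr_from_paf(0.003, 0.01)   # ~1.3
#' grr_from_paf(0.005, 0.01)   # ~1.5
grr_from_paf <- function(paf, maf, protective = FALSE) {
  if (any(paf < 0 | paf >= 1)) stop("need 0 <= paf < 1.", call. = FALSE)
  if (any(maf <= 0 | maf >= 1)) stop("need 0 < maf < 1.", call. = FALSE)
  grr <- 1 + paf / (maf * (1 - paf))
  ifelse(protective, 1 / grr, grr)
}

#' Designate causal and risk variants in a pool
#'
#' Draws `ceiling(causal_fraction * #rare)` causal sites uniformly from the
#' pool sites with population MAF strictly below the rare cutoff, then
#' `ceiling(r_isk * #causal)` of them as risk (the remainder protective;
#' rounding up follows the smallest-integer-not-less rule). Each causal site
#' is assigned its GRR from the scenario PAF and its own population MAF.
#'
#' @param pool A `haplotype_pool`.
#' @param scenario A [sim_scenario].
#' @param seed Optional integer seed.
#' @return The pool with a `causal` tibble attached (`site`, `position`,
#'   `maf`, `risk`, `grr`).
#' @export
assign_causal <- function(pool, scenario, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(scenario, "sim_scenario"))
  rare <- which(pool$population_mafs < scenario$rare_cutoff & pool$population_mafs > 0)
  if (scenario$causal_fraction == 0) {
    pool$causal <- tibble::tibble(site = integer(0), position = integer(0),
                                  maf = numeric(0), risk = logical(0),
                                  grr = numeric(0))
    return(pool)
  }
  if (length(rare) == 0) stop("no rare sites available for causal designation.", call. = FALSE)
  n_causal <- ceiling(scenario$causal_fraction * length(rare))
  if (n_causal > length(rare)) stop("requested causal count exceeds available rare sites.", call. = FALSE)
  pool$causal <- with_seed(seed, {
    site <- sort(sample(rare, n_causal))
    n_risk <- ceiling(scenario$r_isk * n_causal)
    risk_site <- if (n_risk > 0) sample(site, n_risk) else integer(0)
    risk <- site %in% risk_site
    tibble::tibble(
      site = site,
      position = pool$positions[site],
      maf = pool$population_mafs[site],
      risk = risk,
      grr = grr_from_paf(scenario$paf, pool$population_mafs[site], protective = !risk)
    )
  })
  pool
}

#' Penetrance of a diplotype under the multiplicative model
#'
#' The disease probability of a subject with haplotypes `h1`, `h2` is the
#' baseline penetrance multiplied by `GRR_j` for every causal minor allele
#' carried at causal site `j` (so a homozygous carrier contributes the
#' square), capped at 1.
#'
#' @param h1,h2 0/1 haplotype vectors over the pool sites (1 = minor
#'   allele).
#' @param causal_sites Integer indices of the causal sites.
#' @param grrs GRR per causal site, aligned with `causal_sites`.
#' @param f0 Baseline penetrance.
#' @return Disease probability in (0, 1\].
#' @export
penetrance <- function(h1, h2, causal_sites, grrs, f0 = 0.01) {
  dos <- h1[causal_sites] + h2[causal_sites]
  pmin(1, f0 * prod(grrs^dos))
}

#' Sample a case-control replicate from a haplotype pool
#'
#' Subjects are formed by drawing two haplotypes from the pool with
#' replacement; disease status is Bernoulli with the subject's penetrance;
#' drawing continues until both the case and the control quota are met
#' (rejection sampling, capped at `max_draws` subjects). When the scenario
#' has no causal variants the phenotype is independent of the genotypes, and
#' the quotas are filled directly from the required number of subject draws
#' — distributionally identical and much faster for null regions. The
#' genotype matrix is then restricted to the analysis marker set: sites with
#' population MAF strictly below the analysis cutoff that are polymorphic in
#' the sample.
#'
#' @param pool A `haplotype_pool`, with causal assignment attached via
#'   [assign_causal()] when the scenario calls for causal variants.
#' @param scenario A [sim_scenario].
#' @param seed Optional integer seed.
#' @return An object of class `sim_replicate`: list with `region` (a
#'   [region_genotypes] with truth labels in its variant table),
#'   `causal_ids` / `risk_ids` (ids within the analysis set),
#'   `realized_causal_percentage` (fraction of analysis-set variants that
#'   are causal), `n_draws`.
#' @export
sample_case_control <- function(pool, scenario, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(scenario, "sim_scenario"))
  if (is.null(pool$causal)) {
    if (scenario$causal_fraction > 0) {
      stop("run assign_causal() before sampling a non-null scenario.", call. = FALSE)
    }
    pool$causal <- tibble::tibble(site = integer(0), risk = logical(0), grr = numeric(0))
  }
  H <- pool$haplotypes
  npool <- nrow(H)
  nca <- scenario$n_cases
  nco <- scenario$n_controls
  causal <- pool$causal
  null_model <- nrow(causal) == 0 || all(causal$grr == 1)
  if (null_model && scenario$f0 >= 1) {
    stop("baseline penetrance 1 makes every subject a case; control quota unreachable.",
         call. = FALSE)
  }

  drawn <- with_seed(seed, {
    if (null_model) {
      ntot <- nca + nco
      list(h1 = sample.int(npool, ntot, replace = TRUE),
           h2 = sample.int(npool, ntot, replace = TRUE),
           y = c(rep(1L, nca), rep(0L, nco)),
           n_draws = ntot)
    } else {
      log_grr <- log(causal$grr)
      Hc <- H[, causal$site, drop = FALSE]
      case_h1 <- integer(0); case_h2 <- integer(0)
      ctrl_h1 <- integer(0); ctrl_h2 <- integer(0)
      n_draws <- 0L
      batch <- 8192L
      while ((length(case_h1) < nca || length(ctrl_h1) < nco)) {
        if (n_draws >= scenario$max_draws) {
          stop(sprintf(paste0(
            "case-control quota not reached after %d draws ",
            "(%d cases, %d controls so far); penetrance model may be too extreme."),
            n_draws, length(case_h1), length(ctrl_h1)), call. = FALSE)
        }
        h1 <- sample.int(npool, batch, replace = TRUE)
        h2 <- sample.int(npool, batch, replace = TRUE)
        pen <- pmin(1, scenario$f0 * exp((Hc[h1, , drop = FALSE] +
                                          Hc[h2, , drop = FALSE]) %*% log_grr))
        dis <- rbinom(batch, 1L, pen) == 1L
        case_h1 <- c(case_h1, h1[dis]); case_h2 <- c(case_h2, h2[dis])
        ctrl_h1 <- c(ctrl_h1, h1[!dis]); ctrl_h2 <- c(ctrl_h2, h2[!dis])
        n_draws <- n_draws + batch
      }
      list(h1 = c(case_h1[seq_len(nca)], ctrl_h1[seq_len(nco)]),
           h2 = c(case_h2[seq_len(nca)], ctrl_h2[seq_len(nco)]),
           y = c(rep(1L, nca), rep(0L, nco)),
           n_draws = n_draws)
    }
  })

  dosage <- H[drawn$h1, , drop = FALSE] + H[drawn$h2, , drop = FALSE]
  keep <- pool$population_mafs < scenario$analysis_cutoff &
    pool$population_mafs > 0 & colSums(dosage) > 0
  sites <- which(keep)
  is_causal <- sites %in% causal$site
  is_risk <- rep(NA, length(sites))
  is_risk[is_causal] <- sites[is_causal] %in% causal$site[causal$risk]
  variants <- tibble::tibble(
    id = paste0("v", sites),
    position = pool$positions[sites],
    maf_population = pool$population_mafs[sites],
    is_causal = is_causal,
    is_risk = is_risk
  )
  region <- region_genotypes(dosage[, sites, drop = FALSE], drawn$y,
                             variants = variants)
  structure(list(
    region = region,
    causal_ids = variants$id[variants$is_causal],
    risk_ids = variants$id[which(variants$is_risk)],
    realized_causal_percentage = if (length(sites)) mean(is_causal) else NA_real_,
    n_draws = drawn$n_draws
  ), class = "sim_replicate")
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat(sprintf("<sim_replicate> %d analysis-set variants (%d causal), %d draws\n",
              n_variants(x$region), length(x$causal_ids), x$n_draws))
  invisible(x)
}
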