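#' Read genotypes for a region from a VCF file
#'
#' Parses the GT field of a VCF (via the vcfR package) into a
#' [region_genotypes] object. Records are required to be biallelic;
#' multiallelic records are dropped with a warning. Dosages are oriented to
#' the pooled minor allele, so a site whose ALT allele is the major allele in
#' the sample has its ALT counts flipped. Phenotypes are not part of VCF;
#' supply them here.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param phenotype Binary phenotype vector, one entry per VCF sample, in
#'   VCF sample order.
#' @param region Optional length-2 numeric `c(start, end)` restricting to
#'   POS within the closed interval.
#' @return A [region_genotypes] object.
#' @export
read_vcf <- function(path, phenotype, region = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package.", call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF: ", conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sprintf("dropping %d multiallelic record(s).", sum(multi)))
    keep <- keep & !multi
  }
  if (!is.null(region)) keep <- keep & pos >= region[1] & pos <= region[2]
  if (!any(keep)) stop("no biallelic variants in the requested region.", call. = FALSE)
  gt <- vcfR::extract.gt(vcf[keep, ], element = "GT")
  # alt-allele dosage from GT strings; anything uncalled -> NA
  count_alt <- function(x) {
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
  }
  dos <- apply(gt, 1, count_alt)           # samples x variants
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":", pos[keep])[is.na(ids) | ids == "."]
  variants <- tibble::tibble(id = make.unique(ids), position = pos[keep])
  region_genotypes(dos, phenotype, variants = variants, samples = colnames(gt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a dosage table
#'
#' The tabular interchange format of the package: a TSV with columns
#' `sample`, `phenotype`, then one integer column of minor-allele dosages per
#' variant. Writing then reading a region round-trips bit-exactly.
#'
#' @param path File path.
#' @return `read_dosage_table()` returns a [region_genotypes] object;
#'   `write_dosage_table()` invisibly returns `path`.
#' @export
read_dosage_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (!all(c("sample", "phenotype") %in% names(tbl))) {
    stop("dosage table needs `sample` and `phenotype` columns.", call. = FALSE)
  }
  vcols <- setdiff(names(tbl), c("sample", "phenotype"))
  if (length(vcols) == 0) stop("dosage table contains no variant columns.", call. = FALSE)
  d <- as.matrix(tbl[vcols])
  ok <- is.na(d) | d %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("dosage entries must be 0, 1, 2 or NA.", call. = FALSE)
  }
  region_genotypes(d, tbl$phenotype,
                   variants = tibble::tibble(id = vcols),
                   samples = tbl$sample)
}

#' @param g A [region_genotypes] object to write.
#' @rdname read_dosage_table
#' @export
write_dosage_table <- function(g, path) {
  stopifnot(inherits(g, "region_genotypes"))
  tbl <- tibble::tibble(sample = g$samples, phenotype = g$phenotype)
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(g$dosage))
  readr::write_tsv(tbl, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a per-variant carrier-count table
#'
#' Published association tables often report, per variant, only the number of
#' heterozygous carriers among cases and among controls. This reader parses
#' that summary format: metadata lines `#n_cases=` and `#n_controls=`
#' followed by a TSV with columns `variant_id`, `position`,
#' `carriers_cases`, `carriers_controls`.
#'
#' @param path File path.
#' @return A `carrier_table`: a tibble with attributes `n_cases`,
#'   `n_controls`.
#' @export
read_carrier_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) != 1) stop("carrier table must declare #", key, "=", call. = FALSE)
    as.integer(sub(paste0("^#", key, "="), "", hit))
  }
  n_cases <- getm("n_cases")
  n_controls <- getm("n_controls")
  tbl <- readr::read_tsv(I(grep("^#", lines, value = TRUE, invert = TRUE)),
                         col_types = "ciii", progress = FALSE)
  carrier_table(tbl, n_cases = n_cases, n_controls = n_controls)
}

#' Construct a carrier table from counts
#'
#' @param variants Data frame with columns `variant_id`, `position`,
#'   `carriers_cases`, `carriers_controls`.
#' @param n_cases,n_controls Group sizes the counts refer to.
#' @return A `carrier_table` tibble.
#' @export
carrier_table <- function(variants, n_cases, n_controls) {
  tbl <- tibble::as_tibble(variants)
  need <- c("variant_id", "position", "carriers_cases", "carriers_controls")
  if (!all(need %in% names(tbl))) {
    stop("carrier table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(tbl$carriers_cases > n_cases) || any(tbl$carriers_controls > n_controls)) {
    stop("carrier counts cannot exceed the group size.", call. = FALSE)
  }
  structure(tbl, n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
            class = c("carrier_table", class(tbl)))
}

#' Reconstruct a surrogate genotype matrix from carrier counts
#'
#' Builds a deterministic samples-by-variants dosage matrix whose per-variant
#' case/control allele counts reproduce a published carrier table exactly.
#' Every carrier is heterozygous. By default carriers of different variants
#' are assigned to distinct samples in a fixed order (disjoint carriers):
#' for variants this rare, co-carriers are close to certain to be different
#' people, and the published marginal counts carry no information about
#' overlap. Set `disjoint = FALSE` to place each variant's carriers uniformly
#' at random instead (requires a seeded RNG for reproducibility).
#'
#' @param table A `carrier_table` (see [read_carrier_table()]).
#' @param disjoint Assign carriers of different variants to distinct samples
#'   (default `TRUE`).
#' @return A [region_genotypes] object with `n_cases + n_controls` samples.
#' @export
from_carrier_table <- function(table, disjoint = TRUE) {
  stopifnot(inherits(table, "carrier_table"))
  n_cases <- attr(table, "n_cases")
  n_controls <- attr(table, "n_controls")
  n <- n_cases + n_controls
  p <- nrow(table)
  if (disjoint &&
      (sum(table$carriers_cases) > n_cases || sum(table$carriers_controls) > n_controls)) {
    stop("disjoint carrier assignment infeasible: total carriers exceed group size.",
         call. = FALSE)
  }
  d <- matrix(0L, n, p)
  nxt_case <- 1L
  nxt_ctrl <- n_cases + 1L
  for (j in seq_len(p)) {
    a <- table$carriers_cases[j]
    b <- table$carriers_controls[j]
    if (disjoint) {
      if (a > 0) d[nxt_case:(nxt_case + a - 1L), j] <- 1L
      if (b > 0) d[nxt_ctrl:(nxt_ctrl + b - 1L), j] <- 1L
      nxt_case <- nxt_case + a
      nxt_ctrl <- nxt_ctrl + b
    } else {
      if (a > 0) d[sample.int(n_cases, a), j] <- 1L
      if (b > 0) d[n_cases + sample.int(n_controls, b), j] <- 1L
    }
  }
  region_genotypes(
    d, c(rep(1L, n_cases), rep(0L, n_controls)),
    variants = tibble::tibble(id = table$variant_id, position = table$position)
  )
}

#' ANGPTL4 resequencing worked example
#'
#' The 17 rare and low-frequency ANGPTL4 variants observed among 198
#' high-triglyceride cases and 202 low-triglyceride controls (European
#' Americans of the Dallas Heart Study resequencing effort), shipped as a
#' carrier-count table and reconstructed with disjoint heterozygous carriers.
#' All 17 variants have pooled MAF below 5%, so the region is its own
#' analysis marker set.
#'
#' @return A 400-sample, 17-variant [region_genotypes] object.
#' @export
#' @examples
#' g <- angptl4_example()
#' per_site_scan(g)
angptl4_example <- function() {
  path <- system.file("extdata", "angptl4_carriers.tsv", package = "rarepinpoint")
  from_carrier_table(read_carrier_table(path))
}
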