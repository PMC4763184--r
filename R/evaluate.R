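#' Score a selected variant set against simulation truth
#'
#' Counts true positives (selected and causal), false positives (selected
#' but not causal) and the positive predictive value
#' `PPV = TP / (TP + FP)`. When nothing is selected the PPV is undefined
#' (`NA`), not zero — an empty selection makes no precision claim.
#'
#' @param selected Character vector of selected variant ids.
#' @param truth Character vector of truly causal variant ids.
#' @param gene_test_p Optional region-level test P-value, carried along for
#'   significance-stratified summaries.
#' @param method Optional method label.
#' @return A one-row tibble: `method`, `tp`, `fp`, `n_selected`, `ppv`,
#'   `gene_test_p`.
#' @export
#' @examples
#' score_selection(c("a", "b", "c"), c("a", "d"))   # tp 1, fp 2, ppv 1/3
score_selection <- function(selected, truth, gene_test_p = NA_real_,
                            method = NA_character_) {
  selected <- unique(as.character(selected))
  truth <- unique(as.character(truth))
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  tibble::tibble(
    method = method,
    tp = tp,
    fp = fp,
    n_selected = tp + fp,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    gene_test_p = gene_test_p
  )
}

#' Summarise selection outcomes across replicates
#'
#' For each method and each significance stratum ("all", then
#' `gene_test_p <= cutoff` for every requested cutoff), reports the mean,
#' standard deviation and coefficient of variation (SD/mean) of the
#' true-positive count, false-positive count and PPV, along with the number
#' of replicates in the stratum. Two PPV conventions are reported: the
#' headline `ppv_mean` averages over replicates that selected at least one
#' variant (undefined PPVs excluded); `ppv_mean_zero` counts an empty
#' selection as PPV 0.
#'
#' @param outcomes A tibble of [score_selection()] rows (one per replicate).
#' @param strata Numeric P-value cutoffs for the significance-restricted
#'   rows (default `c(0.05, 0.01, 0.001)`).
#' @return A tibble with one row per method x stratum.
#' @export
summarize_selections <- function(outcomes, strata = c(0.05, 0.01, 0.001)) {
  stopifnot(nrow(outcomes) >= 1)
  cv <- function(x) {
    m <- mean(x, na.rm = TRUE)
    if (!is.finite(m) || m == 0) return(NA_real_)
    sd(x, na.rm = TRUE) / m
  }
  one_stratum <- function(df, label) {
    df |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        stratum = label,
        n_replicates = dplyr::n(),
        tp_mean = mean(.data$tp), tp_sd = sd(.data$tp), tp_cv = cv(.data$tp),
        fp_mean = mean(.data$fp), fp_sd = sd(.data$fp), fp_cv = cv(.data$fp),
        ppv_mean = mean(.data$ppv, na.rm = TRUE),
        ppv_sd = sd(.data$ppv, na.rm = TRUE),
        ppv_cv = cv(.data$ppv),
        ppv_mean_zero = mean(dplyr::coalesce(.data$ppv, 0)),
        .groups = "drop"
      )
  }
  out <- one_stratum(outcomes, "all")
  for (s in strata) {
    sub <- dplyr::filter(outcomes, !is.na(.data$gene_test_p), .data$gene_test_p <= s)
    lab <- paste0("p<=", format(s))
    if (nrow(sub) > 0) {
      out <- dplyr::bind_rows(out, one_stratum(sub, lab))
    } else {
      out <- dplyr::bind_rows(out, tibble::tibble(
        method = unique(outcomes$method), stratum = lab, n_replicates = 0L
      ))
    }
  }
  dplyr::arrange(out, .data$method,
                 match(.data$stratum, c("all", paste0("p<=", format(strata)))))
}

#' Rank methods by positive predictive value
#'
#' Orders the "all replicates" rows of a [summarize_selections()] table by
#' mean PPV, descending, and attaches the TP/FP signal-to-noise ratio.
#' Because `a/(a+b) > c/(c+d)` exactly when `a/b > c/d` for positive
#' counts, the PPV ordering and the TP/FP-ratio ordering always agree.
#'
#' @param summary A [summarize_selections()] tibble.
#' @return A tibble with `method`, `ppv_mean`, `tp_fp_ratio` and `rank`.
#' @export
rank_methods <- function(summary) {
  all_rows <- dplyr::filter(summary, .data$stratum == "all")
  if (nrow(all_rows) == 0) stop("summary has no 'all' stratum.", call. = FALSE)
  all_rows |>
    dplyr::mutate(tp_fp_ratio = .data$tp_mean / .data$fp_mean) |>
    dplyr::arrange(dplyr::desc(.data$ppv_mean)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("method", "ppv_mean", "tp_fp_ratio", "rank")
}
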