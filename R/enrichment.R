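#' Single-organism GO term enrichment
#'
#' Over-representation analysis of a study set (typically the disordered
#' proteins of one organism) against a background set (the full filtered
#' proteome, or its annotated subset), per GO term of an expanded
#' annotation set. The p-value is the one-sided hypergeometric upper tail
#' `P(X >= study_hits)`; the `"ease"` method is the conservative variant
#' that removes one study hit before taking the tail (floored at 0 hits,
#' where p = 1). Benjamini-Hochberg adjustment is applied across all
#' tested terms.
#'
#' @param study Character vector of study protein ids; must be a subset of
#'   `background`.
#' @param background Character vector of background protein ids.
#' @param annotations Expanded `annotation_set`.
#' @param method `"fisher"` or `"ease"`.
#' @param background_mode `"annotated"` (default: restrict the background
#'   to proteins carrying at least one annotation) or `"all"`.
#' @return A [tibble::tibble()] with one row per term: `term_id`,
#'   `study_hits`, `study_size`, `background_hits`, `background_size`,
#'   `fold_enrichment`, `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
term_enrichment <- function(study, background, annotations,
                            method = c("fisher", "ease"),
                            background_mode = c("annotated", "all")) {
  method <- match.arg(method)
  background_mode <- match.arg(background_mode)
  study <- unique(study); background <- unique(background)
  if (!all(study %in% background))
    stop("study set must be a subset of the background")
  if (!isTRUE(annotations$expanded))
    stop("term_enrichment requires an expanded annotation set")
  if (background_mode == "annotated") {
    background <- intersect(background, names(annotations$protein2term))
    study <- intersect(study, background)
  }
  N <- length(background)
  n <- length(study)
  rows <- lapply(names(annotations$term2protein), function(t) {
    members <- intersect(annotations$term2protein[[t]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, study))
    k_eff <- if (method == "ease") max(k - 1L, 0L) else k
    p <- if (k_eff == 0L) 1 else
      stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = t, study_hits = k, study_size = n,
                   background_hits = K, background_size = N,
                   fold_enrichment =
                     if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_,
                   p_raw = min(1, p))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) return(res)
  res$p_adj <- bh_adjust(res$p_raw)
  res[order(res$p_raw, res$term_id), ]
}

#' Filter enrichment results
#'
#' Standard post-filter on an adjusted enrichment table: keep terms with
#' `p_adj <= alpha` (boundary inclusive) and at least `min_count` study
#' proteins.
#'
#' @param results Table from [term_enrichment()].
#' @param alpha Adjusted p-value cutoff, default 0.05.
#' @param min_count Minimum study hits, default 2.
#' @return Filtered table.
#' @export
filter_enrichment <- function(results, alpha = 0.05, min_count = 2L) {
  if (nrow(results) == 0L) return(results)
  results[results$p_adj <= alpha & results$study_hits >= min_count, ]
}
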