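#' Build a per-term 2x2 disorder contingency table
#'
#' For one GO term, counts disordered vs non-disordered proteins among the
#' proteins annotated to the term in each organism.
#'
#' @param term_id Term identifier; must be annotated in both organisms.
#' @param flags_a,flags_b Named logical vectors: protein id -> disordered
#'   under the declared criterion.
#' @param ann_a,ann_b Expanded `annotation_set`s for the two organisms.
#' @return One-row [tibble::tibble()] with columns `term_id`, `d_a`,
#'   `nd_a`, `d_b`, `nd_b`.
#' @export
build_contingency <- function(term_id, flags_a, flags_b, ann_a, ann_b) {
  pa <- ann_a$term2protein[[term_id]]
  pb <- ann_b$term2protein[[term_id]]
  if (is.null(pa) || is.null(pb))
    stop("term ", term_id, " is not annotated in both organisms")
  fa <- flags_a[intersect(pa, names(flags_a))]
  fb <- flags_b[intersect(pb, names(flags_b))]
  tibble::tibble(term_id = term_id,
                 d_a = sum(fa), nd_a = sum(!fa),
                 d_b = sum(fb), nd_b = sum(!fb))
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson's chi-square with Yates' continuity correction,
#' `sum((|O - E| - c)^2 / E)` with the correction capped at
#' `c = min(0.5, |O - E|)` in every cell, so the statistic is exactly 0
#' when observed equals expected. The p-value comes from the chi-square
#' distribution with 1 degree of freedom. A table with a zero marginal is
#' degenerate: statistic 0, p 1, flagged.
#'
#' @param d_a,nd_a,d_b,nd_b Cell counts (disordered / non-disordered in
#'   organisms A and B).
#' @return List with `statistic`, `p`, `expected_d_a` (expected count of
#'   disordered proteins in organism A under independence) and
#'   `degenerate`.
#' @export
chi2_yates <- function(d_a, nd_a, d_b, nd_b) {
  o <- c(d_a, nd_a, d_b, nd_b)
  stopifnot(all(o >= 0), sum(o) > 0)
  n <- sum(o)
  row_a <- d_a + nd_a; row_b <- d_b + nd_b
  col_d <- d_a + d_b;  col_nd <- nd_a + nd_b
  e_da <- row_a * col_d / n
  if (row_a == 0 || row_b == 0 || col_d == 0 || col_nd == 0) {
    return(list(statistic = 0, p = 1, expected_d_a = e_da,
                degenerate = TRUE))
  }
  e <- c(e_da, row_a * col_nd / n, row_b * col_d / n, row_b * col_nd / n)
  dev <- abs(o - e)
  cc <- pmin(0.5, dev)
  stat <- sum((dev - cc)^2 / e)
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       expected_d_a = e_da,
       degenerate = FALSE)
}

#' Directional excess filter
#'
#' Keeps only classes where the observed disordered count in organism A
#' exceeds the chi-square expected count by at least `min_excess`
#' (fractionally), so that only classes whose disorder difference favors
#' organism A are reported. With `expected = 0` the filter passes iff any
#' disordered protein is observed (degenerate convention).
#'
#' @param observed Observed disordered count in organism A.
#' @param expected Expected count under independence.
#' @param min_excess Minimum fractional excess, default 0.05 (5%).
#' @return Logical.
#' @export
excess_filter <- function(observed, expected, min_excess = 0.05) {
  if (expected == 0) return(observed > 0)
  observed >= (1 + min_excess) * expected
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, returned in input order and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test of location difference. When the pooled sample
#' has at most `exact_max` observations and no ties, the null distribution
#' of the rank sum is obtained by exhaustive enumeration of all
#' `choose(n + m, n)` labelings. Otherwise an asymptotic approximation is
#' used: a continuity-corrected normal with an Edgeworth kurtosis term
#' (the rank-sum null has excess kurtosis
#' `-(6/5)(n^2 + m^2 + nm + n + m) / (nm(N + 1))`, which the correction
#' restores); with ties the variance is tie-corrected and the kurtosis
#' term is dropped.
#'
#' @param xs,ys Non-empty numeric samples.
#' @param exact_max Pooled-size limit for the exact route, default 12.
#' @return List with `statistic` (rank sum of `xs`), `p` (two-sided) and
#'   `method` (`"exact"` or `"approx"`).
#' @export
rank_sum_test <- function(xs, ys, exact_max = 12L) {
  if (length(xs) == 0L || length(ys) == 0L)
    stop("rank_sum_test requires non-empty samples")
  n <- length(xs); m <- length(ys)
  N <- n + m
  pooled <- c(xs, ys)
  rk <- rank(pooled)
  w <- sum(rk[seq_len(n)])
  mu <- n * (N + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (N <= exact_max && !ties) {
    combs <- utils::combn(N, n)
    sums <- colSums(matrix(rk[combs], nrow = n))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(list(statistic = w, p = p, method = "exact"))
  }
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = w, p = 1, method = "approx"))
  g2 <- if (ties) 0 else
    -(6 / 5) * (n^2 + m^2 + n * m + N) / (n * m * (N + 1))
  # symmetric lower-tail point with continuity correction
  z <- (mu - abs(w - mu) + 0.5 - mu) / sqrt(sigma2)
  lower <- stats::pnorm(z) -
    stats::dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
  list(statistic = w, p = min(1, max(0, 2 * lower)), method = "approx")
}

#' Per-class cross-organism disorder comparison
#'
#' The core comparative analysis. For every GO term shared between the two
#' organisms, the disorder of its annotated proteins is contrasted between
#' organisms A and B:
#' \itemize{
#'   \item Binary criteria (`"pct50"`: at least 50% disordered residues;
#'     `"ldw"`: at least one long disordered window; `"dbr"`: at least one
#'     disordered binding region): a 2x2 contingency table and a
#'     Yates-corrected chi-square test, with the directional excess filter
#'     retaining classes whose observed disordered count in A exceeds
#'     expectation by `min_excess`.
#'   \item Quantitative criteria (a percentage column of the metrics
#'     table, e.g. `"pct_disordered"`): a two-sided Wilcoxon rank-sum test
#'     on the per-protein values within the class; direction requires
#'     `mean_a > mean_b`.
#' }
#' Benjamini-Hochberg correction is applied across all terms tested in
#' the run; a class is `significant` when `p_adj <= alpha` and it passes
#' the direction filter.
#'
#' @param metrics_a,metrics_b Metrics tables (from [metrics_table()]) for
#'   the two organisms.
#' @param ann_a,ann_b Expanded `annotation_set`s.
#' @param criterion `"pct50"`, `"ldw"`, `"dbr"`, or the name of a numeric
#'   metrics column for the quantitative path.
#' @param alpha Significance level on adjusted p-values, default 0.05.
#' @param min_excess Directional excess fraction, default 0.05.
#' @param min_n Minimum annotated proteins (with metrics) per organism for
#'   a term to be tested, default 1.
#' @return A [tibble::tibble()], one row per tested term. Chi-square path
#'   columns: `term_id`, counts, `expected_d_a`, `chi2_stat`, `p_raw`,
#'   `p_adj`, `passes_excess_filter`, `significant`. Rank-sum path:
#'   `term_id`, `n_a`, `n_b`, `mean_a`, `mean_b`, `statistic`, `p_raw`,
#'   `p_adj`, `a_greater`, `significant`.
#' @export
compare_classes <- function(metrics_a, metrics_b, ann_a, ann_b,
                            criterion = "ldw", alpha = 0.05,
                            min_excess = 0.05, min_n = 1L) {
  terms <- shared_terms(ann_a, ann_b)
  binary <- criterion %in% c("pct50", "ldw", "dbr")
  if (length(terms) == 0L) {
    warning("no shared terms between the two annotation sets")
    return(tibble::tibble(term_id = character()))
  }
  if (binary) {
    flags_a <- criterion_flags(metrics_a, criterion)
    flags_b <- criterion_flags(metrics_b, criterion)
    rows <- lapply(terms, function(t) {
      ct <- build_contingency(t, flags_a, flags_b, ann_a, ann_b)
      if (ct$d_a + ct$nd_a < min_n || ct$d_b + ct$nd_b < min_n)
        return(NULL)
      ts <- chi2_yates(ct$d_a, ct$nd_a, ct$d_b, ct$nd_b)
      dplyr::mutate(ct,
                    expected_d_a = ts$expected_d_a,
                    observed_d_a = ct$d_a,
                    chi2_stat = ts$statistic,
                    p_raw = ts$p,
                    degenerate = ts$degenerate,
                    passes_excess_filter =
                      excess_filter(ct$d_a, ts$expected_d_a, min_excess))
    })
    res <- dplyr::bind_rows(rows)
    if (nrow(res) == 0L) return(res)
    res$p_adj <- bh_adjust(res$p_raw)
    res$significant <- res$p_adj <= alpha & res$passes_excess_filter
  } else {
    if (!criterion %in% names(metrics_a))
      stop("unknown criterion/metric: ", criterion)
    va <- stats::setNames(metrics_a[[criterion]], metrics_a$protein_id)
    vb <- stats::setNames(metrics_b[[criterion]], metrics_b$protein_id)
    rows <- lapply(terms, function(t) {
      xa <- va[intersect(ann_a$term2protein[[t]], names(va))]
      xb <- vb[intersect(ann_b$term2protein[[t]], names(vb))]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < max(1L, min_n) || length(xb) < max(1L, min_n))
        return(NULL)
      ts <- rank_sum_test(xa, xb)
      tibble::tibble(term_id = t, n_a = length(xa), n_b = length(xb),
                     mean_a = mean(xa), mean_b = mean(xb),
                     statistic = ts$statistic, p_raw = ts$p)
    })
    res <- dplyr::bind_rows(rows)
    if (nrow(res) == 0L) return(res)
    res$p_adj <- bh_adjust(res$p_raw)
    res$a_greater <- res$mean_a > res$mean_b
    res$significant <- res$p_adj <= alpha & res$a_greater
  }
  res[order(res$p_adj, res$p_raw, res$term_id), ]
}

criterion_flags <- function(metrics, criterion) {
  f <- switch(criterion,
              pct50 = metrics$is_disordered_protein,
              ldw = metrics$n_ldw >= 1L,
              dbr = metrics$n_dbr >= 1L)
  keep <- !is.na(f)
  stats::setNames(f[keep], metrics$protein_id[keep])
}
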