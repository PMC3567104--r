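#' Read an ortholog pair table
#'
#' Plain TSV with columns `id_a`, `id_b` and optionally `group` and
#' `score` (header optional, detected from the first line).
#'
#' @param path File path.
#' @return A [tibble::tibble()] with columns `id_a`, `id_b`, `group`,
#'   `score`.
#' @export
read_orthologs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(tibble::tibble(id_a = character(), id_b = character(),
                          group = character(), score = numeric()))
  if (grepl("^id_a\t", lines[[1]])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("ortholog row with < 2 fields")
  tibble::tibble(
    id_a = vapply(parts, `[[`, character(1), 1L),
    id_b = vapply(parts, `[[`, character(1), 2L),
    group = vapply(parts, function(p)
      if (length(p) >= 3) p[[3]] else NA_character_, character(1)),
    score = vapply(parts, function(p)
      if (length(p) >= 4) as.numeric(p[[4]]) else NA_real_, numeric(1))
  )
}

#' Class-level disorder summary over ortholog pairs
#'
#' For one GO term, restricts to cross-organism ortholog pairs whose
#' members resolve to the metrics tables and are annotated to the term
#' (by default in either organism), and averages a disorder metric over
#' the organism-A and organism-B sides of the retained pairs. This is the
#' annotation-bias control: the same (comparable) proteins enter both
#' means.
#'
#' @param term_id GO term.
#' @param pairs Ortholog table from [read_orthologs()].
#' @param metrics_a,metrics_b Per-protein metrics tables.
#' @param ann_a,ann_b Expanded `annotation_set`s.
#' @param metric Metrics column to average, default `"pct_disordered"`.
#' @param membership `"either"` (a pair counts when either member is
#'   annotated to the term; default, maximizes usable pairs) or `"both"`.
#' @return One-row [tibble::tibble()]: `term_id`, `n_pairs`,
#'   `mean_disorder_a`, `mean_disorder_b` (NA when `n_pairs` is 0),
#'   `a_greater`.
#' @export
class_ortholog_summary <- function(term_id, pairs, metrics_a, metrics_b,
                                   ann_a, ann_b,
                                   metric = "pct_disordered",
                                   membership = c("either", "both")) {
  membership <- match.arg(membership)
  va <- stats::setNames(metrics_a[[metric]], metrics_a$protein_id)
  vb <- stats::setNames(metrics_b[[metric]], metrics_b$protein_id)
  ok <- pairs$id_a %in% names(va) & pairs$id_b %in% names(vb)
  pairs <- pairs[ok, , drop = FALSE]
  in_a <- pairs$id_a %in% ann_a$term2protein[[term_id]]
  in_b <- pairs$id_b %in% ann_b$term2protein[[term_id]]
  keep <- if (membership == "either") in_a | in_b else in_a & in_b
  pairs <- pairs[keep, , drop = FALSE]
  n <- nrow(pairs)
  ma <- if (n > 0) mean(va[pairs$id_a]) else NA_real_
  mb <- if (n > 0) mean(vb[pairs$id_b]) else NA_real_
  tibble::tibble(term_id = term_id, n_pairs = n,
                 mean_disorder_a = ma, mean_disorder_b = mb,
                 a_greater = if (n > 0) ma > mb else NA)
}

#' Ortholog-restricted t-tests across GO classes
#'
#' Tests, across the class-level ortholog mean pairs, whether the two
#' organisms differ in disorder (two-tailed) and whether organism A's
#' orthologs are more disordered (one-tailed, alternative A > B). The
#' default mode treats the class-level means as matched pairs (paired t);
#' Welch's two-sample t is offered as an alternative.
#'
#' @param summaries Table of rows from [class_ortholog_summary()]; classes
#'   with `n_pairs == 0` are dropped.
#' @param mode `"paired"` (default) or `"welch"`.
#' @return List with `n_classes`, `grand_mean_a`, `grand_mean_b`,
#'   `n_a_greater`, `t_two_sided`, `p_two_sided`, `t_one_sided`,
#'   `p_one_sided`, `mode`.
#' @export
ortholog_t_tests <- function(summaries, mode = c("paired", "welch")) {
  mode <- match.arg(mode)
  s <- summaries[summaries$n_pairs > 0, , drop = FALSE]
  if (nrow(s) < 2L)
    stop("ortholog_t_tests needs at least 2 classes with pairs")
  a <- s$mean_disorder_a; b <- s$mean_disorder_b
  if (mode == "paired") {
    two <- stats::t.test(a, b, paired = TRUE)
    one <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  } else {
    two <- stats::t.test(a, b)
    one <- stats::t.test(a, b, alternative = "greater")
  }
  list(n_classes = nrow(s),
       grand_mean_a = mean(a), grand_mean_b = mean(b),
       n_a_greater = sum(s$a_greater),
       t_two_sided = unname(two$statistic), p_two_sided = two$p.value,
       t_one_sided = unname(one$statistic), p_one_sided = one$p.value,
       mode = mode)
}
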