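#' Parse per-residue disorder score tracks
#'
#' Reads predictor output into per-protein score vectors. Two dialects are
#' supported:
#' \describe{
#'   \item{`long_tsv`}{columns `protein_id`, `position` (1-based),
#'     optionally `residue`, and `score`; positions must be contiguous
#'     from 1 within each protein.}
#'   \item{`horizontal`}{one line per protein: `protein_id` followed by a
#'     tab-delimited list of scores.}
#' }
#' All scores must lie in \[0, 1\].
#'
#' @param path Path to the score file (TSV, optional header for
#'   `long_tsv` detected from a non-numeric second field).
#' @param dialect `"long_tsv"` or `"horizontal"`.
#' @param predictor Name recorded with the profiles (e.g. `"disopred"`).
#' @return A named list of numeric score vectors (one per protein), with
#'   attribute `predictor`.
#' @export
parse_scores <- function(path, dialect = c("long_tsv", "horizontal"),
                         predictor = "unknown") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty score file: ", path)
  if (dialect == "horizontal") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[[`, character(1), 1L)
    profiles <- lapply(parts, function(p) {
      s <- suppressWarnings(as.numeric(p[-1]))
      if (anyNA(s)) stop("non-numeric score for protein ", p[[1]])
      s
    })
    names(profiles) <- ids
  } else {
    first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    if (length(first) < 3L)
      stop("long_tsv needs at least protein_id, position, score columns")
    has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
    if (has_header) lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L)) stop("long_tsv row with fewer than 3 fields")
    ids <- vapply(parts, `[[`, character(1), 1L)
    pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
    sc <- as.numeric(vapply(parts, function(p) p[[length(p)]], character(1)))
    if (anyNA(pos) || anyNA(sc)) stop("non-numeric position or score")
    o <- order(match(ids, unique(ids)), pos)
    profiles <- split(sc[o], factor(ids[o], levels = unique(ids)))
    for (id in names(profiles)) {
      p <- sort(pos[ids == id])
      if (!identical(p, seq_along(p))) {
        gap <- setdiff(seq_len(max(p)), p)[1]
        stop("positions for protein ", id,
             " are not contiguous from 1 (missing position ", gap, ")")
      }
    }
    profiles <- lapply(profiles, unname)
  }
  bad <- vapply(profiles, function(s) any(s < 0 | s > 1), logical(1))
  if (any(bad)) {
    stop("scores outside [0,1] for protein ",
         paste(names(profiles)[bad], collapse = ", "))
  }
  structure(profiles, predictor = predictor)
}

#' Binarize a disorder score profile
#'
#' A residue is called disordered when its score is greater than or equal
#' to the threshold (boundary inclusive). Predictor defaults in the
#' literature are 0.5 (VSL2, IUPred) and 0.05 (Disopred).
#'
#' @param scores Numeric vector of per-residue scores in \[0, 1\].
#' @param threshold Calling threshold, strictly between 0 and 1.
#' @return Logical vector, `TRUE` = disordered, with attribute
#'   `threshold`.
#' @export
binarize <- function(scores, threshold = 0.5) {
  stopifnot(is.numeric(scores), threshold > 0, threshold < 1)
  structure(scores >= threshold, threshold = threshold)
}

#' Find long disordered windows
#'
#' Maximal runs of consecutive `TRUE` flags of length at least `min_len`
#' (the field's usual long-disordered-window definition uses 30 residues).
#' Coordinates are half-open and 0-based: a window `(start, end)` covers
#' residues `start+1 .. end` in 1-based terms.
#'
#' @param mask Logical per-residue vector (`TRUE` = disordered).
#' @param min_len Minimum run length; default 30.
#' @return A [tibble::tibble()] with columns `start`, `end`, sorted,
#'   non-overlapping.
#' @export
long_windows <- function(mask, min_len = 30L) {
  stopifnot(is.logical(mask), min_len >= 1)
  if (length(mask) == 0L)
    return(tibble::tibble(start = integer(), end = integer()))
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = as.integer(starts[keep]),
                 end = as.integer(ends[keep]))
}

#' Per-protein disorder metrics
#'
#' Summarizes a binary disorder mask (and optionally a disordered-binding
#' mask) into the standard per-protein metrics: percentage of disordered
#' residues, number of long disordered windows (LDWs), percentage of
#' residues inside LDWs, the disordered-protein flag (at least
#' `disordered_protein_cutoff`% disordered residues, boundary inclusive),
#' and the analogous counts for disordered binding regions (DBRs, maximal
#' runs of the binding mask of length `dbr_min_len` or more).
#'
#' @param disorder_mask Logical per-residue disorder mask.
#' @param dbr_mask Optional logical binding mask of the same length; when
#'   `NULL` the DBR fields are `NA`.
#' @param protein_id Identifier recorded in the output row.
#' @param ldw_min Minimum LDW length (residues), default 30.
#' @param disordered_protein_cutoff Percent cutoff for the
#'   disordered-protein flag, default 50.
#' @param dbr_min_len Minimum DBR length (residues), default 6.
#' @return One-row [tibble::tibble()] with columns `protein_id`, `length`,
#'   `pct_disordered`, `n_ldw`, `pct_in_ldw`, `is_disordered_protein`,
#'   `n_dbr`, `pct_dbr_residues`.
#' @export
compute_metrics <- function(disorder_mask, dbr_mask = NULL,
                            protein_id = NA_character_,
                            ldw_min = 30L,
                            disordered_protein_cutoff = 50,
                            dbr_min_len = 6L) {
  stopifnot(is.logical(disorder_mask), length(disorder_mask) > 0,
            disordered_protein_cutoff > 0, disordered_protein_cutoff <= 100)
  n <- length(disorder_mask)
  if (!is.null(dbr_mask) && length(dbr_mask) != n) {
    stop("dbr_mask length (", length(dbr_mask),
         ") does not match disorder mask length (", n, ")")
  }
  pct <- 100 * sum(disorder_mask) / n
  lw <- long_windows(disorder_mask, ldw_min)
  pct_ldw <- 100 * sum(lw$end - lw$start) / n
  if (is.null(dbr_mask)) {
    n_dbr <- NA_integer_; pct_dbr <- NA_real_
  } else {
    dr <- long_windows(dbr_mask, dbr_min_len)
    n_dbr <- nrow(dr)
    pct_dbr <- 100 * sum(dr$end - dr$start) / n
  }
  tibble::tibble(
    protein_id = protein_id,
    length = n,
    pct_disordered = pct,
    n_ldw = nrow(lw),
    pct_in_ldw = pct_ldw,
    is_disordered_protein = pct >= disordered_protein_cutoff,
    n_dbr = n_dbr,
    pct_dbr_residues = pct_dbr
  )
}

#' Disorder metrics for a collection of profiles
#'
#' Convenience wrapper: binarizes each score profile and computes the
#' per-protein metrics table.
#'
#' @param profiles Named list of score vectors (see [parse_scores()]).
#' @param dbr_profiles Optional named list of binding score vectors; the
#'   names must be a superset of `names(profiles)` for proteins with DBR
#'   tracks, proteins without one get `NA` DBR fields.
#' @param threshold,dbr_threshold Binarization thresholds for the two
#'   track types.
#' @inheritParams compute_metrics
#' @return A [tibble::tibble()] with one row per profile.
#' @export
metrics_table <- function(profiles, dbr_profiles = NULL,
                          threshold = 0.5, dbr_threshold = 0.5,
                          ldw_min = 30L,
                          disordered_protein_cutoff = 50,
                          dbr_min_len = 6L) {
  rows <- lapply(names(profiles), function(id) {
    dm <- binarize(profiles[[id]], threshold)
    bm <- if (!is.null(dbr_profiles) && id %in% names(dbr_profiles))
      binarize(dbr_profiles[[id]], dbr_threshold) else NULL
    compute_metrics(dm, bm, protein_id = id, ldw_min = ldw_min,
                    disordered_protein_cutoff = disordered_protein_cutoff,
                    dbr_min_len = dbr_min_len)
  })
  dplyr::bind_rows(rows)
}

# Kyte-Doolittle hydropathy scale
kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)
charge_scale <- c(K = 1, R = 1, D = -1, E = -1)

#' Built-in composition-based disorder predictor
#'
#' A simple charge/hydropathy sliding-window predictor so the pipeline can
#' run without external predictor output. For each residue a foldability
#' index is computed over a centered window:
#' `f = 2.785 * <H> - |<R>| - 1.151`, where `<H>` is the mean
#' Kyte-Doolittle hydropathy rescaled to \[0, 1\] via `(KD + 4.5) / 9` and
#' `<R>` is the mean net charge (K, R = +1; D, E = -1). Negative `f`
#' indicates a window too polar/charged to fold. The returned score is the
#' logistic squash `1 / (1 + exp(f))`, so `f < 0` maps above 0.5
#' (disordered). Windows are truncated at the termini (no padding).
#'
#' @param sequence Amino-acid string of standard residues.
#' @param window Odd window length, default 51.
#' @return Numeric score vector in \[0, 1\], one value per residue.
#' @export
builtin_predictor <- function(sequence, window = 51L) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            window >= 1, window %% 2 == 1)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) == 0L) stop("empty sequence")
  bad <- !aa %in% names(kd_scale)
  if (any(bad)) {
    stop("nonstandard residue(s) in sequence: ",
         paste(unique(aa[bad]), collapse = ", "))
  }
  n <- length(aa)
  h <- (unname(kd_scale[aa]) + 4.5) / 9
  r <- unname(charge_scale[aa]); r[is.na(r)] <- 0
  half <- (window - 1L) / 2L
  csh <- c(0, cumsum(h)); csr <- c(0, cumsum(r))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  w <- hi - lo + 1
  mh <- (csh[hi + 1L] - csh[lo]) / w
  mr <- (csr[hi + 1L] - csr[lo]) / w
  f <- 2.785 * mh - abs(mr) - 1.151
  1 / (1 + exp(f))
}

#' Bin per-protein metric values into percentage ranges
#'
#' Histograms a percentage-valued metric over ascending bin edges covering
#' \[0, 100\]. Bins are half-open `[a, b)`; the last bin is closed so a
#' value of exactly 100 is counted.
#'
#' @param metrics Metrics table from [metrics_table()].
#' @param field Name of the percentage column to bin
#'   (e.g. `"pct_disordered"`).
#' @param edges Ascending numeric edges starting at 0 and ending at 100;
#'   the default is deciles. A coarse preset `c(0, 30, 50, 100)` mirrors
#'   the low/mid/high ranges often reported.
#' @return A [tibble::tibble()] with columns `bin` (label), `lower`,
#'   `upper`, `count`, `fraction`.
#' @export
bin_fractions <- function(metrics, field = "pct_disordered",
                          edges = seq(0, 100, by = 10)) {
  stopifnot(field %in% names(metrics))
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly ascending")
  if (edges[1] != 0 || edges[length(edges)] != 100)
    stop("edges must cover [0, 100]")
  x <- metrics[[field]]
  x <- x[!is.na(x)]
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  k <- length(edges) - 1L
  counts <- tabulate(idx, nbins = k)
  tibble::tibble(
    bin = paste0("[", edges[-length(edges)], ",", edges[-1],
                 c(rep(")", k - 1L), "]")),
    lower = edges[-length(edges)],
    upper = edges[-1],
    count = counts,
    fraction = if (length(x)) counts / length(x) else rep(0, k)
  )
}
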