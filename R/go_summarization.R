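#' Information content of GO terms
#'
#' Annotation-frequency information content against a reference corpus:
#' `p(t)` is the fraction of the namespace root's annotated proteins that
#' carry term `t` (annotations must be ancestor-expanded, so counts are
#' descendant-inclusive), and `IC(t) = -log p(t)` (natural log). The
#' namespace root has `p = 1`, `IC = 0`. Terms with no annotated protein
#' are excluded with a warning.
#'
#' @param annotations Expanded `annotation_set` serving as the reference
#'   corpus. The corpus is an explicit input: IC values (and hence SimRel)
#'   depend on it.
#' @param dag A `go_dag`.
#' @return A [tibble::tibble()] with columns `term_id`, `namespace`, `p`,
#'   `ic`.
#' @export
information_content <- function(annotations, dag) {
  if (!isTRUE(annotations$expanded))
    stop("information_content requires an expanded annotation set")
  counts <- lengths(annotations$term2protein)
  ns <- stats::setNames(dag$terms$namespace, dag$terms$term_id)
  roots <- dag$terms$term_id[lengths(dag$parents[dag$terms$term_id]) == 0L &
                               !dag$terms$obsolete]
  root_count <- stats::setNames(rep(NA_real_, length(unique(ns))),
                                unique(ns))
  for (r in roots) {
    cnt <- counts[r]
    if (!is.na(cnt)) {
      cur <- root_count[[ns[[r]]]]
      root_count[[ns[[r]]]] <- max(cur, cnt, na.rm = TRUE)
    }
  }
  ids <- intersect(dag$terms$term_id[!dag$terms$obsolete], names(counts))
  zero <- setdiff(dag$terms$term_id[!dag$terms$obsolete], ids)
  if (length(zero))
    warning(length(zero), " term(s) with no annotated protein excluded ",
            "from IC: ", paste(utils::head(zero, 5), collapse = ", "))
  p <- pmin(1, counts[ids] / root_count[ns[ids]])
  tibble::tibble(term_id = ids,
                 namespace = unname(ns[ids]),
                 p = unname(p),
                 ic = -log(unname(p)))
}

#' SimRel semantic similarity between two GO terms
#'
#' Relevance similarity: with `c` the common ancestor of maximal
#' information content (a term counts as its own ancestor here),
#' `sim = (2 IC(c) / (IC(t1) + IC(t2))) * (1 - p(c))`. The `(1 - p(c))`
#' factor down-weights similarity inherited through very general terms.
#' The value is 0 when the only common ancestor is the root (IC 0), when
#' either term is the root, or when the terms share no ancestor
#' (cross-namespace convention).
#'
#' @param dag A `go_dag`.
#' @param ic IC table from [information_content()].
#' @param t1,t2 Term ids present in `ic`.
#' @return Similarity in \[0, 1\].
#' @export
simrel <- function(dag, ic, t1, t2) {
  icv <- stats::setNames(ic$ic, ic$term_id)
  pv <- stats::setNames(ic$p, ic$term_id)
  if (!t1 %in% names(icv) || !t2 %in% names(icv))
    stop("terms must have information content")
  common <- intersect(c(t1, ancestors(dag, t1)),
                      c(t2, ancestors(dag, t2)))
  common <- intersect(common, names(icv))
  if (length(common) == 0L) return(0)
  c_ic <- max(icv[common])
  denom <- icv[[t1]] + icv[[t2]]
  if (denom == 0 || c_ic == 0) return(0)
  cbest <- common[which.max(icv[common])]
  unname(min(1, (2 * c_ic / denom) * (1 - pv[[cbest]])))
}

simrel_matrix <- function(dag, ic, terms) {
  k <- length(terms)
  m <- matrix(0, k, k, dimnames = list(terms, terms))
  if (k == 0L) return(m)
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      s <- if (i == j) simrel(dag, ic, terms[i], terms[i])
      else simrel(dag, ic, terms[i], terms[j])
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Summarize a GO term list into representative clusters
#'
#' Redundancy reduction of a significant-term list: terms are greedily
#' agglomerated by SimRel similarity (single linkage: at each step the
#' most similar pair of clusters — measured by their most similar
#' cross-pair — is merged while that similarity is at least `threshold`).
#' Each cluster is labeled by the representative member with the best
#' (lowest) p-value, ties broken by higher IC, then lexically smaller
#' term id. Cluster representatives are then joined into loose
#' "superclusters" by the same procedure at `supercluster_threshold`.
#' The uniqueness of a term is one minus its mean similarity to all other
#' input terms; low uniqueness marks redundant terms.
#'
#' @param terms A data frame with columns `term_id` and `p_value` (e.g. a
#'   filtered enrichment or comparison table), or a character vector (all
#'   p-values treated as equal).
#' @param dag A `go_dag`.
#' @param ic IC table from [information_content()].
#' @param threshold Similarity threshold for clustering, default 0.7.
#' @param supercluster_threshold Threshold for joining representatives,
#'   default 0.5.
#' @return A [tibble::tibble()] with columns `term_id`, `p_value`,
#'   `cluster`, `representative`, `supercluster`, `uniqueness`. Clusters
#'   partition the input.
#' @export
summarize_terms <- function(terms, dag, ic, threshold = 0.7,
                            supercluster_threshold = 0.5) {
  if (is.character(terms))
    terms <- tibble::tibble(term_id = terms, p_value = 1)
  if (nrow(terms) == 0L)
    return(tibble::tibble(term_id = character(), p_value = numeric(),
                          cluster = integer(), representative = character(),
                          supercluster = integer(), uniqueness = numeric()))
  ids <- terms$term_id
  if (anyDuplicated(ids)) stop("duplicate term ids in input list")
  missing_ic <- setdiff(ids, ic$term_id)
  if (length(missing_ic))
    stop("terms without information content: ",
         paste(missing_ic, collapse = ", "))
  sim <- simrel_matrix(dag, ic, ids)
  membership <- greedy_single_linkage(sim, threshold)
  icv <- stats::setNames(ic$ic, ic$term_id)
  pv <- stats::setNames(terms$p_value, ids)
  rep_of <- vapply(split(ids, membership), function(members) {
    o <- order(pv[members], -icv[members], members)
    members[o[1]]
  }, character(1))
  reps <- unname(rep_of)
  super_membership <- greedy_single_linkage(
    sim[reps, reps, drop = FALSE], supercluster_threshold)
  super_of_rep <- stats::setNames(super_membership, reps)
  uniq <- if (length(ids) > 1) {
    off <- sim; diag(off) <- NA
    1 - rowMeans(off, na.rm = TRUE)
  } else stats::setNames(1, ids)
  cl <- as.integer(factor(membership, levels = unique(membership)))
  rep_col <- rep_of[as.character(membership)]
  out <- tibble::tibble(
    term_id = ids,
    p_value = unname(pv[ids]),
    cluster = cl,
    representative = unname(rep_col),
    supercluster = as.integer(unname(super_of_rep[rep_col])),
    uniqueness = unname(uniq[ids])
  )
  out[order(out$cluster, out$p_value, out$term_id), ]
}

# Greedy single-linkage agglomeration over a similarity matrix.
# Returns an integer membership vector named by the matrix's rownames.
# Deterministic: among equally similar pairs the one with lexically
# smallest (then next) member ids is merged first.
greedy_single_linkage <- function(sim, threshold) {
  ids <- rownames(sim)
  k <- length(ids)
  membership <- stats::setNames(seq_len(k), ids)
  if (k <= 1) return(membership)
  repeat {
    groups <- unique(membership)
    if (length(groups) == 1L) break
    best <- NULL; best_sim <- -Inf
    for (gi in seq_along(groups)) {
      for (gj in seq_len(gi - 1L)) {
        a <- ids[membership == groups[gi]]
        b <- ids[membership == groups[gj]]
        s <- max(sim[a, b, drop = FALSE])
        pair_key <- paste(sort(c(min(a), min(b))), collapse = "|")
        if (s > best_sim + 1e-12 ||
            (abs(s - best_sim) <= 1e-12 && !is.null(best) &&
             pair_key < best$key)) {
          best <- list(gi = groups[gi], gj = groups[gj], key = pair_key)
          best_sim <- s
        }
      }
    }
    if (is.null(best) || best_sim < threshold) break
    membership[membership == best$gi] <- best$gj
  }
  membership
}
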