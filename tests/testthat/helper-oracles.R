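# Independent brute-force oracles and tiny fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# maximal true-runs of length >= min_len by explicit left-to-right scan
oracle_long_windows <- function(mask, min_len) {
  out <- NULL
  i <- 1L
  n <- length(mask)
  while (i <= n) {
    if (mask[i]) {
      j <- i
      while (j < n && mask[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i - 1L, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# textbook step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hypergeometric upper tail by explicit summation of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  kk <- seq(max(0, n + K - N), min(n, K))
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# two-sided exact rank-sum p by enumeration of all labelings
oracle_ranksum_exact <- function(xs, ys) {
  n <- length(xs)
  rk <- rank(c(xs, ys))
  w <- sum(rk[seq_len(n)])
  mu <- n * (n + length(ys) + 1) / 2
  combs <- combn(n + length(ys), n)
  sums <- colSums(matrix(rk[combs], nrow = n))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}

# reachability of ancestors by repeated naive expansion
oracle_reachable <- function(parents, id) {
  seen <- character()
  frontier <- parents[[id]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier],
                                      use.names = FALSE)), seen)
  }
  seen
}

# random parent map over n nodes (node 1 is the only root), emitted as
# OBO text so tests exercise the parser too
random_obo <- function(n, max_parents = 3L, obsolete = integer()) {
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  parents[[1]] <- character()
  lines <- "format-version: 1.2"
  for (i in seq_len(n)) {
    if (i > 1) {
      np <- sample.int(min(max_parents, i - 1L), 1L)
      parents[[i]] <- sample(ids[seq_len(i - 1L)], np)
    }
    lines <- c(lines, "", "[Term]", paste0("id: ", ids[i]),
               paste0("name: node ", i),
               "namespace: biological_process",
               if (length(parents[[i]]))
                 paste0("is_a: ", parents[[i]]),
               if (i %in% obsolete) "is_obsolete: true")
  }
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  list(path = path, parents = parents, ids = ids)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# tiny chain/diamond ontologies used by several tests
chain_obo <- function() {
  write_tmp(c("format-version: 1.2",
              "", "[Term]", "id: GO:0000001", "name: a",
              "namespace: biological_process",
              "", "[Term]", "id: GO:0000002", "name: b",
              "namespace: biological_process", "is_a: GO:0000001",
              "", "[Term]", "id: GO:0000003", "name: c",
              "namespace: biological_process", "is_a: GO:0000002"),
            ".obo")
}

diamond_obo <- function() {
  write_tmp(c("format-version: 1.2",
              "", "[Term]", "id: GO:0000001", "name: a",
              "namespace: biological_process",
              "", "[Term]", "id: GO:0000002", "name: b",
              "namespace: biological_process", "is_a: GO:0000001",
              "", "[Term]", "id: GO:0000003", "name: c",
              "namespace: biological_process", "is_a: GO:0000001",
              "", "[Term]", "id: GO:0000004", "name: d",
              "namespace: biological_process", "is_a: GO:0000002",
              "is_a: GO:0000003"),
            ".obo")
}

# annotation set spanning a term -> protein design matrix
ann_from_list <- function(term2prot, organism = "x", expanded = TRUE) {
  prot2term <- list()
  for (t in names(term2prot)) {
    for (p in term2prot[[t]]) prot2term[[p]] <- c(prot2term[[p]], t)
  }
  annotation_set(prot2term, organism, expanded = expanded)
}
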