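test_that("build_contingency counts disordered proteins per organism", {
  ann_a <- ann_from_list(list(t1 = c("p1", "p2")), "a")
  ann_b <- ann_from_list(list(t1 = c("q1", "q2", "q3")), "b")
  ct <- build_contingency("t1",
                          c(p1 = TRUE, p2 = FALSE),
                          c(q1 = TRUE, q2 = TRUE, q3 = FALSE),
                          ann_a, ann_b)
  expect_equal(unlist(ct[, c("d_a", "nd_a", "d_b", "nd_b")]),
               c(d_a = 1L, nd_a = 1L, d_b = 2L, nd_b = 1L))
  expect_error(build_contingency("t2", c(p1 = TRUE), c(q1 = TRUE),
                                 ann_a, ann_b), "both organisms")
})

test_that("chi2_yates matches hand evaluation and handles degeneracy", {
  r <- chi2_yates(20, 80, 40, 60)
  expect_equal(r$statistic, 8.595238, tolerance = 1e-6)
  expect_equal(r$p, pchisq(8.595238, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # O = E: capped correction gives exactly 0
  r0 <- chi2_yates(10, 10, 10, 10)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # zero marginal is degenerate
  rz <- chi2_yates(0, 10, 0, 20)
  expect_true(rz$degenerate)
  expect_equal(rz$p, 1)
})

test_that("chi2_yates agrees with the reference implementation", {
  set.seed(21)
  for (i in 1:50) {
    cells <- rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1L
    r <- chi2_yates(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("chi2_yates is invariant under simultaneous row/column swaps", {
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(4, 30) + 1
    a <- chi2_yates(x[1], x[2], x[3], x[4])
    b <- chi2_yates(x[4], x[3], x[2], x[1])
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  }
})

test_that("excess filter is boundary-inclusive with a degenerate rule", {
  expect_true(excess_filter(105, 100))
  expect_false(excess_filter(104, 100))
  expect_true(excess_filter(1, 0))
  expect_false(excess_filter(0, 0))
})

test_that("bh_adjust matches the brute-force step-up procedure", {
  expect_equal(bh_adjust(c(.01, .02, .03, .04)), rep(.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(.5, 7)), rep(.5, 7))
  expect_error(bh_adjust(c(.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:1000, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("rank-sum exact route matches enumeration and wilcox.test", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(r$p, wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value)
  # a rank sum at the null center cannot be extreme
  ri <- rank_sum_test(c(1, 4, 5), c(2, 3, 6))
  expect_equal(ri$p, 1)
  set.seed(41)
  for (i in 1:50) {
    xs <- rnorm(5); ys <- rnorm(6)
    expect_equal(rank_sum_test(xs, ys)$p,
                 oracle_ranksum_exact(xs, ys), tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p at n = m = 6", {
  set.seed(51)
  for (i in 1:100) {
    xs <- rnorm(6); ys <- rnorm(6, mean = runif(1, -1, 1))
    exact <- rank_sum_test(xs, ys, exact_max = 12L)
    approx <- rank_sum_test(xs, ys, exact_max = 0L)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "approx")
    expect_lt(abs(exact$p - approx$p), 0.01)
  }
})

test_that("approximate route separates well-shifted samples", {
  set.seed(61)
  xs <- rnorm(20, 10); ys <- rnorm(20, 0)
  expect_lt(rank_sum_test(xs, ys)$p, 1e-6)
  expect_error(rank_sum_test(numeric(), 1:3), "non-empty")
})

test_that("compare_classes flags a strongly planted term", {
  set.seed(71)
  n <- 200
  ids_a <- paste0("a", 1:n); ids_b <- paste0("b", 1:n)
  flags_a <- setNames(runif(n) < 0.6, ids_a)
  flags_b <- setNames(runif(n) < 0.2, ids_b)
  metrics_a <- tibble::tibble(protein_id = ids_a,
                              n_ldw = as.integer(flags_a))
  metrics_b <- tibble::tibble(protein_id = ids_b,
                              n_ldw = as.integer(flags_b))
  ann_a <- ann_from_list(list(t1 = ids_a), "a")
  ann_b <- ann_from_list(list(t1 = ids_b), "b")
  res <- compare_classes(metrics_a, metrics_b, ann_a, ann_b,
                         criterion = "ldw")
  expect_equal(nrow(res), 1L)
  expect_true(res$significant)
  expect_equal(res$p_adj, res$p_raw)  # single term: BH is the identity
})

test_that("significance requires the organism-A direction", {
  # disorder excess on the B side: huge chi-square but filtered out
  ids_a <- paste0("a", 1:100); ids_b <- paste0("b", 1:100)
  metrics_a <- tibble::tibble(protein_id = ids_a,
                              n_ldw = rep(0:1, c(80, 20)))
  metrics_b <- tibble::tibble(protein_id = ids_b,
                              n_ldw = rep(0:1, c(20, 80)))
  res <- compare_classes(metrics_a, metrics_b,
                         ann_from_list(list(t1 = ids_a), "a"),
                         ann_from_list(list(t1 = ids_b), "b"),
                         criterion = "ldw")
  expect_lt(res$p_raw, 1e-10)
  expect_false(res$passes_excess_filter)
  expect_false(res$significant)
})

test_that("quantitative criterion uses the rank-sum path per class", {
  ids_a <- paste0("a", 1:30); ids_b <- paste0("b", 1:30)
  set.seed(81)
  metrics_a <- tibble::tibble(protein_id = ids_a,
                              pct_disordered = rnorm(30, 60, 5))
  metrics_b <- tibble::tibble(protein_id = ids_b,
                              pct_disordered = rnorm(30, 30, 5))
  res <- compare_classes(metrics_a, metrics_b,
                         ann_from_list(list(t1 = ids_a), "a"),
                         ann_from_list(list(t1 = ids_b), "b"),
                         criterion = "pct_disordered")
  expect_true(res$a_greater)
  expect_true(res$significant)
  expect_lt(res$p_raw, 1e-6)
})

test_that("no shared terms yields an empty table with a warning", {
  a <- ann_from_list(list(t1 = "p1"), "a")
  b <- ann_from_list(list(t2 = "q1"), "b")
  m <- tibble::tibble(protein_id = "p1", n_ldw = 1L)
  m2 <- tibble::tibble(protein_id = "q1", n_ldw = 1L)
  expect_warning(res <- compare_classes(m, m2, a, b, criterion = "ldw"),
                 "no shared")
  expect_equal(nrow(res), 0L)
})
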