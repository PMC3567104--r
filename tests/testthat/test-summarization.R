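# builds a diamond DAG with hand-set annotation counts:
# root (8 proteins), b (4, p = 0.5), c (5, p = 0.625), d (2, p = 0.25,
# child of b and c). Hand-evaluated SimRel: sim(b,d) = 1/3,
# sim(c,d) ~ 0.19, sim(b,c) = 0 (root-only common ancestor).
diamond_ic_fixture <- function() {
  dag <- parse_obo(diamond_obo())
  prots <- paste0("p", 1:8)
  ann <- ann_from_list(list(
    "GO:0000001" = prots,
    "GO:0000002" = prots[1:4],
    "GO:0000003" = prots[3:7],
    "GO:0000004" = prots[3:4]), "x")
  list(dag = dag, ann = ann, ic = information_content(ann, dag))
}

test_that("information content follows annotation frequency", {
  fx <- diamond_ic_fixture()
  ic <- fx$ic
  expect_equal(ic$p[ic$term_id == "GO:0000001"], 1)
  expect_equal(ic$ic[ic$term_id == "GO:0000001"], 0)
  expect_equal(ic$p[ic$term_id == "GO:0000002"], 0.5)
  expect_equal(ic$ic[ic$term_id == "GO:0000004"], -log(0.25))
})

test_that("child probability never exceeds parent probability", {
  set.seed(141)
  for (i in 1:10) {
    spec <- random_obo(sample(8:40, 1))
    dag <- parse_obo(spec$path)
    prots <- paste0("p", 1:30)
    raw <- annotation_set(
      setNames(lapply(prots, function(p)
        sample(spec$ids, sample(1:3, 1))), prots), "x")
    ann <- expand_annotations(dag, raw)
    ic <- suppressWarnings(information_content(ann, dag))
    pv <- setNames(ic$p, ic$term_id)
    for (id in ic$term_id) {
      for (par in dag$parents[[id]]) {
        if (par %in% names(pv)) expect_lte(pv[[id]], pv[[par]] + 1e-12)
      }
    }
  }
})

test_that("simrel identity, root and diamond cases evaluate correctly", {
  fx <- diamond_ic_fixture()
  # identity: sim(t,t) = 1 - p(t)
  expect_equal(simrel(fx$dag, fx$ic, "GO:0000004", "GO:0000004"),
               1 - 0.25, tolerance = 1e-12)
  # against the root: IC(root) = 0 forces similarity 0
  expect_equal(simrel(fx$dag, fx$ic, "GO:0000002", "GO:0000001"), 0)
  # siblings b and c: only common ancestor is the root
  expect_equal(simrel(fx$dag, fx$ic, "GO:0000002", "GO:0000003"), 0)
  # b vs d: the max-IC common ancestor is b itself (hand evaluation)
  icb <- -log(0.5); icd <- -log(0.25)
  expect_equal(simrel(fx$dag, fx$ic, "GO:0000002", "GO:0000004"),
               (2 * icb / (icb + icd)) * (1 - 0.5), tolerance = 1e-12)
})

test_that("simrel is symmetric and bounded on random DAGs", {
  set.seed(151)
  for (i in 1:5) {
    spec <- random_obo(sample(10:30, 1))
    dag <- parse_obo(spec$path)
    prots <- paste0("p", 1:25)
    raw <- annotation_set(
      setNames(lapply(prots, function(p)
        sample(spec$ids, sample(1:3, 1))), prots), "x")
    ann <- expand_annotations(dag, raw)
    ic <- suppressWarnings(information_content(ann, dag))
    ids <- sample(ic$term_id, min(8, nrow(ic)))
    for (t1 in ids) for (t2 in ids) {
      s12 <- simrel(dag, ic, t1, t2)
      expect_gte(s12, 0); expect_lte(s12, 1)
      expect_equal(s12, simrel(dag, ic, t2, t1), tolerance = 1e-12)
    }
  }
})

test_that("summarize_terms clusters similar terms and scores uniqueness", {
  fx <- diamond_ic_fixture()
  # threshold 0.3 sits between sim(b,d) = 1/3 and sim(c,d) ~ 0.19
  res <- summarize_terms(
    tibble::tibble(term_id = c("GO:0000002", "GO:0000003", "GO:0000004"),
                   p_value = c(0.01, 0.02, 0.001)),
    fx$dag, fx$ic, threshold = 0.3)
  expect_equal(length(unique(res$cluster)), 2L)
  bd <- res[res$term_id %in% c("GO:0000002", "GO:0000004"), ]
  expect_equal(unique(bd$cluster), bd$cluster[1])
  # representative of the b/d cluster is the lower-p member, d
  expect_equal(unique(bd$representative), "GO:0000004")
  # clusters partition the input
  expect_setequal(res$term_id,
                  c("GO:0000002", "GO:0000003", "GO:0000004"))

  # two-term list with known similarity: uniqueness = 1 - sim
  s_bd <- simrel(fx$dag, fx$ic, "GO:0000002", "GO:0000004")
  res2 <- summarize_terms(c("GO:0000002", "GO:0000004"), fx$dag, fx$ic,
                          threshold = 0.5)
  expect_equal(res2$uniqueness, rep(1 - s_bd, 2), tolerance = 1e-12)
})

test_that("below-threshold lists stay as singletons", {
  fx <- diamond_ic_fixture()
  res <- summarize_terms(c("GO:0000002", "GO:0000003"), fx$dag, fx$ic,
                         threshold = 0.7)
  expect_equal(length(unique(res$cluster)), 2L)
  expect_equal(nrow(summarize_terms(character(), fx$dag, fx$ic)), 0L)
})

test_that("raising the threshold never decreases the cluster count", {
  set.seed(161)
  for (i in 1:5) {
    spec <- random_obo(20)
    dag <- parse_obo(spec$path)
    prots <- paste0("p", 1:25)
    raw <- annotation_set(
      setNames(lapply(prots, function(p)
        sample(spec$ids, sample(1:3, 1))), prots), "x")
    ann <- expand_annotations(dag, raw)
    ic <- suppressWarnings(information_content(ann, dag))
    ids <- sample(ic$term_id, min(10, nrow(ic)))
    terms <- tibble::tibble(term_id = ids,
                            p_value = runif(length(ids)))
    counts <- vapply(c(0.2, 0.5, 0.8), function(th)
      length(unique(summarize_terms(terms, dag, ic,
                                    threshold = th)$cluster)),
      numeric(1))
    expect_true(!is.unsorted(counts))
  }
})

test_that("summarization output is deterministic", {
  fx <- diamond_ic_fixture()
  terms <- tibble::tibble(
    term_id = c("GO:0000002", "GO:0000003", "GO:0000004"),
    p_value = c(0.01, 0.01, 0.01))
  r1 <- summarize_terms(terms, fx$dag, fx$ic, threshold = 0.4)
  r2 <- summarize_terms(terms, fx$dag, fx$ic, threshold = 0.4)
  expect_identical(r1, r2)
})
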