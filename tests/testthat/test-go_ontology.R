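test_that("parse_obo builds chains, flags obsolete terms, rejects cycles", {
  dag <- parse_obo(chain_obo())
  expect_equal(nrow(dag$terms), 3L)
  expect_equal(sum(lengths(dag$parents)), 2L)

  obs <- write_tmp(c("format-version: 1.2",
                     "", "[Term]", "id: GO:0000001", "name: a",
                     "namespace: biological_process",
                     "", "[Term]", "id: GO:0000002", "name: old",
                     "namespace: biological_process",
                     "is_a: GO:0000001", "is_obsolete: true"), ".obo")
  d2 <- parse_obo(obs)
  expect_true(d2$terms$obsolete[d2$terms$term_id == "GO:0000002"])

  cyc <- write_tmp(c("format-version: 1.2",
                     "", "[Term]", "id: GO:0000001", "name: a",
                     "namespace: biological_process", "is_a: GO:0000002",
                     "", "[Term]", "id: GO:0000002", "name: b",
                     "namespace: biological_process",
                     "is_a: GO:0000001"), ".obo")
  expect_error(parse_obo(cyc), "cyclic")

  dangle <- write_tmp(c("format-version: 1.2",
                        "", "[Term]", "id: GO:0000001", "name: a",
                        "namespace: biological_process",
                        "is_a: GO:0000099"), ".obo")
  expect_error(parse_obo(dangle), "dangling")
})

test_that("ancestors walks chains and diamonds, excluding self", {
  chain <- parse_obo(chain_obo())
  expect_equal(ancestors(chain, "GO:0000001"), character())
  expect_setequal(ancestors(chain, "GO:0000003"),
                  c("GO:0000002", "GO:0000001"))
  diamond <- parse_obo(diamond_obo())
  expect_setequal(ancestors(diamond, "GO:0000004"),
                  c("GO:0000002", "GO:0000003", "GO:0000001"))
  expect_error(ancestors(chain, "GO:9999999"), "unknown")
})

test_that("ancestors agrees with brute-force reachability on random DAGs", {
  set.seed(13)
  for (i in 1:40) {
    spec <- random_obo(sample(5:100, 1))
    dag <- parse_obo(spec$path)
    for (id in sample(spec$ids, min(10, length(spec$ids)))) {
      expect_setequal(ancestors(dag, id),
                      oracle_reachable(spec$parents, id))
    }
  }
})

test_that("expand_annotations closes under ancestors and drops obsolete", {
  dag <- parse_obo(chain_obo())
  raw <- annotation_set(list(p1 = "GO:0000003"), "x")
  exp <- expand_annotations(dag, raw)
  expect_setequal(exp$protein2term$p1,
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_true(exp$expanded)

  obs <- write_tmp(c("format-version: 1.2",
                     "", "[Term]", "id: GO:0000001", "name: a",
                     "namespace: biological_process",
                     "", "[Term]", "id: GO:0000002", "name: old",
                     "namespace: biological_process",
                     "is_a: GO:0000001", "is_obsolete: true"), ".obo")
  d2 <- parse_obo(obs)
  e2 <- expand_annotations(d2, annotation_set(list(p1 = "GO:0000002"),
                                              "x"))
  expect_null(e2$protein2term$p1)

  diamond <- parse_obo(diamond_obo())
  e3 <- expand_annotations(diamond,
                           annotation_set(list(p1 = "GO:0000002",
                                               p2 = "GO:0000003"), "x"))
  expect_setequal(e3$term2protein[["GO:0000001"]], c("p1", "p2"))
})

test_that("expansion is idempotent, monotone, and grows the term set", {
  set.seed(3)
  for (i in 1:10) {
    spec <- random_obo(sample(10:60, 1))
    dag <- parse_obo(spec$path)
    prots <- paste0("p", 1:15)
    raw <- annotation_set(
      setNames(lapply(prots, function(p)
        sample(spec$ids, sample(1:4, 1))), prots), "x")
    e1 <- expand_annotations(dag, raw)
    e2 <- expand_annotations(dag, e1)
    expect_identical(e1$protein2term, e2$protein2term)
    for (p in names(raw$protein2term)) {
      expect_true(all(raw$protein2term[[p]] %in% e1$protein2term[[p]]))
    }
    expect_gte(length(e1$term2protein), length(raw$term2protein))
  }
})

test_that("unknown annotation terms warn-and-drop by default", {
  dag <- parse_obo(chain_obo())
  raw <- annotation_set(list(p1 = c("GO:0000003", "GO:7777777")), "x")
  expect_warning(e <- expand_annotations(dag, raw), "unknown")
  expect_setequal(e$protein2term$p1,
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  expect_error(expand_annotations(dag, raw, on_unknown = "error"),
               "unknown")
})

test_that("shared_terms intersects annotated term sets", {
  dag <- parse_obo(diamond_obo())
  a <- expand_annotations(dag, annotation_set(list(p1 = "GO:0000002"),
                                              "a"))
  b <- expand_annotations(dag, annotation_set(list(q1 = "GO:0000003"),
                                              "b"))
  expect_setequal(shared_terms(a, b), "GO:0000001")
  expect_setequal(shared_terms(a, a), names(a$term2protein))
  expect_error(shared_terms(a, annotation_set(list(q1 = "GO:0000003"),
                                              "b")),
               "expanded")
})

test_that("GAF input drops NOT rows and uses columns 2 and 5", {
  gaf <- write_tmp(c("!gaf-version: 2.1",
                     paste("DB", "P1", "SYM", "", "GO:0000003", "REF",
                           "IEA", "", "P", sep = "\t"),
                     paste("DB", "P2", "SYM", "NOT", "GO:0000003",
                           "REF", "IEA", "", "P", sep = "\t")), ".gaf")
  ann <- read_annotations(gaf, "x", format = "gaf")
  expect_equal(names(ann$protein2term), "P1")
  expect_equal(ann$protein2term$P1, "GO:0000003")
})
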