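#' Configuration for a synthetic comparative-disorder study
#'
#' Defines the generating conditions for [generate_study()]: two organisms
#' of `n_proteins` proteins each, a random GO-like DAG, leaf-class
#' annotations, and a two-state (ordered/disordered) segmental score
#' model. A subset of leaf classes is "planted": their member proteins are
#' disordered with probability `planted_rate_a` in organism A and
#' `planted_rate_b` in organism B, while all other proteins are disordered
#' with `baseline_rate` in both organisms. Disorder status is imposed at
#' the whole-protein level and realized in the score tracks so that the
#' three binary criteria (>= 50% disordered residues, >= 1 long disordered
#' window, >= 1 disordered binding region) agree: a "disordered" protein
#' receives 55-85% disordered residues including one run of >= 40 and one
#' binding region, an "ordered" one 5-35% in runs of < 30 and no binding
#' region.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Proteins per organism; default 400.
#' @param len_range Protein length range (residues); default 100-400.
#' @param baseline_rate Disordered-protein probability outside planted
#'   classes; default 0.3.
#' @param planted_rate_a,planted_rate_b Disordered-protein probability
#'   for planted-class members in organisms A and B; defaults 0.6 / 0.2.
#' @param n_terms Terms in the DAG (including the root); default 40.
#' @param max_parents Maximum parents per term; default 2.
#' @param n_planted Number of planted leaf classes; default 3.
#' @param class_frac Fraction of the proteome annotated to each leaf
#'   class; default 0.5 (200 proteins per class at the default size).
#' @param ortholog_fraction Fraction of proteins paired across organisms;
#'   default 0.5.
#' @param score_means,score_sd Mean score of the disordered and ordered
#'   states (`c(disordered, ordered)`) and their spread; scores are
#'   truncated to \[0.55, 0.99\] / \[0.01, 0.45\] so that binarization at
#'   0.5 recovers the generating state exactly.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_proteins = 400L,
                             len_range = c(100L, 400L),
                             baseline_rate = 0.3,
                             planted_rate_a = 0.6,
                             planted_rate_b = 0.2,
                             n_terms = 40L,
                             max_parents = 2L,
                             n_planted = 3L,
                             class_frac = 0.5,
                             ortholog_fraction = 0.5,
                             score_means = c(0.8, 0.2),
                             score_sd = 0.06) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              len_range = as.integer(len_range),
              baseline_rate = baseline_rate,
              planted_rate_a = planted_rate_a,
              planted_rate_b = planted_rate_b,
              n_terms = as.integer(n_terms),
              max_parents = as.integer(max_parents),
              n_planted = as.integer(n_planted),
              class_frac = class_frac,
              ortholog_fraction = ortholog_fraction,
              score_means = score_means, score_sd = score_sd)
  probs <- c(cfg$baseline_rate, cfg$planted_rate_a, cfg$planted_rate_b,
             cfg$class_frac, cfg$ortholog_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_proteins < 2L) stop("need at least 2 proteins per organism")
  if (cfg$len_range[1] < 100L) stop("minimum protein length is 100")
  if (cfg$n_terms < 3L) stop("need at least 3 terms")
  if (round(cfg$class_frac * cfg$n_proteins) < 1L && cfg$n_planted > 0L)
    stop("planted classes would be empty at this class_frac / n_proteins")
  structure(cfg, class = "synthetic_config")
}

# residue composition by state; disordered segments are enriched in the
# disorder-promoting residues P, E, S, K, Q
disorder_comp <- c(P = .12, E = .14, S = .13, K = .12, Q = .10, G = .09,
                   A = .08, R = .07, D = .06, T = .05, N = .04,
                   L = .01, I = .01, V = .01, F = .01, M = .01, H = .02,
                   W = .01, Y = .01, C = .01)
order_comp <- c(L = .12, I = .10, V = .11, F = .07, A = .10, G = .08,
                M = .04, W = .03, Y = .05, C = .03, T = .06, S = .05,
                H = .03, N = .03, D = .03, E = .02, K = .02, Q = .01,
                R = .01, P = .01)

rtrunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# split `total` residues into run lengths bounded by `max_run`
split_runs <- function(total, min_run, max_run) {
  runs <- integer()
  while (total > 0) {
    r <- min(total, sample(seq(min_run, max_run), 1L))
    # avoid a trailing stub shorter than min_run
    if (total - r > 0 && total - r < min_run) r <- total
    runs <- c(runs, r)
    total <- total - r
  }
  runs
}

# lay out disordered runs with >= 1 ordered residue between them;
# returns a logical mask of length L
lay_out_mask <- function(L, runs) {
  k <- length(runs)
  ordered_total <- L - sum(runs)
  stopifnot(ordered_total >= k - 1L)
  gaps <- rep(0L, k + 1L)
  if (k > 1L) gaps[2:k] <- 1L
  spare <- ordered_total - sum(gaps)
  if (spare > 0) {
    add <- tabulate(sample.int(k + 1L, spare, replace = TRUE), k + 1L)
    gaps <- gaps + add
  }
  mask <- logical(0)
  for (i in seq_len(k)) {
    mask <- c(mask, rep(FALSE, gaps[i]), rep(TRUE, runs[i]))
  }
  c(mask, rep(FALSE, gaps[k + 1L]))
}

# build one protein's state mask, DBR mask, score tracks and sequence
make_protein <- function(disordered, cfg) {
  L <- sample(seq(cfg$len_range[1], cfg$len_range[2]), 1L)
  if (disordered) {
    D <- round(L * stats::runif(1, 0.55, 0.85))
    first <- max(40L, ceiling(D * 0.5))
    rest <- split_runs(D - first, 5L, 25L)
    runs <- c(first, rest)
  } else {
    D <- round(L * stats::runif(1, 0.05, 0.35))
    runs <- split_runs(D, 3L, 25L)
  }
  mask <- lay_out_mask(L, runs)
  scores <- numeric(L)
  nd <- sum(mask)
  scores[mask] <- rtrunc(nd, cfg$score_means[1], cfg$score_sd, 0.55, 0.99)
  scores[!mask] <- rtrunc(L - nd, cfg$score_means[2], cfg$score_sd,
                          0.01, 0.45)
  dbr_mask <- logical(L)
  if (disordered) {
    first_start <- which(mask)[1]
    blen <- sample(8:20, 1L)
    dbr_mask[first_start:(first_start + blen - 1L)] <- TRUE
  }
  dbr_scores <- numeric(L)
  dbr_scores[dbr_mask] <- rtrunc(sum(dbr_mask), 0.8, 0.06, 0.55, 0.99)
  dbr_scores[!dbr_mask] <- rtrunc(sum(!dbr_mask), 0.15, 0.06, 0.01, 0.45)
  seq <- character(L)
  seq[mask] <- sample(names(disorder_comp), sum(mask), replace = TRUE,
                      prob = disorder_comp)
  seq[!mask] <- sample(names(order_comp), sum(!mask), replace = TRUE,
                       prob = order_comp)
  list(sequence = paste(seq, collapse = ""), scores = scores,
       dbr_scores = dbr_scores)
}

# random rooted DAG: term 1 is the root, every later term picks 1..max_parents
# parents among earlier terms
make_dag <- function(n_terms, max_parents) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1]] <- character()
  for (i in seq_len(n_terms)[-1]) {
    np <- sample(seq_len(min(max_parents, i - 1L)), 1L)
    parents[[i]] <- sample(ids[seq_len(i - 1L)], np)
  }
  tt <- tibble::tibble(term_id = ids,
                       name = paste0("synthetic process ", seq_len(n_terms)),
                       namespace = "biological_process",
                       obsolete = FALSE)
  dag <- structure(list(terms = tt, parents = parents, relations = "is_a"),
                   class = "go_dag")
  dag$closure <- ancestor_closure(dag)
  dag
}

generate_organism <- function(cfg, prefix, leaf_terms, planted,
                              planted_rate) {
  n <- cfg$n_proteins
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  class_size <- round(cfg$class_frac * n)
  members <- lapply(leaf_terms, function(t) sample(ids, class_size))
  names(members) <- leaf_terms
  in_planted <- unique(unlist(members[planted], use.names = FALSE))
  status <- stats::rbinom(n, 1L, cfg$baseline_rate) == 1L
  names(status) <- ids
  if (length(in_planted))
    status[in_planted] <- stats::rbinom(length(in_planted), 1L,
                                        planted_rate) == 1L
  prot <- lapply(status, function(d) make_protein(d, cfg))
  p2t <- invert_map(members)
  list(
    proteome = new_proteome(
      tibble::tibble(protein_id = ids,
                     sequence = unname(vapply(prot, `[[`, character(1),
                                              "sequence"))),
      organism = prefix, filtered = TRUE),
    profiles = lapply(prot, `[[`, "scores"),
    dbr_profiles = lapply(prot, `[[`, "dbr_scores"),
    annotations = annotation_set(p2t, organism = prefix,
                                 expanded = FALSE),
    status = status
  )
}

#' Generate a seeded synthetic comparative-disorder study
#'
#' Produces all the inputs of the comparative pipeline — two proteomes,
#' per-residue disorder and binding score tracks, a GO-like DAG, leaf
#' annotations for both organisms, an ortholog map — plus the truth table
#' of planted term ids. Identical seeds reproduce identical studies.
#'
#' @param cfg A `synthetic_config`.
#' @return A `synthetic_study`: list with `proteome_a`, `proteome_b`,
#'   `profiles_a`, `profiles_b`, `dbr_profiles_a`, `dbr_profiles_b`,
#'   `dag`, `annotations_a`, `annotations_b` (unexpanded), `orthologs`,
#'   `truth` (tibble of planted `term_id`, `rate_a`, `rate_b`) and `cfg`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr_seed(cfg$seed)
  dag <- make_dag(cfg$n_terms, cfg$max_parents)
  has_child <- unique(unlist(dag$parents, use.names = FALSE))
  leaves <- setdiff(dag$terms$term_id, c(has_child, dag$terms$term_id[1]))
  if (cfg$n_planted > length(leaves))
    stop("n_planted (", cfg$n_planted, ") exceeds the ", length(leaves),
         " leaf terms of the generated DAG")
  planted <- sort(sample(leaves, cfg$n_planted))
  org_a <- generate_organism(cfg, "ATH", leaves, planted,
                             cfg$planted_rate_a)
  org_b <- generate_organism(cfg, "HSA", leaves, planted,
                             cfg$planted_rate_b)
  n_pairs <- round(cfg$ortholog_fraction * cfg$n_proteins)
  idx <- sort(sample(cfg$n_proteins, n_pairs))
  orthologs <- tibble::tibble(
    id_a = org_a$proteome$protein_id[idx],
    id_b = org_b$proteome$protein_id[idx],
    group = paste0("OG", seq_along(idx)),
    score = 1
  )
  structure(list(
    proteome_a = org_a$proteome, proteome_b = org_b$proteome,
    profiles_a = org_a$profiles, profiles_b = org_b$profiles,
    dbr_profiles_a = org_a$dbr_profiles,
    dbr_profiles_b = org_b$dbr_profiles,
    dag = dag,
    annotations_a = org_a$annotations,
    annotations_b = org_b$annotations,
    orthologs = orthologs,
    status_a = org_a$status, status_b = org_b$status,
    truth = tibble::tibble(term_id = planted,
                           rate_a = rep(cfg$planted_rate_a,
                                        length(planted)),
                           rate_b = rep(cfg$planted_rate_b,
                                        length(planted))),
    cfg = cfg
  ), class = "synthetic_study")
}

#' Generate a null synthetic study
#'
#' As [generate_study()] but with zero planted classes: both organisms
#' share one generating distribution and the truth table is empty.
#'
#' @param cfg A `synthetic_config`; its `n_planted` is forced to 0.
#' @return A `synthetic_study` with an empty truth table.
#' @export
generate_null_study <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg$n_planted <- 0L
  generate_study(cfg)
}

# local seed that does not disturb the caller's RNG stream
withr_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Write a synthetic study to plain-text files
#'
#' Serializes a study to the on-disk formats the pipeline reads: FASTA
#' proteomes, horizontal score TSVs (disorder and binding), an OBO
#' ontology, 2-column annotation TSVs, an ortholog TSV and a truth-table
#' JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fasta_a = file.path(dir, "proteome_a.fasta"),
    fasta_b = file.path(dir, "proteome_b.fasta"),
    scores_a = file.path(dir, "scores_a.tsv"),
    scores_b = file.path(dir, "scores_b.tsv"),
    dbr_a = file.path(dir, "dbr_scores_a.tsv"),
    dbr_b = file.path(dir, "dbr_scores_b.tsv"),
    obo = file.path(dir, "ontology.obo"),
    annotations_a = file.path(dir, "annotations_a.tsv"),
    annotations_b = file.path(dir, "annotations_b.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(study$proteome_a, paths$fasta_a)
  write_fasta(study$proteome_b, paths$fasta_b)
  write_scores_horizontal(study$profiles_a, paths$scores_a)
  write_scores_horizontal(study$profiles_b, paths$scores_b)
  write_scores_horizontal(study$dbr_profiles_a, paths$dbr_a)
  write_scores_horizontal(study$dbr_profiles_b, paths$dbr_b)
  write_obo(study$dag, paths$obo)
  write_annotation_tsv(study$annotations_a, paths$annotations_a)
  write_annotation_tsv(study$annotations_b, paths$annotations_b)
  utils::write.table(study$orthologs, paths$orthologs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted = study$truth,
                            seed = study$cfg$seed),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_scores_horizontal <- function(profiles, path) {
  lines <- vapply(names(profiles), function(id) {
    paste(c(id, formatC(profiles[[id]], digits = 6, format = "f")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_annotation_tsv <- function(annotations, path) {
  p2t <- annotations$protein2term
  prot <- rep(names(p2t), lengths(p2t))
  term <- unlist(p2t, use.names = FALSE)
  writeLines(paste(prot, term, sep = "\t"), path)
  invisible(path)
}
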