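#' Run the full comparative-disorder study
#'
#' Orchestrates the end-to-end analysis for two organisms from a single
#' configuration: reads and filters the proteomes, loads (or predicts)
#' per-residue disorder and binding score tracks, computes per-protein
#' metrics, expands GO annotations, and emits the report bundle:
#' \describe{
#'   \item{`summary_<org>.tsv`}{proteome-level disorder summary per
#'     organism (mean disorder content, % proteins with >= 1 LDW, mean
#'     LDW count, mean % residues in LDWs, % proteins with >= 1 DBR, mean
#'     DBR count, mean % DBR residues).}
#'   \item{`metrics_<org>.tsv`}{per-protein metrics tables.}
#'   \item{`bins_<org>.tsv`}{binned disorder-content distributions.}
#'   \item{`enrichment_a.tsv`}{GO terms enriched in organism A's
#'     disordered-protein set (filtered).}
#'   \item{`comparison.tsv`}{cross-organism per-class comparison
#'     (filtered to significant classes in `comparison_significant.tsv`).}
#'   \item{`term_categories.tsv`}{three-way categorization of terms:
#'     enrichment-only, comparison-only, both.}
#'   \item{`clusters.tsv`}{semantic summarization of the significant
#'     comparison terms.}
#'   \item{`ortholog_report.json` + `ortholog_classes.tsv`}{ortholog
#'     validation (only when an ortholog table is configured).}
#'   \item{`run_log.json`}{machine-readable log of package version,
#'     parameters, seed and input checksums.}
#' }
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `fasta_a`, `fasta_b`, `scores_a`, `scores_b` (optional; when absent
#'   the built-in predictor is used), `dbr_a`, `dbr_b` (optional),
#'   `obo`, `annotations_a`, `annotations_b`, `orthologs` (optional),
#'   `out_dir`, and parameters `threshold` (default 0.5), `dbr_threshold`
#'   (0.5), `ldw_min` (30), `disordered_protein_cutoff` (50),
#'   `dbr_min_len` (6), `criterion` ("ldw"), `alpha` (0.05), `min_excess`
#'   (0.05), `min_count` (2), `enrichment_method` ("ease"),
#'   `cluster_threshold` (0.7), `supercluster_threshold` (0.5),
#'   `score_dialect` ("horizontal"), `annotation_format` ("tsv"),
#'   `seed` (1).
#' @return Invisibly, a list with the in-memory report objects and the
#'   written paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)
  required <- c("fasta_a", "fasta_b", "obo", "annotations_a",
                "annotations_b", "out_dir")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("config error: missing entries ", paste(miss, collapse = ", "))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  withr_seed(cfg$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- sequences ------------------------------------------------------
  org <- list(a = list(), b = list())
  for (side in c("a", "b")) {
    fa <- stage(paste0("read_fasta_", side),
                read_fasta(cfg[[paste0("fasta_", side)]]))
    fl <- stage(paste0("filter_", side), filter_proteome(fa))
    org[[side]]$proteome <- fl$proteome
    org[[side]]$filter_report <- fl$report
  }

  # -- score tracks ---------------------------------------------------
  for (side in c("a", "b")) {
    key <- paste0("scores_", side)
    prot <- org[[side]]$proteome
    if (!is.null(cfg[[key]])) {
      prof <- stage(paste0("parse_scores_", side),
                    parse_scores(cfg[[key]], dialect = cfg$score_dialect))
      prof <- prof[intersect(names(prof), prot$protein_id)]
    } else {
      prof <- stage(paste0("builtin_predictor_", side), {
        p <- lapply(prot$sequence, builtin_predictor)
        names(p) <- prot$protein_id
        p
      })
    }
    org[[side]]$profiles <- prof
    dkey <- paste0("dbr_", side)
    org[[side]]$dbr_profiles <- if (!is.null(cfg[[dkey]]))
      stage(paste0("parse_dbr_", side),
            parse_scores(cfg[[dkey]], dialect = cfg$score_dialect))
    else NULL
  }

  # -- per-protein metrics and summaries ------------------------------
  for (side in c("a", "b")) {
    org[[side]]$metrics <- stage(
      paste0("metrics_", side),
      metrics_table(org[[side]]$profiles, org[[side]]$dbr_profiles,
                    threshold = cfg$threshold,
                    dbr_threshold = cfg$dbr_threshold,
                    ldw_min = cfg$ldw_min,
                    disordered_protein_cutoff =
                      cfg$disordered_protein_cutoff,
                    dbr_min_len = cfg$dbr_min_len))
    org[[side]]$summary <- proteome_summary(org[[side]]$metrics)
    org[[side]]$bins <- bin_fractions(org[[side]]$metrics,
                                      "pct_disordered")
  }

  # -- ontology and annotations ---------------------------------------
  dag <- stage("parse_obo", parse_obo(cfg$obo))
  ann <- list()
  for (side in c("a", "b")) {
    raw <- stage(paste0("read_annotations_", side),
                 read_annotations(cfg[[paste0("annotations_", side)]],
                                  organism = side,
                                  format = cfg$annotation_format))
    ann[[side]] <- stage(paste0("expand_annotations_", side),
                         expand_annotations(dag, raw))
  }

  # -- single-organism enrichment (organism A) ------------------------
  flags_a <- criterion_flags(org$a$metrics, cfg$criterion)
  study_set <- names(flags_a)[flags_a]
  enr <- stage("term_enrichment",
               term_enrichment(study_set, org$a$metrics$protein_id,
                               ann$a, method = cfg$enrichment_method))
  enr_kept <- filter_enrichment(enr, alpha = cfg$alpha,
                                min_count = cfg$min_count)

  # -- cross-organism class comparison --------------------------------
  cmp <- stage("compare_classes",
               compare_classes(org$a$metrics, org$b$metrics,
                               ann$a, ann$b, criterion = cfg$criterion,
                               alpha = cfg$alpha,
                               min_excess = cfg$min_excess))
  cmp_sig <- cmp[cmp$significant, , drop = FALSE]

  # -- three-way term categorization ----------------------------------
  cats <- term_categories(enr_kept$term_id, cmp_sig$term_id)

  # -- semantic summarization of the comparison list ------------------
  ic <- stage("information_content",
              suppressWarnings(information_content(ann$a, dag)))
  clu_input <- tibble::tibble(term_id = cmp_sig$term_id,
                              p_value = cmp_sig$p_adj)
  clu_input <- clu_input[clu_input$term_id %in% ic$term_id, ]
  clusters <- stage("summarize_terms",
                    summarize_terms(clu_input, dag, ic,
                                    threshold = cfg$cluster_threshold,
                                    supercluster_threshold =
                                      cfg$supercluster_threshold))

  # -- ortholog validation (optional) ---------------------------------
  ortho <- NULL
  if (!is.null(cfg$orthologs)) {
    pairs <- stage("read_orthologs", read_orthologs(cfg$orthologs))
    sums <- dplyr::bind_rows(lapply(cmp_sig$term_id, function(t)
      class_ortholog_summary(t, pairs, org$a$metrics, org$b$metrics,
                             ann$a, ann$b)))
    if (nrow(sums) == 0L)
      sums <- tibble::tibble(term_id = character(), n_pairs = integer(),
                             mean_disorder_a = numeric(),
                             mean_disorder_b = numeric(),
                             a_greater = logical())
    tests <- if (sum(sums$n_pairs > 0) >= 2)
      ortholog_t_tests(sums) else NULL
    ortho <- list(classes = sums, tests = tests)
  }

  # -- write the bundle -----------------------------------------------
  paths <- list()
  for (side in c("a", "b")) {
    paths[[paste0("summary_", side)]] <-
      write_tsv(org[[side]]$summary, file.path(out, paste0("summary_",
                                                           side, ".tsv")))
    paths[[paste0("metrics_", side)]] <-
      write_tsv(org[[side]]$metrics, file.path(out, paste0("metrics_",
                                                           side, ".tsv")))
    paths[[paste0("bins_", side)]] <-
      write_tsv(org[[side]]$bins, file.path(out, paste0("bins_", side,
                                                        ".tsv")))
    filter_report_json(org[[side]]$filter_report,
                       file.path(out, paste0("filter_report_", side,
                                             ".json")))
  }
  paths$enrichment <- write_tsv(enr_kept,
                                file.path(out, "enrichment_a.tsv"))
  paths$comparison <- write_tsv(cmp, file.path(out, "comparison.tsv"))
  paths$comparison_significant <-
    write_tsv(cmp_sig, file.path(out, "comparison_significant.tsv"))
  paths$term_categories <- write_tsv(cats,
                                     file.path(out, "term_categories.tsv"))
  paths$clusters <- write_tsv(clusters, file.path(out, "clusters.tsv"))
  if (!is.null(ortho)) {
    paths$ortholog_classes <-
      write_tsv(ortho$classes, file.path(out, "ortholog_classes.tsv"))
    jsonlite::write_json(ortho$tests,
                         file.path(out, "ortholog_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    paths$ortholog_report <- file.path(out, "ortholog_report.json")
  }
  log <- list(
    package = "idpcompare",
    version = as.character(utils::packageVersion("idpcompare")),
    parameters = cfg[setdiff(names(cfg),
                             c("fasta_a", "fasta_b", "scores_a",
                               "scores_b", "dbr_a", "dbr_b", "obo",
                               "annotations_a", "annotations_b",
                               "orthologs", "out_dir"))],
    inputs = input_checksums(cfg)
  )
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$run_log <- file.path(out, "run_log.json")

  invisible(list(summary_a = org$a$summary, summary_b = org$b$summary,
                 metrics_a = org$a$metrics, metrics_b = org$b$metrics,
                 enrichment = enr_kept, comparison = cmp,
                 comparison_significant = cmp_sig,
                 term_categories = cats, clusters = clusters,
                 ortholog = ortho, paths = paths))
}

pipeline_defaults <- function(config) {
  defaults <- list(threshold = 0.5, dbr_threshold = 0.5, ldw_min = 30L,
                   disordered_protein_cutoff = 50, dbr_min_len = 6L,
                   criterion = "ldw", alpha = 0.05, min_excess = 0.05,
                   min_count = 2L, enrichment_method = "ease",
                   cluster_threshold = 0.7, supercluster_threshold = 0.5,
                   score_dialect = "horizontal",
                   annotation_format = "tsv", seed = 1L)
  utils::modifyList(defaults, config)
}

#' Proteome-level disorder summary
#'
#' Aggregates a per-protein metrics table into the headline
#' proteome-level figures: mean disorder content, the percentage of
#' proteins with at least one LDW, mean LDW count, mean percentage of
#' residues in LDWs, and the DBR analogues.
#'
#' @param metrics Metrics table from [metrics_table()].
#' @return One-row [tibble::tibble()].
#' @export
proteome_summary <- function(metrics) {
  has_dbr <- !all(is.na(metrics$n_dbr))
  tibble::tibble(
    n_proteins = nrow(metrics),
    mean_pct_disordered = mean(metrics$pct_disordered),
    pct_proteins_with_ldw = 100 * mean(metrics$n_ldw >= 1),
    mean_n_ldw = mean(metrics$n_ldw),
    mean_pct_in_ldw = mean(metrics$pct_in_ldw),
    pct_disordered_proteins = 100 * mean(metrics$is_disordered_protein),
    pct_proteins_with_dbr = if (has_dbr)
      100 * mean(metrics$n_dbr >= 1, na.rm = TRUE) else NA_real_,
    mean_n_dbr = if (has_dbr) mean(metrics$n_dbr, na.rm = TRUE)
    else NA_real_,
    mean_pct_dbr_residues = if (has_dbr)
      mean(metrics$pct_dbr_residues, na.rm = TRUE) else NA_real_
  )
}

#' Three-way categorization of GO term lists
#'
#' Partitions the union of the single-organism enrichment list and the
#' cross-organism comparison list into `enrichment_only` (enriched in
#' organism A but with similar disorder levels in B), `comparison_only`
#' (more disordered than in B without being especially enriched in A) and
#' `both`.
#'
#' @param enriched Term ids from the filtered enrichment.
#' @param comparative Term ids significant in the comparison.
#' @return A [tibble::tibble()] with columns `term_id`, `category`.
#' @export
term_categories <- function(enriched, comparative) {
  all_terms <- sort(union(enriched, comparative))
  cat <- ifelse(all_terms %in% enriched & all_terms %in% comparative,
                "both",
                ifelse(all_terms %in% enriched, "enrichment_only",
                       "comparison_only"))
  tibble::tibble(term_id = all_terms, category = cat)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

input_checksums <- function(cfg) {
  keys <- c("fasta_a", "fasta_b", "scores_a", "scores_b", "dbr_a",
            "dbr_b", "obo", "annotations_a", "annotations_b", "orthologs")
  sums <- list()
  for (k in keys) {
    if (!is.null(cfg[[k]]) && file.exists(cfg[[k]])) {
      sums[[k]] <- list(file = basename(cfg[[k]]),
                        size = file.size(cfg[[k]]),
                        crc = sum(as.integer(charToRaw(
                          paste(readLines(cfg[[k]], warn = FALSE),
                                collapse = "\n")))) %% 2147483647)
    }
  }
  sums
}
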