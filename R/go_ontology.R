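#' Parse a Gene Ontology OBO file
#'
#' Reads the OBO 1.2 subset needed for annotation propagation: `[Term]`
#' stanzas with `id`, `name`, `namespace`, `is_a`, `relationship: part_of`
#' and `is_obsolete` tags. Other stanzas and tags are ignored. Obsolete
#' terms are retained in the DAG but flagged. The graph over the selected
#' traversal relations must be acyclic and every referenced parent must be
#' defined; cross-namespace parent edges are rejected.
#'
#' @param path Path to an OBO file.
#' @param relations Relations used for traversal: subset of
#'   `c("is_a", "part_of")`. `is_a` is the uncontested subsumption
#'   relation and the default.
#' @return A `go_dag`: list with `terms` (tibble: `term_id`, `name`,
#'   `namespace`, `obsolete`), `parents` (named list of parent term-id
#'   vectors under the selected relations), `relations`, and a cached
#'   ancestor closure.
#' @export
parse_obo <- function(path, relations = "is_a") {
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  lines <- readLines(path)
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(is_a = character(), part_of = character(),
                  obsolete = FALSE, name = NA_character_,
                  namespace = NA_character_)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a" && nzchar(val))
      cur$is_a <- c(cur$is_a, strsplit(val, "\\s")[[1]][1])
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      p <- strsplit(val, "\\s+")[[1]]
      if (length(p) >= 2 && p[1] == "part_of")
        cur$part_of <- c(cur$part_of, p[2])
    }
  }
  terms <- flush(cur, terms)
  if (length(terms) == 0L) stop("no [Term] stanzas in ", path)
  ids <- names(terms)
  tt <- tibble::tibble(
    term_id = ids,
    name = vapply(terms, function(t) t$name, character(1)),
    namespace = vapply(terms, function(t) t$namespace, character(1)),
    obsolete = vapply(terms, function(t) t$obsolete, logical(1))
  )
  parents <- lapply(terms, function(t)
    unique(unlist(t[relations], use.names = FALSE)))
  names(parents) <- ids
  all_parents <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(all_parents, ids)
  if (length(dangling))
    stop("dangling parent term(s): ", paste(dangling, collapse = ", "))
  ns <- stats::setNames(tt$namespace, tt$term_id)
  for (id in ids) {
    cross <- parents[[id]][!is.na(ns[parents[[id]]]) & !is.na(ns[id]) &
                             ns[parents[[id]]] != ns[id]]
    if (length(cross))
      stop("cross-namespace parent edge: ", id, " -> ",
           paste(cross, collapse = ", "))
  }
  dag <- structure(list(terms = tt, parents = parents,
                        relations = relations),
                   class = "go_dag")
  g <- dag_igraph(dag)
  if (igraph::vcount(g) && !igraph::is_dag(g)) {
    cyc <- find_cycle(parents)
    stop("ontology graph is cyclic, e.g.: ", paste(cyc, collapse = " -> "))
  }
  dag$closure <- ancestor_closure(dag)
  dag
}

# child -> parent edge graph
dag_igraph <- function(dag) {
  e <- unlist(lapply(names(dag$parents), function(id) {
    ps <- dag$parents[[id]]
    if (length(ps)) rbind(id, ps) else NULL
  }))
  igraph::graph_from_data_frame(
    if (is.null(e)) data.frame(from = character(), to = character())
    else data.frame(from = e[c(TRUE, FALSE)], to = e[c(FALSE, TRUE)]),
    vertices = dag$terms$term_id)
}

find_cycle <- function(parents) {
  state <- new.env()
  for (id in names(parents)) assign(id, 0L, envir = state)
  path <- character()
  dfs <- function(id) {
    s <- get(id, envir = state)
    if (s == 1L) return(id)
    if (s == 2L) return(NULL)
    assign(id, 1L, envir = state)
    path <<- c(path, id)
    for (p in parents[[id]]) {
      hit <- dfs(p)
      if (!is.null(hit)) return(hit)
    }
    assign(id, 2L, envir = state)
    path <<- path[-length(path)]
    NULL
  }
  for (id in names(parents)) {
    hit <- dfs(id)
    if (!is.null(hit)) {
      i <- match(hit, path)
      return(c(path[i:length(path)], hit))
    }
  }
  character()
}

# ancestor sets for every term, by propagation in topological order
ancestor_closure <- function(dag) {
  ids <- dag$terms$term_id
  g <- dag_igraph(dag)
  ord <- names(igraph::topo_sort(g, mode = "in"))  # parents before children
  clo <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ord) {
    ps <- dag$parents[[id]]
    clo[[id]] <- unique(c(ps, unlist(clo[ps], use.names = FALSE)))
  }
  clo
}

#' Ancestors of a GO term
#'
#' Transitive closure over the DAG's traversal relations, excluding the
#' term itself.
#'
#' @param dag A `go_dag` from [parse_obo()].
#' @param term_id Term identifier.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(dag, term_id) {
  if (!term_id %in% dag$terms$term_id)
    stop("unknown term: ", term_id)
  dag$closure[[term_id]] %||% character()
}

#' Construct an annotation set
#'
#' @param protein2term Named list: protein id -> character vector of term
#'   ids.
#' @param organism Organism label.
#' @param expanded Whether the sets are already closed under ancestors.
#' @return An `annotation_set` (list with `organism`, `protein2term`,
#'   `term2protein`, `expanded`).
#' @export
annotation_set <- function(protein2term, organism, expanded = FALSE) {
  protein2term <- lapply(protein2term, unique)
  structure(list(organism = organism,
                 protein2term = protein2term,
                 term2protein = invert_map(protein2term),
                 expanded = expanded),
            class = "annotation_set")
}

invert_map <- function(p2t) {
  if (length(p2t) == 0L) return(list())
  prot <- rep(names(p2t), lengths(p2t))
  term <- unlist(p2t, use.names = FALSE)
  lapply(split(prot, term), unique)
}

#' Read protein-to-term annotations
#'
#' Supports GAF 2.x (columns 2 and 5 used; rows whose qualifier contains
#' `NOT` are dropped; comment lines start with `!`) and plain 2-column
#' TSV (`protein_id`, `term_id`).
#'
#' @param path Annotation file path.
#' @param organism Organism label.
#' @param format `"tsv"` or `"gaf"`.
#' @return An unexpanded `annotation_set`.
#' @export
read_annotations <- function(path, organism, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    keep <- vapply(parts, function(p)
      length(p) >= 5 && !grepl("NOT", p[[4]]), logical(1))
    parts <- parts[keep]
    prot <- vapply(parts, `[[`, character(1), 2L)
    term <- vapply(parts, `[[`, character(1), 5L)
  } else {
    if (any(lengths(parts) < 2L)) stop("TSV annotation row with < 2 fields")
    prot <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  }
  annotation_set(split(term, prot), organism, expanded = FALSE)
}

#' Expand annotations to GO ancestors
#'
#' Drops annotations to obsolete terms, then closes each protein's term
#' set under the DAG's ancestor relation, so that any two proteins can be
#' compared at the most specific level they share.
#'
#' @param dag A `go_dag`.
#' @param annotations An unexpanded `annotation_set`.
#' @param on_unknown What to do with annotations to terms absent from the
#'   DAG: `"warn"` (drop with a warning, the default — release mismatches
#'   are common) or `"error"`.
#' @param namespace Optional namespace filter (e.g.
#'   `"biological_process"`); annotations outside it are dropped silently.
#' @return An expanded `annotation_set`.
#' @export
expand_annotations <- function(dag, annotations,
                               on_unknown = c("warn", "error"),
                               namespace = NULL) {
  on_unknown <- match.arg(on_unknown)
  if (isTRUE(annotations$expanded))
    return(annotations)
  known <- dag$terms$term_id
  obsolete <- dag$terms$term_id[dag$terms$obsolete]
  keep_ns <- if (is.null(namespace)) known else
    dag$terms$term_id[dag$terms$namespace %in% namespace]
  unknown <- setdiff(unique(unlist(annotations$protein2term,
                                   use.names = FALSE)), known)
  if (length(unknown)) {
    msg <- paste0("dropping annotations to ", length(unknown),
                  " unknown term(s): ",
                  paste(utils::head(unknown, 5), collapse = ", "))
    if (on_unknown == "error") stop(msg) else warning(msg)
  }
  p2t <- lapply(annotations$protein2term, function(ts) {
    ts <- setdiff(intersect(ts, keep_ns), obsolete)
    if (length(ts) == 0L) return(character())
    unique(c(ts, unlist(dag$closure[ts], use.names = FALSE)))
  })
  p2t <- p2t[lengths(p2t) > 0L]
  annotation_set(p2t, annotations$organism, expanded = TRUE)
}

#' Terms annotated in both organisms
#'
#' The comparative analysis is restricted to GO terms that annotate at
#' least one protein in each organism.
#'
#' @param a,b Expanded `annotation_set`s.
#' @return Character vector of shared term ids.
#' @export
shared_terms <- function(a, b) {
  if (!isTRUE(a$expanded) || !isTRUE(b$expanded))
    stop("shared_terms requires expanded annotation sets")
  intersect(names(a$term2protein), names(b$term2protein))
}

#' Write a go_dag back to OBO
#'
#' Emits the subset of OBO understood by [parse_obo()]; used by the
#' synthetic-study writer.
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$term_id[i]
    writeLines(c("", "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i])), con)
    for (p in dag$parents[[id]])
      writeLines(paste0("is_a: ", p), con)
    if (dag$terms$obsolete[i]) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}
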