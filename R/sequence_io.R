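#' Read a proteome from a FASTA file
#'
#' Parses an amino-acid FASTA file into a proteome table. The first
#' whitespace-delimited token of each header becomes the protein identifier;
#' the remainder of the header is scanned for a fragment marker (by default
#' the UniProt-style `"(Fragment)"`) which sets the `is_fragment` flag.
#' Sequences are uppercased.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param organism Organism label attached to the proteome; defaults to the
#'   file name without extension.
#' @param fragment_marker Substring of the header that marks a fragment
#'   entry. Matched literally, case sensitive.
#'
#' @return A `proteome`: a [tibble::tibble()] with columns `protein_id`,
#'   `gene_id` (NA unless a `GN=` field is present in the header),
#'   `sequence` and `is_fragment`, plus attributes `organism` and
#'   `filtered` (`FALSE` on read).
#' @seealso [filter_proteome()]
#' @export
read_fasta <- function(path, organism = NULL,
                       fragment_marker = "(Fragment)") {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate protein_id in FASTA: ", paste(dup, collapse = ", "))
  }
  gene <- rep(NA_character_, length(set))
  gn <- regmatches(headers, regexpr("GN=[^ ]+", headers))
  has_gn <- grepl("GN=[^ ]+", headers)
  gene[has_gn] <- sub("^GN=", "", gn)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  new_proteome(
    tibble::tibble(
      protein_id = unname(ids),
      gene_id = gene,
      sequence = unname(seqs),
      is_fragment = grepl(fragment_marker, headers, fixed = TRUE)
    ),
    organism = organism %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Construct a proteome table
#'
#' @param records Data frame with at least `protein_id` and `sequence`
#'   columns; `gene_id` and `is_fragment` are filled with defaults when
#'   absent.
#' @param organism Organism label.
#' @param filtered Whether the records have already passed dataset filters.
#' @return A `proteome` tibble.
#' @export
new_proteome <- function(records, organism, filtered = FALSE) {
  records <- tibble::as_tibble(records)
  if (!"gene_id" %in% names(records)) records$gene_id <- NA_character_
  if (!"is_fragment" %in% names(records)) records$is_fragment <- FALSE
  records <- records[, c("protein_id", "gene_id", "sequence", "is_fragment")]
  if (anyDuplicated(records$protein_id)) {
    stop("duplicate protein_id in proteome: ",
         paste(unique(records$protein_id[duplicated(records$protein_id)]),
               collapse = ", "))
  }
  structure(records,
            class = c("proteome", class(records)),
            organism = organism, filtered = filtered)
}

standard_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
nonstandard_aa <- c("U", "O")   # selenocysteine, pyrrolysine
ambiguous_aa <- c("B", "X", "Z", "J")

#' Filter a proteome by the dataset cleaning rules
#'
#' Removes records that would not be tractable by residue-level disorder
#' predictors: repeated sequences (identical full amino-acid sequence to an
#' earlier record; the first occurrence is kept), fragments (header-flagged),
#' sequences containing non-standard residues (U selenocysteine, O
#' pyrrolysine) and sequences containing ambiguity codes (B, X, Z, J).
#' A record is attributed to the first active rule that catches it, in the
#' order duplicate, fragment, nonstandard, ambiguous.
#'
#' @param proteome A `proteome` from [read_fasta()] or [new_proteome()].
#' @param rules Character subset of
#'   `c("duplicate", "fragment", "nonstandard", "ambiguous")`.
#' @return A list with elements `proteome` (surviving records, input order,
#'   `filtered` attribute set) and `report` (a `filter_report` list with
#'   per-rule removal counts and input/output totals; serialize with
#'   [filter_report_json()]).
#' @export
filter_proteome <- function(proteome,
                            rules = c("duplicate", "fragment",
                                      "nonstandard", "ambiguous")) {
  rules <- match.arg(rules, several.ok = TRUE)
  n_in <- nrow(proteome)
  removed <- c(duplicate = 0L, fragment = 0L,
               nonstandard = 0L, ambiguous = 0L)
  drop <- rep(FALSE, n_in)
  reason <- rep(NA_character_, n_in)
  if ("duplicate" %in% rules) {
    d <- duplicated(proteome$sequence)
    reason[d & !drop] <- "duplicate"; drop <- drop | d
  }
  if ("fragment" %in% rules) {
    d <- proteome$is_fragment
    reason[d & !drop] <- "fragment"; drop <- drop | d
  }
  if ("nonstandard" %in% rules) {
    d <- grepl(paste0("[", paste(nonstandard_aa, collapse = ""), "]"),
               proteome$sequence)
    reason[d & !drop] <- "nonstandard"; drop <- drop | d
  }
  if ("ambiguous" %in% rules) {
    d <- grepl(paste0("[", paste(ambiguous_aa, collapse = ""), "]"),
               proteome$sequence)
    reason[d & !drop] <- "ambiguous"; drop <- drop | d
  }
  tab <- table(factor(reason[drop], levels = names(removed)))
  removed[names(tab)] <- as.integer(tab)
  out <- new_proteome(proteome[!drop, , drop = FALSE],
                      organism = attr(proteome, "organism"),
                      filtered = TRUE)
  report <- structure(
    list(organism = attr(proteome, "organism"),
         rules = rules,
         removed = as.list(removed),
         input_total = n_in,
         output_total = nrow(out)),
    class = "filter_report")
  list(proteome = out, report = report)
}

#' Serialize a filter report as JSON
#'
#' @param report A `filter_report` from [filter_proteome()].
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
filter_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write a proteome to FASTA
#'
#' @param proteome A `proteome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  hdr <- ifelse(proteome$is_fragment,
                paste0(proteome$protein_id, " (Fragment)"),
                proteome$protein_id)
  lines <- as.vector(rbind(paste0(">", hdr), proteome$sequence))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
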